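# End-to-end codec orchestration: model container, subband feature
# normalization, bitstream format, compress/decompress, training loop with
# early stopping, and rate-distortion sweeps.
#
# Pipeline (compress):  dwt2 -> normalize -> cross-attention reweighting ->
#   VAE encoder (posterior mean as the deterministic code) -> uniform
#   quantization -> adaptive arithmetic coding -> container.
# Pipeline (decompress): decode symbols -> dequantize -> VAE decoder ->
#   un-normalize -> idwt2 -> optional trained spatial filter.

#' Create an (untrained) codec model
#'
#' The model ties together the wavelet front end, the frozen seeded
#' cross-attention block, and the VAE. The codec path uses a single
#' decomposition level; subband coefficients are mapped affinely into
#' `[0, 1]` before the networks (`LL / 2`, `detail / 2 + 0.5` for an
#' orthonormal level-1 transform) and the decoder output is mapped back.
#'
#' @param image_shape `(height, width)` of the images the model codes; must
#'   be divisible by 32 (one wavelet halving plus four pooling stages).
#' @param wavelet_name Orthonormal wavelet for the front end.
#' @param channels,latent_dim,fc_dim,dropout VAE architecture (see
#'   [vae_spec()]).
#' @param heads,embed_dim Cross-attention configuration.
#' @param loss_mode `"mse"` (composite MSE + perceptual + KL) or `"bce"`
#'   (binary cross-entropy + KL).
#' @param lambda A [loss_weights()].
#' @param seed Integer seed for all weight initialization.
#' @return A `wavecal_model`.
#' @export
wavecal_model <- function(image_shape = c(64L, 64L), wavelet_name = "haar",
                          channels = c(32L, 64L, 128L, 128L),
                          latent_dim = 64L, fc_dim = 128L, dropout = 0.3,
                          heads = 8L, embed_dim = 64L,
                          loss_mode = c("mse", "bce"),
                          lambda = loss_weights(), seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (any(image_shape %% 32L != 0L)) {
    stop("`image_shape` must be divisible by 32", call. = FALSE)
  }
  feat_shape <- c(image_shape %/% 2L, 4L)
  vs <- vae_spec(input_shape = feat_shape, channels = channels,
                 latent_dim = latent_dim, fc_dim = fc_dim, dropout = dropout)
  structure(
    list(image_shape = as.integer(image_shape),
         wavelet_name = wavelet_name, levels = 1L,
         cal = cal_weights(multi_head_config(heads, embed_dim),
                           n_hf_channels = 3L, seed = seed + 7L),
         vae = vae_new(vs, seed = seed),
         extractor = perceptual_extractor(4L, seed = seed + 11L),
         filter_kernel = NULL,
         loss_mode = loss_mode, lambda = lambda,
         trained = FALSE, hash = NULL, seed = as.integer(seed)),
    class = "wavecal_model"
  )
}

model_hash <- function(model) {
  object_hash8(list(model$vae, model$cal, model$wavelet_name, model$levels,
                    model$image_shape))
}

# subband set -> normalized (H/2, W/2, 4) arrays: encoder input (with
# attention-reweighted details) and reconstruction target (plain details)
codec_features <- function(model, image) {
  sb <- dwt2(image, model$wavelet_name, model$levels)
  ll_n <- sb$ll / 2
  d <- sb$detail[[1]]
  hf_n <- array(c(d$LH / 2 + 0.5, d$HL / 2 + 0.5, d$HH / 2 + 0.5),
                c(dim(sb$ll), 3L))
  hf_att <- cal_block(ll_n, hf_n, model$cal)
  hf_att <- pmin(pmax(hf_att, 0), 1)
  x <- array(c(ll_n, hf_att), c(dim(sb$ll), 4L))
  target <- array(c(ll_n, hf_n), c(dim(sb$ll), 4L))
  list(x = x, target = target)
}

# decoded (H/2, W/2, 4) feature array -> image via inverse wavelet transform
features_to_image <- function(model, feats) {
  m2 <- dim(feats)[1]; n2 <- dim(feats)[2]
  sb <- structure(
    list(detail = list(list(LH = (feats[, , 2] - 0.5) * 2,
                            HL = (feats[, , 3] - 0.5) * 2,
                            HH = (feats[, , 4] - 0.5) * 2)),
         ll = feats[, , 1] * 2,
         wavelet_name = model$wavelet_name, levels = 1L,
         boundary_mode = "periodic",
         original_shape = c(2L * m2, 2L * n2)),
    class = "subband_set")
  pmin(pmax(idwt2(sb), 0), 1)
}

float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric", size = 4L)
}

#' Compress an image to a bitstream
#'
#' Deterministic at inference: the latent code is the posterior mean, so the
#' same (image, model, quantizer) always yields byte-identical bitstreams.
#' The quantization step is rounded to float32 (its stored precision) before
#' use, so encoder and decoder share the exact step.
#'
#' @param image Numeric matrix in `[0, 1]` matching the model's image shape.
#' @param model A trained `wavecal_model`.
#' @param qconfig A [quantizer_config()].
#' @return A `wavecal_bitstream` object.
#' @export
compress <- function(image, model, qconfig = quantizer_config()) {
  if (!inherits(model, "wavecal_model")) {
    stop("`model` must be a `wavecal_model`", call. = FALSE)
  }
  if (!isTRUE(model$trained)) {
    stop("model is untrained; run train_codec() first", call. = FALSE)
  }
  if (!identical(dim(image), model$image_shape)) {
    stop(sprintf("image is %d x %d but the model codes %d x %d",
                 nrow(image), ncol(image),
                 model$image_shape[1], model$image_shape[2]), call. = FALSE)
  }
  qstep <- float32(qconfig$step)
  qc <- quantizer_config(qstep, qconfig$clip_range)
  feats <- codec_features(model, image)
  dist <- encode(feats$x, model$vae)
  stream <- quantize(dist$mu, qc)
  payload <- encode_symbols(stream)
  structure(
    list(version = 1L,
         height = nrow(image), width = ncol(image),
         wavelet_id = .wavelet_ids[[model$wavelet_name]],
         levels = model$levels, qstep = qstep,
         model_hash = model$hash,
         n_symbols = length(stream$symbols),
         alphabet_size = stream$alphabet_size,
         checksum = adler32(payload),
         payload = payload),
    class = "wavecal_bitstream"
  )
}

#' Serialize a bitstream to raw bytes (little-endian container)
#'
#' Layout: magic `"WCAL"`, version (1 byte), height/width (uint16), wavelet
#' id and levels (1 byte each), qstep (float32), model hash (8 bytes),
#' n_symbols (uint32), alphabet size (uint16), Adler-32 payload checksum
#' (uint32), payload length (uint32), payload.
#'
#' @param bs A `wavecal_bitstream`.
#' @return Raw vector.
#' @export
bitstream_to_raw <- function(bs) {
  c(charToRaw("WCAL"),
    as.raw(bs$version),
    uint16_to_raw(bs$height), uint16_to_raw(bs$width),
    as.raw(bs$wavelet_id), as.raw(bs$levels),
    writeBin(as.numeric(bs$qstep), raw(), size = 4L, endian = "little"),
    bs$model_hash,
    uint32_to_raw(bs$n_symbols),
    uint16_to_raw(bs$alphabet_size),
    uint32_to_raw(bs$checksum),
    uint32_to_raw(length(bs$payload)),
    bs$payload)
}

#' Parse a bitstream from raw bytes
#'
#' Verifies the magic number, version, declared payload length and the
#' payload checksum; any failure is a format error, never a silent wrong
#' decode.
#'
#' @param r Raw vector from [bitstream_to_raw()] or a `.wcal` file.
#' @return A `wavecal_bitstream`.
#' @export
bitstream_from_raw <- function(r) {
  if (length(r) < 37L || !identical(rawToChar(r[1:4]), "WCAL")) {
    stop("not a WCAL bitstream (bad magic)", call. = FALSE)
  }
  version <- as.integer(r[5])
  if (version != 1L) stop("unsupported bitstream version", call. = FALSE)
  height <- as.integer(raw_to_uint16(r[6:7]))
  width <- as.integer(raw_to_uint16(r[8:9]))
  wavelet_id <- as.integer(r[10])
  levels <- as.integer(r[11])
  qstep <- readBin(r[12:15], "numeric", size = 4L, endian = "little")
  hash <- r[16:23]
  n_symbols <- as.integer(raw_to_uint32(r[24:27]))
  alphabet_size <- as.integer(raw_to_uint16(r[28:29]))
  checksum <- raw_to_uint32(r[30:33])
  plen <- raw_to_uint32(r[34:37])
  if (length(r) != 37L + plen) {
    stop("truncated or oversized bitstream payload", call. = FALSE)
  }
  payload <- if (plen > 0) r[38:(37L + plen)] else raw(0)
  if (adler32(payload) != checksum) {
    stop("payload checksum mismatch: corrupt bitstream", call. = FALSE)
  }
  structure(
    list(version = version, height = height, width = width,
         wavelet_id = wavelet_id, levels = levels, qstep = qstep,
         model_hash = hash, n_symbols = n_symbols,
         alphabet_size = alphabet_size, checksum = checksum,
         payload = payload),
    class = "wavecal_bitstream"
  )
}

#' Write / read a bitstream file
#'
#' @param bs A `wavecal_bitstream`.
#' @param path File path (conventionally `.wcal`).
#' @return `write_bitstream`: `path` invisibly; `read_bitstream`: the parsed
#'   bitstream.
#' @export
write_bitstream <- function(bs, path) {
  writeBin(bitstream_to_raw(bs), path)
  invisible(path)
}

#' @rdname write_bitstream
#' @export
read_bitstream <- function(path) {
  bitstream_from_raw(readBin(path, "raw", n = file.size(path)))
}

#' Total size of a bitstream in bits (header + payload)
#' @param bs A `wavecal_bitstream`.
#' @return Number of bits.
#' @export
bitstream_n_bits <- function(bs) {
  8 * length(bitstream_to_raw(bs))
}

#' Decompress a bitstream back to an image
#'
#' Refuses to decode with a model whose hash does not match the header
#' (encoder/decoder pairing is enforced). If the model carries a trained
#' spatial filter, it is applied after the inverse wavelet transform.
#'
#' @param bs A `wavecal_bitstream`.
#' @param model The `wavecal_model` that produced it.
#' @return Reconstructed image matrix in `[0, 1]`.
#' @export
decompress <- function(bs, model) {
  if (!inherits(bs, "wavecal_bitstream")) {
    stop("`bs` must be a `wavecal_bitstream`", call. = FALSE)
  }
  if (!identical(as.raw(bs$model_hash), as.raw(model$hash))) {
    stop("model hash mismatch: bitstream was produced by a different model",
         call. = FALSE)
  }
  qc <- quantizer_config(bs$qstep,
                         clip_range = (bs$alphabet_size - 1L) %/% 2L)
  stream <- decode_symbols(bs$payload, bs$alphabet_size, bs$n_symbols)
  z <- dequantize(stream, qc)
  feats <- decode(z, model$vae)
  img <- features_to_image(model, feats)
  if (!is.null(model$filter_kernel)) {
    img <- apply_filter(img, model$filter_kernel)
  }
  img
}

#' Training configuration
#'
#' Defaults follow the reference setup: Adam (`beta1 = 0.9`, `beta2 =
#' 0.999`), batch size 32, up to 150 epochs, dropout 0.3 after dense layers,
#' Xavier-normal initialization, early stopping with patience 10. The default
#' learning rate is 1e-4; the alternative 2e-4 that the same source also
#' states, or any other rate, can be set explicitly (scaled-down desk runs
#' use larger rates since they take far fewer steps).
#'
#' @param lr Learning rate (initial, when `lr_end` is set).
#' @param lr_end Final learning rate of a cosine decay schedule over the
#'   planned epochs; `NULL` (default) keeps `lr` constant.
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param seed Integer seed governing the split, shuffling, dropout and
#'   reparameterization noise.
#' @param fractions Train/val/test fractions for [make_split()].
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 1e-4, lr_end = NULL, batch_size = 32L,
                         epochs = 150L, patience = 10L, seed = 1L,
                         fractions = c(0.70, 0.15, 0.15)) {
  if (lr <= 0 || batch_size < 1 || epochs < 1 || patience < 1) {
    stop("rates and sizes must be positive; patience >= 1", call. = FALSE)
  }
  structure(list(lr = lr, lr_end = if (is.null(lr_end)) lr else lr_end,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed), fractions = fractions),
            class = "train_config")
}

# epoch at which early stopping halts: best-so-far val loss (strict
# improvement; first occurrence kept on ties) unimproved for `patience`
# epochs. Returns NA if training runs to the end of the sequence.
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf
  best_at <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_at <- e
    } else if (e - best_at >= patience) {
      return(e)
    }
  }
  NA_integer_
}

stack_features <- function(model, images) {
  n <- length(images)
  d2 <- c(model$image_shape %/% 2L, 4L)
  x <- array(0, c(d2, n))
  tg <- array(0, c(d2, n))
  for (i in seq_len(n)) {
    f <- codec_features(model, images[[i]])
    x[, , , i] <- f$x
    tg[, , , i] <- f$target
  }
  list(x = x, target = tg)
}

#' Train the codec VAE on a set of images
#'
#' Splits the images 70/15/15 (train/val/test), precomputes the wavelet +
#' cross-attention features once per image (the attention projections are
#' frozen), and minimizes the composite loss with Adam. Validation loss is
#' monitored deterministically (posterior mean, inference-mode batch norm);
#' early stopping restores the best-validation checkpoint (first occurrence
#' on ties). After training, batch-norm running statistics are re-estimated
#' over the training features at the final weights (they lag the weights
#' during optimization). Fully seeded: the same images, config and seed
#' reproduce an identical model. The log's epoch-0 row records the validation
#' metrics of the untrained model. If a loss becomes non-finite (a diverging
#' learning rate), training warns, halts, and returns the best finite
#' checkpoint rather than erroring.
#'
#' @param images List of equal-sized image matrices in `[0, 1]`.
#' @param model A `wavecal_model` (untrained or to be re-trained).
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return `list(model, log, split)`: the trained model, a per-epoch
#'   `data.frame` (`epoch`, `train_loss`, `val_loss`, `val_recon_mse`) and
#'   the `dataset_split` used.
#' @export
train_codec <- function(images, model, config = train_config(),
                        verbose = FALSE) {
  if (length(images) < 10L) stop("need at least 10 images", call. = FALSE)
  split <- make_split(length(images), config$fractions, seed = config$seed)
  feats <- stack_features(model, images)
  d2 <- dim(feats$x)[1:3]
  tr_ids <- split$train_ids
  va_ids <- split$val_ids
  xa <- feats$x; tga <- feats$target

  vae <- model$vae
  lw <- model$lambda
  mode <- model$loss_mode
  extractor <- model$extractor
  latent <- vae$spec$latent_dim

  val_metrics <- function(vv) {
    xv <- xa[, , , va_ids, drop = FALSE]
    tv <- tga[, , , va_ids, drop = FALSE]
    dist <- encode(xv, vv)
    recon <- decode(dist$mu, vv)
    lb <- composite_loss(recon, tv, dist, lw, mode = mode,
                         extractor = extractor)
    c(total = lb$total, recon_mse = mean((recon - tv)^2))
  }

  n_tr <- length(tr_ids)
  states <- list(enc = adam_init(vae$enc), head_mu = adam_init(vae$head_mu),
                 head_logvar = adam_init(vae$head_logvar),
                 dec = adam_init(vae$dec))
  step_t <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_recon_mse = numeric(0))
  best_val <- Inf
  best_vae <- vae
  best_epoch <- 0L

  vm0 <- val_metrics(vae)
  log <- rbind(log, data.frame(epoch = 0L, train_loss = NA_real_,
                               val_loss = vm0[["total"]],
                               val_recon_mse = vm0[["recon_mse"]]))
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr_t <- config$lr_end + 0.5 * (config$lr - config$lr_end) *
        (1 + cos(pi * (epoch - 1) / config$epochs))
      ord <- sample(tr_ids)
      ep_loss <- 0
      n_batches <- 0L
      vm <- tryCatch({
      for (b0 in seq(1L, n_tr, by = config$batch_size)) {
        ids <- ord[b0:min(b0 + config$batch_size - 1L, n_tr)]
        xb <- xa[, , , ids, drop = FALSE]
        tb <- tga[, , , ids, drop = FALSE]
        eps <- matrix(stats::rnorm(length(ids) * latent), length(ids))
        res <- vae_loss_grads(vae, xb, tb, eps, lw, mode = mode,
                              extractor = extractor, training = TRUE)
        vae$enc <- res$nets$enc
        vae$head_mu <- res$nets$head_mu
        vae$head_logvar <- res$nets$head_logvar
        vae$dec <- res$nets$dec
        step_t <- step_t + 1L
        for (part in names(states)) {
          st <- adam_step(vae[[part]], res$grads[[part]], states[[part]],
                          t = step_t, lr = lr_t)
          vae[[part]] <- st$net
          states[[part]] <- st$state
        }
        ep_loss <- ep_loss + res$loss$total
        n_batches <- n_batches + 1L
      }
      val_metrics(vae)
      }, error = function(e) {
        # non-finite activations surface as errors from the forward pass;
        # anything else is a genuine bug and must propagate
        if (!grepl("non-finite", conditionMessage(e))) stop(e)
        c(total = NaN, recon_mse = NaN)
      })
      if (!is.finite(vm[["total"]])) {
        warning("training loss became non-finite at epoch ", epoch,
                "; stopping and keeping the best checkpoint (epoch ",
                best_epoch, "). A smaller learning rate avoids this.",
                call. = FALSE)
        break
      }
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = ep_loss / n_batches,
                                   val_loss = vm[["total"]],
                                   val_recon_mse = vm[["recon_mse"]]))
      if (verbose) {
        message(sprintf("epoch %3d  train %.6f  val %.6f  val recon %.6f",
                        epoch, ep_loss / n_batches, vm[["total"]],
                        vm[["recon_mse"]]))
      }
      if (vm[["total"]] < best_val) {
        best_val <- vm[["total"]]
        best_vae <- vae
        best_epoch <- epoch
      } else if (epoch - best_epoch >= config$patience) {
        break
      }
    }
  })
  model$vae <- vae_recalibrate_bn(best_vae, xa[, , , tr_ids, drop = FALSE])
  model$trained <- TRUE
  model$hash <- model_hash(model)
  list(model = model, log = log, split = split)
}

#' Packaged desk-scale codec configuration
#'
#' A codec model and training configuration sized for single-CPU runs
#' (minutes, not hours): the reference channel widths (32, 64, 128, 128) and
#' latent dimension 64, but dropout disabled, a zero KL weight, and a larger
#' cosine-decayed learning rate. The methods vignette motivates each
#' departure from the full-scale defaults: a 30-epoch run takes two orders of
#' magnitude fewer optimizer steps than the reference schedule, where
#' regularization only slows convergence, and any positive KL weight under
#' Adam collapses the posterior before the latent code becomes informative.
#'
#' @param image_shape `(height, width)`, divisible by 32.
#' @param seed Integer seed.
#' @return `demo_model()`: an untrained `wavecal_model`;
#'   `demo_train_config()`: a `train_config`.
#' @export
demo_model <- function(image_shape = c(32L, 32L), seed = 1L) {
  wavecal_model(image_shape = image_shape,
                channels = c(32L, 64L, 128L, 128L),
                latent_dim = 64L, fc_dim = 128L, dropout = 0,
                lambda = loss_weights(1, 0.01, 0), seed = seed)
}

#' @rdname demo_model
#' @param epochs Training epochs (default 30).
#' @param lr,lr_end Cosine learning-rate schedule endpoints. The defaults
#'   suit 32x32 inputs; larger inputs need a smaller rate (training at
#'   64x64 diverges at the 32x32 default).
#' @export
demo_train_config <- function(seed = 1L, epochs = 30L, lr = 1e-2,
                              lr_end = lr / 10) {
  train_config(lr = lr, lr_end = lr_end, batch_size = 8L, epochs = epochs,
               patience = 10L, seed = seed)
}

#' Five-fold cross-validation driver
#'
#' Re-runs [train_codec()] on each fold (the fold is held out for
#' validation-style evaluation; early stopping still uses the inner split)
#' and reports the mean and standard deviation of the held-out feature-domain
#' reconstruction MSE.
#'
#' @param images List of image matrices.
#' @param model_factory Zero-argument function returning a fresh untrained
#'   `wavecal_model`.
#' @param config A [train_config()].
#' @param k Number of folds.
#' @return `data.frame` with one row per fold plus attributes `mean`, `sd`.
#' @export
train_codec_cv <- function(images, model_factory, config = train_config(),
                           k = 5L) {
  n <- length(images)
  fold_of <- with_seed(config$seed, sample(rep_len(seq_len(k), n)))
  res <- data.frame(fold = seq_len(k), recon_mse = NA_real_)
  for (f in seq_len(k)) {
    tr_imgs <- images[fold_of != f]
    te_imgs <- images[fold_of == f]
    fit <- train_codec(tr_imgs, model_factory(), config)
    fe <- stack_features(fit$model, te_imgs)
    dist <- encode(fe$x, fit$model$vae)
    recon <- decode(dist$mu, fit$model$vae)
    res$recon_mse[f] <- mean((recon - fe$target)^2)
  }
  attr(res, "mean") <- mean(res$recon_mse)
  attr(res, "sd") <- stats::sd(res$recon_mse)
  res
}

#' Compress/decompress a set of images and collect quality metrics
#'
#' @param model Trained `wavecal_model`.
#' @param images List of image matrices.
#' @param qconfig A [quantizer_config()].
#' @return `data.frame` of per-image metric records (see [evaluate_pair()]).
#' @export
codec_evaluate <- function(model, images, qconfig = quantizer_config()) {
  rows <- lapply(seq_along(images), function(i) {
    t0 <- proc.time()[["elapsed"]]
    bs <- compress(images[[i]], model, qconfig)
    rec <- decompress(bs, model)
    dt <- (proc.time()[["elapsed"]] - t0) * 1000
    evaluate_pair(images[[i]], rec, n_bits = bitstream_n_bits(bs),
                  image_id = sprintf("img%03d", i), time_ms = dt)
  })
  do.call(rbind, rows)
}

#' Rate-distortion sweep over quantization steps
#'
#' @param images List of image matrices.
#' @param model Trained `wavecal_model`.
#' @param qsteps Numeric vector of at least 2 quantization steps.
#' @return `data.frame` with one metric record per (image, qstep).
#' @export
rd_curve <- function(images, model, qsteps) {
  if (length(qsteps) < 2L) {
    stop("`qsteps` must contain at least two steps", call. = FALSE)
  }
  out <- lapply(qsteps, function(q) {
    r <- codec_evaluate(model, images, quantizer_config(step = q))
    r$qstep <- q
    r
  })
  do.call(rbind, out)
}
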