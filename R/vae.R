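# Convolutional variational autoencoder with a Gaussian latent prior:
# 4x (3x3 conv -> ReLU -> batch-norm -> 2x2 max-pool) encoder, two fully
# connected layers producing the latent mean and log-variance, and a
# mirrored transposed-convolution decoder with a sigmoid output squashing.

#' Specify a VAE architecture
#'
#' @param input_shape `(height, width, channels)` of the feature maps fed to
#'   the encoder; height and width must be divisible by 16 (four 2x2 pools).
#' @param channels Widths of the four convolutional stages.
#' @param latent_dim Latent code length.
#' @param fc_dim Width of the fully connected layer before the latent heads.
#' @param dropout Dropout rate applied after dense layers during training.
#' @param logvar_bias Initial bias of the log-variance head. A low starting
#'   value (default -6, posterior sd ~ 0.05) keeps early reparameterization
#'   noise from swamping the reconstruction signal in short training runs;
#'   the head is free to move away from it.
#' @return A `vae_spec` object.
#' @export
vae_spec <- function(input_shape = c(32L, 32L, 4L),
                     channels = c(32L, 64L, 128L, 128L),
                     latent_dim = 64L, fc_dim = 128L, dropout = 0.3,
                     logvar_bias = -6) {
  if (length(input_shape) != 3L) {
    stop("`input_shape` must be (height, width, channels)", call. = FALSE)
  }
  if (input_shape[1] %% 16L != 0L || input_shape[2] %% 16L != 0L) {
    stop("encoder input height/width must be divisible by 16", call. = FALSE)
  }
  if (length(channels) != 4L) stop("`channels` must have length 4", call. = FALSE)
  structure(list(input_shape = as.integer(input_shape),
                 channels = as.integer(channels),
                 latent_dim = as.integer(latent_dim),
                 fc_dim = as.integer(fc_dim), dropout = dropout,
                 logvar_bias = logvar_bias),
            class = "vae_spec")
}

#' Create a VAE with Xavier-normal initialized weights
#'
#' @param spec A [vae_spec()].
#' @param seed Integer seed for initialization.
#' @return A `wavecal_vae` object with encoder trunk, latent heads
#'   (`head_mu`, `head_logvar`) and decoder.
#' @export
vae_new <- function(spec, seed = 1L) {
  hs <- spec$input_shape[1]
  ws <- spec$input_shape[2]
  c_in <- spec$input_shape[3]
  ch <- spec$channels
  h4 <- hs %/% 16L
  w4 <- ws %/% 16L
  d_flat <- h4 * w4 * ch[4]

  enc <- list(
    nn_conv(c_in, ch[1]), nn_relu(), nn_bn(ch[1]), nn_pool(),
    nn_conv(ch[1], ch[2]), nn_relu(), nn_bn(ch[2]), nn_pool(),
    nn_conv(ch[2], ch[3]), nn_relu(), nn_bn(ch[3]), nn_pool(),
    nn_conv(ch[3], ch[4]), nn_relu(), nn_bn(ch[4]), nn_pool(),
    nn_flatten(),
    nn_dense(d_flat, spec$fc_dim), nn_relu(), nn_dropout(spec$dropout)
  )
  head_mu <- list(nn_dense(spec$fc_dim, spec$latent_dim))
  head_logvar <- list(nn_dense(spec$fc_dim, spec$latent_dim))
  dec <- list(
    nn_dense(spec$latent_dim, spec$fc_dim), nn_relu(),
    nn_dropout(spec$dropout),
    nn_dense(spec$fc_dim, d_flat), nn_relu(),
    nn_reshape(h4, w4, ch[4]),
    nn_tconv(ch[4], ch[3]), nn_relu(), nn_bn(ch[3]),
    nn_tconv(ch[3], ch[2]), nn_relu(), nn_bn(ch[2]),
    nn_tconv(ch[2], ch[1]), nn_relu(), nn_bn(ch[1]),
    nn_tconv(ch[1], c_in), nn_sigmoid()
  )
  head_logvar <- nn_init(head_logvar, seed + 2L)
  head_logvar[[1]]$b <- rep(spec$logvar_bias, spec$latent_dim)
  structure(
    list(spec = spec,
         enc = nn_init(enc, seed),
         head_mu = nn_init(head_mu, seed + 1L),
         head_logvar = head_logvar,
         dec = nn_init(dec, seed + 3L)),
    class = "wavecal_vae"
  )
}

as_batch <- function(features, c_expected) {
  d <- dim(features)
  if (length(d) == 3L) {
    array(features, c(d, 1L))
  } else if (length(d) == 4L) {
    features
  } else {
    stop("features must be an (H, W, C) or (H, W, C, N) array", call. = FALSE)
  }
}

#' Encode features to a latent Gaussian posterior
#'
#' Inference-mode forward pass (batch-norm running statistics, dropout off),
#' deterministic given the weights.
#'
#' @param features `(H, W, C)` array (or `(H, W, C, N)` batch) matching the
#'   VAE's input shape.
#' @param vae A `wavecal_vae`.
#' @return For a single image, a `latent_distribution` with vectors `mu` and
#'   `logvar`; for a batch, matrices (`N x latent_dim`).
#' @export
encode <- function(features, vae) {
  x <- as_batch(features, vae$spec$input_shape[3])
  single <- dim(x)[4] == 1L && length(dim(features)) == 3L
  trunk <- nn_forward(vae$enc, x, training = FALSE)
  mu <- nn_forward(vae$head_mu, trunk$out, training = FALSE)$out
  logvar <- nn_forward(vae$head_logvar, trunk$out, training = FALSE)$out
  if (single) {
    latent_distribution(as.vector(mu), as.vector(logvar))
  } else {
    latent_distribution(mu, logvar)
  }
}

#' Construct a latent distribution object
#'
#' @param mu Latent mean vector (or `N x d` matrix).
#' @param logvar Latent log-variance of the same shape.
#' @param z Optional sampled code.
#' @return A `latent_distribution` object.
#' @export
latent_distribution <- function(mu, logvar, z = NULL) {
  if (!all(is.finite(mu)) || !all(is.finite(logvar))) {
    stop("`mu` and `logvar` must be finite", call. = FALSE)
  }
  if (length(mu) != length(logvar)) {
    stop("`mu` and `logvar` must have equal length", call. = FALSE)
  }
  structure(list(mu = mu, logvar = logvar, z = z),
            class = "latent_distribution")
}

#' Reparameterized sample from the latent posterior
#'
#' `z = mu + exp(logvar / 2) * eps`, `eps ~ N(0, I)` drawn from the seeded
#' generator.
#'
#' @param dist A [latent_distribution()].
#' @param seed Integer seed.
#' @return Sampled code `z`, same shape as `mu`.
#' @export
reparameterize <- function(dist, seed = 1L) {
  eps <- with_seed(seed, stats::rnorm(length(dist$mu)))
  if (is.matrix(dist$mu)) eps <- matrix(eps, nrow(dist$mu))
  dist$mu + exp(dist$logvar / 2) * eps
}

#' Decode a latent code to feature maps
#'
#' Inference-mode forward pass; output values lie in `[0, 1]` after the final
#' sigmoid squashing and the spatial shape equals the encoder input shape.
#'
#' @param z Latent vector of length `latent_dim` (or `N x latent_dim` matrix).
#' @param vae A `wavecal_vae`.
#' @return `(H, W, C)` array (or `(H, W, C, N)` for a batch).
#' @export
decode <- function(z, vae) {
  single <- !is.matrix(z)
  zm <- if (single) matrix(z, 1L) else z
  if (ncol(zm) != vae$spec$latent_dim) {
    stop("`z` length must equal latent_dim", call. = FALSE)
  }
  out <- nn_forward(vae$dec, zm, training = FALSE)$out
  if (single) array(out, dim(out)[1:3]) else out
}

#' Closed-form KL divergence to the standard normal prior
#'
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)` for a diagonal Gaussian
#' posterior; non-negative, and zero iff `mu = 0, logvar = 0`. For matrix
#' (batch) input the per-image KLs are averaged.
#'
#' @param dist A [latent_distribution()].
#' @return Scalar KL divergence (nats).
#' @export
kl_gaussian <- function(dist) {
  k <- 0.5 * (dist$mu^2 + exp(dist$logvar) - 1 - dist$logvar)
  if (is.matrix(dist$mu)) mean(rowSums(k)) else sum(k)
}

#' Loss weights for the composite objective
#'
#' The composite training loss is
#' `lambda1 * L_recon + lambda2 * L_perceptual + lambda3 * KL`.
#' Defaults: reconstruction dominates (`lambda1 = 1`), a small perceptual
#' term (`lambda2 = 0.01`) and a mild KL regularizer (`lambda3 = 1e-4`) --
#' the source formulation names the terms but not their weights.
#'
#' @param lambda1,lambda2,lambda3 Non-negative weights, not all zero.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 0.01, lambda3 = 1e-4) {
  lam <- c(lambda1, lambda2, lambda3)
  if (any(lam < 0) || all(lam == 0)) {
    stop("loss weights must be non-negative and not all zero", call. = FALSE)
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

#' Frozen perceptual feature extractor
#'
#' A small fixed, seeded, untrained two-layer convolutional network whose
#' feature maps define the perceptual distance. Using a frozen random
#' extractor keeps the "feature-space similarity" role of the perceptual term
#' without any pretrained weights.
#'
#' @param c_in Input channel count.
#' @param seed Integer seed.
#' @return A frozen layer list.
#' @export
perceptual_extractor <- function(c_in, seed = 99L) {
  nn_init(list(nn_conv(c_in, 8L), nn_relu(), nn_conv(8L, 8L)), seed)
}

bce_mean <- function(recon, target) {
  if (min(recon) < 0 || max(recon) > 1 || min(target) < 0 || max(target) > 1) {
    stop("BCE requires values in [0, 1]", call. = FALSE)
  }
  eps <- 1e-7
  r <- pmin(pmax(recon, eps), 1 - eps)
  mean(-(target * log(r) + (1 - target) * log(1 - r)))
}

#' Composite training loss
#'
#' `mse` mode: `lambda1 * MSE + lambda2 * L_perceptual + lambda3 * KL`.
#' `bce` mode: pixelwise binary cross-entropy replaces MSE and the perceptual
#' term is dropped (its weight is ignored). The breakdown always satisfies
#' `total = lambda1*recon + lambda2*perceptual + lambda3*kl`.
#'
#' @param recon,target Arrays of equal shape (on the `[0, 1]` scale for
#'   `"bce"`).
#' @param dist A [latent_distribution()].
#' @param weights A [loss_weights()].
#' @param mode `"mse"` or `"bce"`.
#' @param extractor Optional frozen extractor from [perceptual_extractor()];
#'   if `NULL` and `lambda2 > 0` in `"mse"` mode, a default one is built for
#'   the input channel count.
#' @return A `loss_breakdown` list: `total`, `recon`, `perceptual`, `kl`.
#' @export
composite_loss <- function(recon, target, dist, weights = loss_weights(),
                           mode = c("mse", "bce"), extractor = NULL) {
  mode <- match.arg(mode)
  if (!identical(dim(recon), dim(target))) {
    stop("`recon` and `target` must have identical shape", call. = FALSE)
  }
  kl <- kl_gaussian(dist)
  perc <- 0
  if (mode == "mse") {
    rec <- mean((recon - target)^2)
    if (weights$lambda2 > 0) {
      x <- as_batch(recon, NA)
      y <- as_batch(target, NA)
      if (is.null(extractor)) extractor <- perceptual_extractor(dim(x)[3])
      fx <- nn_forward(extractor, x, training = FALSE)$out
      fy <- nn_forward(extractor, y, training = FALSE)$out
      perc <- mean((fx - fy)^2)
    }
  } else {
    rec <- bce_mean(recon, target)
  }
  lam2 <- if (mode == "bce") 0 else weights$lambda2
  structure(list(
    total = weights$lambda1 * rec + lam2 * perc + weights$lambda3 * kl,
    recon = rec, perceptual = perc, kl = kl
  ), class = "loss_breakdown")
}

# Re-estimate batch-norm running statistics at the current weights over a
# reference input set, with the deterministic code z = mu. During training
# the running averages lag the moving weights (and include reparameterization
# noise); a single calibration pass makes inference-mode normalization match
# the statistics the final weights actually produce.
vae_recalibrate_bn <- function(vae, x) {
  recal <- function(net, input) {
    for (i in seq_along(net)) {
      if (net[[i]]$type == "bn") {
        mu_c <- apply(input, 3, mean)
        xc <- sweep(input, 3, mu_c)
        net[[i]]$run_mean <- mu_c
        net[[i]]$run_var <- apply(xc^2, 3, mean)
      }
      input <- nn_forward(net[i], input, training = FALSE)$out
    }
    list(net = net, out = input)
  }
  r <- recal(vae$enc, x)
  vae$enc <- r$net
  mu <- nn_forward(vae$head_mu, r$out, training = FALSE)$out
  vae$dec <- recal(vae$dec, mu)$net
  vae
}

# ---- training-mode forward/backward (used by the codec training loop) ------

# One full loss evaluation with analytic gradients for all VAE parameters.
# x: encoder input batch (H, W, C, N); target: decoder target batch of the
# same shape; eps: pre-drawn standard normal noise (N x latent) for the
# reparameterized sample. Dropout (if active) draws from the caller's RNG.
vae_loss_grads <- function(vae, x, target, eps, lw, mode = "mse",
                           extractor = NULL, training = TRUE) {
  trunk <- nn_forward(vae$enc, x, training = training)
  fmu <- nn_forward(vae$head_mu, trunk$out, training = training)
  flv <- nn_forward(vae$head_logvar, trunk$out, training = training)
  mu <- fmu$out
  logvar <- flv$out
  sd_ <- exp(logvar / 2)
  z <- mu + sd_ * eps
  fdec <- nn_forward(vae$dec, z, training = training)
  recon <- fdec$out
  n_batch <- dim(x)[4]

  kl <- mean(rowSums(0.5 * (mu^2 + exp(logvar) - 1 - logvar)))
  if (mode == "mse") {
    rec <- mean((recon - target)^2)
    drecon <- lw$lambda1 * 2 * (recon - target) / length(recon)
    perc <- 0
    if (lw$lambda2 > 0) {
      if (is.null(extractor)) extractor <- perceptual_extractor(dim(x)[3])
      fx <- nn_forward(extractor, recon, training = FALSE)
      fy <- nn_forward(extractor, target, training = FALSE)
      diff <- fx$out - fy$out
      perc <- mean(diff^2)
      dphi <- lw$lambda2 * 2 * diff / length(diff)
      drecon <- drecon + nn_backward(extractor, fx$caches, dphi)$dx
    }
  } else {
    rec <- bce_mean(recon, target)
    eps_c <- 1e-7
    r <- pmin(pmax(recon, eps_c), 1 - eps_c)
    drecon <- lw$lambda1 * (-(target / r) + (1 - target) / (1 - r)) /
      length(recon)
    perc <- 0
  }
  total <- lw$lambda1 * rec +
    (if (mode == "bce") 0 else lw$lambda2) * perc + lw$lambda3 * kl

  bdec <- nn_backward(vae$dec, fdec$caches, drecon)
  dz <- bdec$dx
  dmu <- dz + lw$lambda3 * mu / n_batch
  dlogvar <- dz * 0.5 * sd_ * eps +
    lw$lambda3 * 0.5 * (exp(logvar) - 1) / n_batch
  bmu <- nn_backward(vae$head_mu, fmu$caches, dmu)
  blv <- nn_backward(vae$head_logvar, flv$caches, dlogvar)
  benc <- nn_backward(vae$enc, trunk$caches, bmu$dx + blv$dx)

  list(
    loss = structure(list(total = total, recon = rec, perceptual = perc,
                          kl = kl), class = "loss_breakdown"),
    grads = list(enc = benc$grads, head_mu = bmu$grads,
                 head_logvar = blv$grads, dec = bdec$grads),
    nets = list(enc = trunk$net, head_mu = fmu$net,
                head_logvar = flv$net, dec = fdec$net),
    recon = recon
  )
}
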