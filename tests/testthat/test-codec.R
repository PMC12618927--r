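# Bitstream container, compress/decompress contracts, early stopping, and
# the end-to-end desk-scale quality gate.

make_bs <- function() {
  # a syntactically valid bitstream without touching a trained model
  structure(
    list(version = 1L, height = 64L, width = 64L, wavelet_id = 1L,
         levels = 1L, qstep = wavecal:::float32(0.05),
         model_hash = as.raw(1:8), n_symbols = 5L, alphabet_size = 255L,
         checksum = wavecal:::adler32(as.raw(c(9, 8, 7))),
         payload = as.raw(c(9, 8, 7))),
    class = "wavecal_bitstream")
}

test_that("container headers round-trip bit-exactly through raw and file forms", {
  bs <- make_bs()
  r <- bitstream_to_raw(bs)
  back <- bitstream_from_raw(r)
  for (f in c("version", "height", "width", "wavelet_id", "levels",
              "n_symbols", "alphabet_size", "checksum")) {
    expect_identical(back[[f]], bs[[f]], label = f)
  }
  expect_identical(back$payload, bs$payload)
  expect_equal(back$qstep, bs$qstep)
  path <- tempfile(fileext = ".wcal")
  write_bitstream(bs, path)
  expect_equal(bitstream_n_bits(bs), 8 * file.size(path))
  expect_identical(read_bitstream(path), back)
  unlink(path)
})

test_that("every single-byte corruption of a bitstream is detected", {
  bs <- make_bs()
  r <- bitstream_to_raw(bs)
  for (i in seq_along(r)) {
    bad <- r
    bad[i] <- xor(bad[i], as.raw(0x40))
    expect_error(
      {
        parsed <- bitstream_from_raw(bad)
        # header fields that do not participate in parsing must still be
        # caught downstream: the model-hash check guards those bytes
        if (!identical(parsed[c("height", "width", "qstep", "model_hash",
                                "wavelet_id", "levels", "n_symbols",
                                "alphabet_size")],
                       bs[c("height", "width", "qstep", "model_hash",
                            "wavelet_id", "levels", "n_symbols",
                            "alphabet_size")])) {
          stop("header field corrupted")
        }
        parsed
      },
      regexp = ".")
  }
})

test_that("early stopping halts after `patience` epochs without improvement", {
  # plateau after epoch 3 with patience 2 -> halt at epoch 5
  expect_equal(wavecal:::early_stop_epoch(c(5, 4, 3, 3, 3, 3), 2L), 5L)
  # strictly improving: never halts
  expect_true(is.na(wavecal:::early_stop_epoch(c(5, 4, 3, 2, 1), 2L)))
  # ties keep the first occurrence as best
  expect_equal(wavecal:::early_stop_epoch(c(2, 2, 2, 2), 3L), 4L)
})

test_that("compress refuses untrained models and mismatched shapes", {
  model <- demo_model(c(32L, 32L), seed = 1L)
  img <- generate_phantom(phantom_spec(32, 32, seed = 1L))
  expect_error(compress(img, model), "untrained")
  model$trained <- TRUE
  model$hash <- wavecal:::model_hash(model)
  expect_error(compress(matrix(0.5, 64, 64), model), "64 x 64")
})

# -- one small shared training run for the remaining contracts ---------------
small_fit <- local({
  imgs <- generate_phantom_set(40, 32L, 32L, seed = 77L)
  model <- demo_model(c(32L, 32L), seed = 3L)
  cfg <- demo_train_config(seed = 3L, epochs = 4L)
  train_codec(imgs, model, cfg)
})

test_that("training is seeded-deterministic: identical checkpoint hashes", {
  imgs <- generate_phantom_set(40, 32L, 32L, seed = 77L)
  fit2 <- train_codec(imgs, demo_model(c(32L, 32L), seed = 3L),
                      demo_train_config(seed = 3L, epochs = 4L))
  expect_identical(fit2$model$hash, small_fit$model$hash)
  expect_equal(fit2$log, small_fit$log)
})

test_that("inference is deterministic and byte-identical across runs", {
  img <- generate_phantom(phantom_spec(32, 32, seed = 5L))
  b1 <- compress(img, small_fit$model)
  b2 <- compress(img, small_fit$model)
  expect_identical(bitstream_to_raw(b1), bitstream_to_raw(b2))
  r1 <- decompress(b1, small_fit$model)
  expect_identical(r1, decompress(b2, small_fit$model))
  expect_equal(dim(r1), c(32L, 32L))
  expect_true(all(r1 >= 0 & r1 <= 1))
})

test_that("decompress enforces model pairing and payload integrity", {
  img <- generate_phantom(phantom_spec(32, 32, seed = 6L))
  bs <- compress(img, small_fit$model)
  other <- small_fit$model
  other$hash <- as.raw(rep(1, 8))
  expect_error(decompress(bs, other), "hash mismatch")
  r <- bitstream_to_raw(bs)
  r[length(r)] <- xor(r[length(r)], as.raw(1))
  expect_error(bitstream_from_raw(r), "checksum")
})

test_that("a trained filter attached to the model is applied on decompress", {
  img <- generate_phantom(phantom_spec(32, 32, seed = 7L))
  bs <- compress(img, small_fit$model)
  plain <- decompress(bs, small_fit$model)
  m2 <- small_fit$model
  m2$filter_kernel <- filter_kernel(matrix(c(0, 0, 0, 0, 0.5, 0, 0, 0, 0), 3, 3),
                                    bias = 0.1)
  expect_equal(decompress(bs, m2),
               pmin(pmax(plain * 0.5 + 0.1, 0), 1), tolerance = 1e-12)
})

test_that("rd_curve produces one record per image/qstep and coarse steps cost fewer bits", {
  imgs <- generate_phantom_set(3, 32L, 32L, seed = 9L)
  # steps chosen so no latent saturates the +/-127 clip: rate monotonicity
  # only holds below saturation (a clipped fine step concentrates symbols at
  # the clip values and can code *cheaper* than a coarser unclipped one)
  rd <- rd_curve(imgs, small_fit$model, qsteps = c(0.25, 1, 4))
  expect_equal(nrow(rd), 9L)
  bpp <- tapply(rd$bpp, rd$qstep, mean)
  psnr_q <- tapply(rd$psnr_db, rd$qstep, mean)
  # 4x+ coarser quantization must not cost more bits nor gain fidelity;
  # PSNR gets a 0.05 dB fluctuation allowance because below saturation the
  # quantization error is tiny next to the model's own reconstruction error
  expect_lte(bpp[["4"]], bpp[["1"]])
  expect_lte(bpp[["1"]], bpp[["0.25"]])
  expect_lte(psnr_q[["4"]], psnr_q[["1"]] + 0.05)
  expect_lte(psnr_q[["1"]], psnr_q[["0.25"]] + 0.05)
  expect_error(rd_curve(imgs, small_fit$model, qsteps = 0.5), "at least two")
  r1 <- codec_evaluate(small_fit$model, imgs[1], quantizer_config(0.2))
  r2 <- codec_evaluate(small_fit$model, imgs[1], quantizer_config(0.2))
  expect_equal(r1[, setdiff(names(r1), "time_ms")],
               r2[, setdiff(names(r2), "time_ms")])
})

test_that("a diverging run warns, halts, and still returns a usable checkpoint", {
  imgs <- generate_phantom_set(12, 32L, 32L, seed = 13L)
  expect_warning(
    fit <- train_codec(imgs, demo_model(c(32L, 32L), seed = 1L),
                       demo_train_config(seed = 1L, epochs = 6L, lr = 50)),
    "non-finite")
  expect_true(fit$model$trained)
  expect_true(all(is.finite(fit$log$val_loss)))
  img <- imgs[[1]]
  rec <- decompress(compress(img, fit$model, quantizer_config(0.25, 1023L)),
                    fit$model)
  expect_true(all(is.finite(rec)))
})

test_that("a 30-epoch 64x64 fixture training beats the constant-mean baseline under 4 bpp", {
  imgs <- generate_phantom_set(60, 64L, 64L, seed = 2024L)
  fit <- train_codec(imgs, demo_model(c(64L, 64L), seed = 11L),
                     demo_train_config(seed = 11L, epochs = 30L, lr = 5e-3))
  te <- imgs[fit$split$test_ids]
  rec <- codec_evaluate(fit$model, te, quantizer_config(0.25, clip_range = 1023L))
  const_psnr <- vapply(te, function(im) {
    psnr(im * 255, matrix(mean(im), 64, 64) * 255)
  }, numeric(1))
  expect_gt(mean(rec$psnr_db), mean(const_psnr))
  expect_lte(mean(rec$bpp), 4.0)
})
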