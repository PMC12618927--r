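# VAE: encode/decode contracts, reparameterization, KL closed form,
# composite loss, and the end-to-end gradient identity.

tiny_vae <- function(seed = 2L, dropout = 0) {
  vae_new(vae_spec(c(16L, 16L, 2L), channels = c(3L, 4L, 5L, 6L),
                   latent_dim = 5L, fc_dim = 7L, dropout = dropout),
          seed = seed)
}

test_that("encode is deterministic and zeroed heads give mu = logvar = 0", {
  v <- tiny_vae()
  x <- array(rand_image(16, 32, seed = 1), c(16, 16, 2))
  d1 <- encode(x, v)
  d2 <- encode(x, v)
  expect_identical(d1, d2)
  expect_length(d1$mu, 5L)
  # zero the head weights/biases: any trunk output maps to exactly zero
  v$head_mu[[1]]$W[] <- 0; v$head_mu[[1]]$b[] <- 0
  v$head_logvar[[1]]$W[] <- 0; v$head_logvar[[1]]$b[] <- 0
  d0 <- encode(x, v)
  expect_equal(d0$mu, rep(0, 5))
  expect_equal(d0$logvar, rep(0, 5))
})

test_that("reparameterize is seeded, degenerate at tiny variance, unbiased", {
  dist <- latent_distribution(mu = c(1, -2, 0.5), logvar = rep(-60, 3))
  expect_equal(reparameterize(dist, seed = 4L), dist$mu, tolerance = 1e-10)
  dist2 <- latent_distribution(mu = c(1, -2, 0.5), logvar = c(0.2, -1, 0.4))
  expect_identical(reparameterize(dist2, seed = 7L),
                   reparameterize(dist2, seed = 7L))
  # law of large numbers: mean of 1e5 draws within 3 sigma / sqrt(1e5)
  n <- 1e5
  draws <- vapply(seq_len(n), function(i) reparameterize(dist2, seed = i),
                  numeric(3))
  sd_ <- exp(dist2$logvar / 2)
  expect_true(all(abs(rowMeans(draws) - dist2$mu) <= 3 * sd_ / sqrt(n)))
})

test_that("decode returns [0,1] features of the encoder input shape", {
  v <- tiny_vae()
  z <- rnorm(5)
  out <- decode(z, v)
  expect_equal(dim(out), c(16L, 16L, 2L))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(decode(z, v), decode(z, v))
  expect_error(decode(rnorm(4), v), "latent_dim")
})

test_that("KL closed form: zero at the prior, 0.5 at mu=1, monotone in |mu|", {
  expect_equal(kl_gaussian(latent_distribution(0, 0)), 0)
  expect_equal(kl_gaussian(latent_distribution(1, 0)), 0.5)
  expect_gt(kl_gaussian(latent_distribution(2, 0)),
            kl_gaussian(latent_distribution(1, 0)))
  set.seed(5)
  for (k in 1:10) {
    d <- latent_distribution(rnorm(4), rnorm(4))
    expect_gte(kl_gaussian(d), 0)
  }
})

test_that("KL closed form agrees with a 1e6-sample Monte-Carlo estimate", {
  # KL(q||p) = E_q[log q(z) - log p(z)] at mu = 1, sigma = 1
  set.seed(6)
  z <- rnorm(1e6, mean = 1, sd = 1)
  mc <- mean(dnorm(z, 1, 1, log = TRUE) - dnorm(z, 0, 1, log = TRUE))
  expect_lt(abs(kl_gaussian(latent_distribution(1, 0)) - mc), 1e-2)
})

test_that("composite loss reduces correctly and satisfies its decomposition", {
  tgt <- array(0.5, c(2, 2, 1))
  rec <- tgt + 0.1
  d10 <- latent_distribution(1, 0)
  lb <- composite_loss(rec, tgt, d10, loss_weights(1, 0, 1), mode = "mse")
  expect_equal(lb$total, 0.01 + 0.5, tolerance = 1e-12)
  # perfect reconstruction at the prior: total zero
  lb0 <- composite_loss(tgt, tgt, latent_distribution(0, 0),
                        loss_weights(1, 0.01, 1), mode = "mse")
  expect_equal(lb0$total, 0)
  # lambda2 = lambda3 = 0 reduces to pure MSE
  lbm <- composite_loss(rec, tgt, d10, loss_weights(2, 0, 0))
  expect_equal(lbm$total, 2 * 0.01, tolerance = 1e-12)
  # decomposition identity on random inputs
  set.seed(7)
  for (k in 1:5) {
    r <- array(runif(32), c(4, 4, 2))
    t_ <- array(runif(32), c(4, 4, 2))
    w <- loss_weights(runif(1), runif(1), runif(1))
    d <- latent_distribution(rnorm(3), rnorm(3))
    lb <- composite_loss(r, t_, d, w, mode = "mse",
                         extractor = perceptual_extractor(2L, seed = 3L))
    expect_equal(lb$total,
                 w$lambda1 * lb$recon + w$lambda2 * lb$perceptual +
                   w$lambda3 * lb$kl,
                 tolerance = 1e-9)
  }
})

test_that("bce mode computes pixelwise cross-entropy and rejects out-of-range input", {
  tgt <- array(c(0.2, 0.8, 0.5, 0.5), c(2, 2, 1))
  rec <- array(c(0.3, 0.7, 0.5, 0.5), c(2, 2, 1))
  lb <- composite_loss(rec, tgt, latent_distribution(0, 0),
                       loss_weights(1, 0, 1), mode = "bce")
  manual <- mean(-(tgt * log(rec) + (1 - tgt) * log(1 - rec)))
  expect_equal(lb$recon, manual, tolerance = 1e-9)
  expect_error(composite_loss(rec + 1, tgt, latent_distribution(0, 0),
                              loss_weights(), mode = "bce"), "\\[0, 1\\]")
})

test_that("composite-loss gradients agree with finite differences on a tiny VAE", {
  set.seed(8)
  v <- tiny_vae(seed = 3L)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  tg <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  eps <- matrix(rnorm(5), 1)
  lw <- loss_weights(1, 0.01, 1e-3)
  ext <- perceptual_extractor(2L, seed = 9L)
  res <- wavecal:::vae_loss_grads(v, x, tg, eps, lw, "mse", ext,
                                  training = TRUE)
  lossf <- function(vv) {
    wavecal:::vae_loss_grads(vv, x, tg, eps, lw, "mse", ext,
                             training = TRUE)$loss$total
  }
  worst <- 0
  for (part in c("enc", "head_mu", "head_logvar", "dec")) {
    for (i in seq_along(v[[part]])) {
      g <- res$grads[[part]][[i]]
      if (is.null(g)) next
      for (nm in names(g)) {
        for (k in seq_len(min(2L, length(v[[part]][[i]][[nm]])))) {
          h <- 1e-5
          vp <- v; vp[[part]][[i]][[nm]][k] <- vp[[part]][[i]][[nm]][k] + h
          vm <- v; vm[[part]][[i]][[nm]][k] <- vm[[part]][[i]][[nm]][k] - h
          fd <- (lossf(vp) - lossf(vm)) / (2 * h)
          an <- g[[nm]][k]
          worst <- max(worst, abs(fd - an) / max(1e-7, abs(fd) + abs(an)))
        }
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("500 seeded steps overfit a single phantom by >= 100x in recon MSE", {
  img <- generate_phantom(phantom_spec(32, 32, seed = 5L))
  model <- wavecal_model(image_shape = c(32L, 32L),
                         channels = c(16L, 32L, 64L, 64L),
                         latent_dim = 32L, fc_dim = 128L, dropout = 0,
                         lambda = loss_weights(1, 0.01, 1e-4), seed = 1L)
  f <- wavecal:::codec_features(model, img)
  x <- array(f$x, c(dim(f$x), 1L))
  tg <- array(f$target, c(dim(f$target), 1L))
  vae <- model$vae
  states <- lapply(vae[c("enc", "head_mu", "head_logvar", "dec")],
                   wavecal:::adam_init)
  init_mse <- NA
  wavecal:::with_seed(1L, {
    for (t in 1:500) {
      lr <- 1e-3 + 0.5 * (1e-2 - 1e-3) * (1 + cos(pi * (t - 1) / 500))
      eps <- matrix(rnorm(32), 1)
      res <- wavecal:::vae_loss_grads(vae, x, tg, eps, model$lambda, "mse",
                                      model$extractor, training = TRUE)
      if (t == 1) init_mse <- res$loss$recon
      for (p in names(states)) {
        vae[[p]] <- res$nets[[p]]
        st <- wavecal:::adam_step(vae[[p]], res$grads[[p]], states[[p]],
                                  t = t, lr = lr)
        vae[[p]] <- st$net
        states[[p]] <- st$state
      }
    }
  })
  vae <- wavecal:::vae_recalibrate_bn(vae, x)
  rec <- decode(encode(f$x, vae)$mu, vae)
  final_mse <- mean((rec - f$target)^2)
  expect_gte(init_mse / final_mse, 100)
})
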