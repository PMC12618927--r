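# Pixel-context extraction, the small feedforward regressors, and
# regression-R evaluation.

test_that("context counts match window geometry", {
  img <- rand_image(8, 8, seed = 1)
  ctx <- extract_contexts(img, predictor_spec("square3x3"))
  expect_equal(nrow(ctx$inputs), 36L)      # (8-2)^2 interior pixels
  expect_equal(ncol(ctx$inputs), 8L)
  expect_equal(ncol(ctx$targets), 1L)
  row16 <- rand_image(4, 16, seed = 2)
  ctx2 <- extract_contexts(row16, predictor_spec("linear1x8"))
  expect_equal(nrow(ctx2$inputs), 4L * 7L)  # 16 - 10 + 1 windows per row
  expect_equal(ncol(ctx2$targets), 2L)
})

test_that("contexts carry the right pixels", {
  img <- matrix(1:20, 4, 5)
  ctx <- extract_contexts(img, predictor_spec("square3x3"))
  # first interior pixel in row-major order is (2,2): value 6
  expect_equal(ctx$targets[1, 1], 6)
  expect_equal(ctx$inputs[1, ], c(1, 5, 9, 2, 10, 3, 7, 11))
  lin <- extract_contexts(rand_image(2, 10, seed = 3),
                          predictor_spec("linear1x8"))
  img2 <- rand_image(2, 10, seed = 3)
  expect_equal(lin$inputs[1, ], img2[1, 1:8])
  expect_equal(lin$targets[1, ], img2[1, 9:10])
  # constant image: all entries equal the constant
  cimg <- matrix(0.4, 6, 12)
  cc <- extract_contexts(cimg, predictor_spec("square3x3"))
  expect_true(all(cc$inputs == 0.4) && all(cc$targets == 0.4))
  expect_error(extract_contexts(matrix(1, 2, 2), predictor_spec("square3x3")),
               "3x3")
  expect_error(extract_contexts(matrix(1, 4, 9), predictor_spec("linear1x8")),
               "1x10")
})

test_that("a realizable linear map is learned to R >= 0.999", {
  set.seed(41)
  X <- matrix(runif(500 * 8), 500, 8)
  Y <- X[, 3, drop = FALSE]
  fit <- train_predictor(X, Y, predictor_spec("square3x3", seed = 2L),
                         epochs = 2000L, lr = 0.01)
  expect_gte(fit$report$R, 0.999)
})

test_that("zero-variance targets raise a flagged error, never NaN", {
  cimg <- matrix(0.5, 8, 8)
  ctx <- extract_contexts(cimg, predictor_spec("square3x3"))
  expect_error(train_predictor(ctx$inputs, ctx$targets,
                               predictor_spec("square3x3")),
               "zero-variance")
})

test_that("training is seeded-deterministic and predictions are clipped", {
  img <- generate_phantom(phantom_spec(16, 16, noise_sigma = 0, seed = 3L))
  ctx <- extract_contexts(img, predictor_spec("square3x3"))
  sp <- predictor_spec("square3x3", seed = 5L)
  f1 <- train_predictor(ctx$inputs, ctx$targets, sp, epochs = 50L)
  f2 <- train_predictor(ctx$inputs, ctx$targets, sp, epochs = 50L)
  expect_identical(f1$net, f2$net)
  p <- predict(f1, ctx$inputs)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict(f1, matrix(1, 2, 7)), "width 8")
})

test_that("zero-weight network predicts the output bias", {
  sp <- predictor_spec("square3x3", seed = 1L)
  fit <- train_predictor(matrix(runif(160), 20, 8),
                         matrix(runif(20), 20, 1), sp, epochs = 1L)
  for (i in seq_along(fit$net)) {
    if (!is.null(fit$net[[i]]$W)) {
      fit$net[[i]]$W[] <- 0
      fit$net[[i]]$b[] <- 0
    }
  }
  nl <- length(fit$net)
  fit$net[[nl]]$b <- 0.3
  expect_true(all(predict(fit, matrix(runif(16), 2, 8)) == 0.3))
})

test_that("one-hidden-unit tanh network matches manual arithmetic", {
  net <- list(wavecal:::nn_dense(8L, 1L), wavecal:::nn_tanh(),
              wavecal:::nn_dense(1L, 1L))
  net[[1]]$W <- matrix(seq(0.1, 0.8, by = 0.1), 8, 1)
  net[[1]]$b <- 0.05
  net[[3]]$W <- matrix(2)
  net[[3]]$b <- -0.1
  x <- matrix(seq(0.1, 0.8, by = 0.1), 1, 8)
  manual <- 2 * tanh(sum(x * seq(0.1, 0.8, by = 0.1)) + 0.05) - 0.1
  expect_equal(wavecal:::nn_forward(net, x)$out[1, 1], manual,
               tolerance = 1e-12)
})

test_that("full-batch gradient descent with a small step never increases the loss", {
  set.seed(44)
  X <- matrix(runif(30 * 8), 30, 8)
  Y <- matrix(rowMeans(X) + rnorm(30, sd = 0.01), 30, 1)
  fit <- train_predictor(X, Y, predictor_spec("square3x3", seed = 3L),
                         epochs = 200L, lr = 0.005, optimizer = "gd")
  expect_true(all(diff(fit$loss_history) <= 1e-12))
})

test_that("regression_r matches the Pearson formula and its invariances", {
  expect_equal(regression_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(regression_r(c(1, 2, 3), c(5, 4, 3)), -1)
  r <- regression_r(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r, 0.981981, tolerance = 1e-6)
  # positive affine invariance
  expect_equal(regression_r(2 * c(1, 2, 3) + 7, c(1, 2, 4)), r)
  expect_error(regression_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(regression_r(1, 2), "at least two")
})

test_that("square3x3 prediction on smooth noise-free phantoms reaches R >= 0.95", {
  ctx <- lapply(9:10, function(s) {
    img <- generate_phantom(phantom_spec(48, 48, noise_sigma = 0, seed = s))
    extract_contexts(img, predictor_spec("square3x3"))
  })
  inputs <- do.call(rbind, lapply(ctx, `[[`, "inputs"))
  targets <- do.call(rbind, lapply(ctx, `[[`, "targets"))
  fit <- train_predictor(inputs, targets,
                         predictor_spec("square3x3", seed = 1L),
                         epochs = 1000L, lr = 0.03)
  expect_gte(fit$report$R, 0.95)
})
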