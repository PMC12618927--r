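# Scaled dot-product and multi-head cross-attention algebra.

test_that("attention weights are row-stochastic and outputs convex in V", {
  set.seed(10)
  for (k in 1:5) {
    Q <- matrix(rnorm(12), 4, 3)
    K <- matrix(rnorm(18), 6, 3)
    V <- matrix(rnorm(12), 6, 2)
    r <- scaled_dot_attention(Q, K, V, return_weights = TRUE)
    expect_true(all(r$weights >= 0))
    expect_lt(max(abs(rowSums(r$weights) - 1)), 1e-12)
    expect_true(all(r$out <= matrix(apply(V, 2, max), 4, 2, byrow = TRUE) + 1e-12))
    expect_true(all(r$out >= matrix(apply(V, 2, min), 4, 2, byrow = TRUE) - 1e-12))
  }
})

test_that("zero keys give uniform weights; a single key/value returns V", {
  Q <- matrix(rnorm(6), 2, 3)
  V <- matrix(1:8, 4, 2)
  out <- scaled_dot_attention(Q, matrix(0, 4, 3), V)
  expect_equal(out, matrix(colMeans(V), 2, 2, byrow = TRUE), tolerance = 1e-12)
  out1 <- scaled_dot_attention(Q, matrix(c(1, 2, 3), 1, 3), matrix(c(5, 7), 1, 2))
  expect_equal(out1, matrix(c(5, 7), 2, 2, byrow = TRUE))
})

test_that("scalar example matches the hand-computed softmax", {
  r <- scaled_dot_attention(matrix(2), matrix(c(0, 1)), matrix(c(0, 1)),
                            return_weights = TRUE)
  expect_equal(as.vector(r$weights),
               c(1 / (1 + exp(2)), exp(2) / (1 + exp(2))), tolerance = 1e-15)
  expect_equal(r$out[1, 1], exp(2) / (1 + exp(2)), tolerance = 1e-15)
})

test_that("scaling Q and K by c scales logits by c^2/sqrt(d_k) as per formula", {
  set.seed(11)
  Q <- matrix(rnorm(9), 3, 3)
  K <- matrix(rnorm(9), 3, 3)
  V <- diag(3)
  cc <- 1.7
  w1 <- scaled_dot_attention(Q, K, V, return_weights = TRUE)$weights
  w2 <- scaled_dot_attention(cc * Q, cc * K, V, return_weights = TRUE)$weights
  logits <- Q %*% t(K) / sqrt(3)
  soft <- function(L) t(apply(L, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(w1, soft(logits), tolerance = 1e-12)
  expect_equal(w2, soft(cc^2 * logits), tolerance = 1e-12)
})

test_that("multi_head with one head and identity projections reduces to scaled_dot_attention", {
  set.seed(12)
  X <- matrix(rnorm(8), 2, 4)
  Y <- matrix(rnorm(12), 3, 4)
  proj <- list(W_Q = diag(4), W_K = diag(4), W_V = diag(4), W_O = diag(4))
  out <- multi_head(X, Y, multi_head_config(1L, 4L), proj)
  expect_equal(out, scaled_dot_attention(X, Y, Y), tolerance = 1e-14)
})

test_that("multi_head is invariant to permuting key/value rows together", {
  set.seed(13)
  cfg <- multi_head_config(2L, 4L)
  proj <- attention_projections(3L, 5L, cfg, d_out = 5L, seed = 4L)
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(30), 6, 5)
  perm <- sample(6)
  expect_lt(max(abs(multi_head(X, Y, cfg, proj) -
                    multi_head(X, Y[perm, ], cfg, proj))), 1e-10)
  # and equivariant over query tokens
  qperm <- sample(4)
  expect_equal(multi_head(X[qperm, ], Y, cfg, proj),
               multi_head(X, Y, cfg, proj)[qperm, ], tolerance = 1e-12)
})

test_that("a seeded 2-token instance matches a straight-line trace of the equations", {
  set.seed(14)
  cfg <- multi_head_config(2L, 4L)
  proj <- attention_projections(2L, 3L, cfg, d_out = 3L, seed = 21L)
  X <- matrix(rnorm(4), 2, 2)
  Y <- matrix(rnorm(6), 2, 3)
  expect_equal(multi_head(X, Y, cfg, proj),
               multi_head_trace(X, Y, 2L, proj), tolerance = 1e-12)
})

test_that("embed_dim must divide by the head count", {
  expect_error(multi_head_config(3L, 64L), "divisible")
})

test_that("cal_block: zero details stay zero through the residual path", {
  w <- cal_weights(multi_head_config(2L, 8L), seed = 2L)
  ll <- rand_image(4, 4, seed = 30)
  hf0 <- array(0, c(4, 4, 3))
  out <- cal_block(ll, hf0, w)
  expect_equal(out, hf0)   # V = W_V * 0 = 0, plus zero residual
})

test_that("cal_block is deterministic and equals the manual tokenize/attend/untokenize composition", {
  w <- cal_weights(multi_head_config(4L, 8L), seed = 5L)
  ll <- rand_image(4, 4, seed = 31)
  hf <- array(rand_image(4, 12, seed = 32), c(4, 4, 3))
  out1 <- cal_block(ll, hf, w)
  expect_identical(out1, cal_block(ll, hf, w))
  X <- matrix(as.vector(ll), 16, 1)
  Y <- matrix(hf, 16, 3)
  manual <- array(Y + multi_head_trace(X, Y, 4L, w$projections), c(4, 4, 3))
  expect_equal(out1, manual, tolerance = 1e-12)
})

test_that("cal_block rejects mismatched spatial shapes", {
  w <- cal_weights(seed = 1L)
  expect_error(cal_block(rand_image(4, 4, seed = 1), array(0, c(4, 6, 3)), w),
               "matching")
})
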