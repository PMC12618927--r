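# Shared fixtures and independent oracles used across test files.

rand_image <- function(m, n, seed) {
  set.seed(seed)
  matrix(runif(m * n), m, n)
}

# Brute-force mean SSIM: explicit loop over every fully-interior window
# position, weighted moments computed directly from the window pixels.
ssim_bruteforce <- function(x, y, L = 255, K1 = 0.01, K2 = 0.03, size = 11L,
                            sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w <- w / sum(w)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  m <- nrow(x) - size + 1L
  n <- ncol(x) - size + 1L
  vals <- numeric(m * n)
  k <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      wx <- x[i:(i + size - 1L), j:(j + size - 1L)]
      wy <- y[i:(i + size - 1L), j:(j + size - 1L)]
      mx <- sum(w * wx); my <- sum(w * wy)
      vx <- sum(w * wx^2) - mx^2
      vy <- sum(w * wy^2) - my^2
      cxy <- sum(w * wx * wy) - mx * my
      k <- k + 1L
      vals[k] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  }
  mean(vals)
}

# Orthonormal 2-D Haar analysis of a 2x2 block as an explicit 4x4 matrix
# acting on the flattened block (order: x11, x21, x12, x22). Rows: LL, LH
# (horizontal difference), HL (vertical difference), HH (diagonal).
haar2x2_matrix <- function() {
  matrix(c( 1,  1,  1,  1,
            1,  1, -1, -1,
            1, -1,  1, -1,
            1, -1, -1,  1) / 2,
         nrow = 4, byrow = TRUE)
}

# straight-line recomputation of multi-head cross-attention for the derived
# examples (independent of the package implementation)
multi_head_trace <- function(X, Y, h, proj) {
  Q <- X %*% proj$W_Q
  K <- Y %*% proj$W_K
  V <- Y %*% proj$W_V
  e <- ncol(Q)
  dh <- e / h
  heads <- list()
  for (i in seq_len(h)) {
    sel <- ((i - 1) * dh + 1):(i * dh)
    logits <- Q[, sel, drop = FALSE] %*% t(K[, sel, drop = FALSE]) / sqrt(dh)
    A <- t(apply(logits, 1, function(r) {
      er <- exp(r - max(r))
      er / sum(er)
    }))
    if (nrow(logits) == 1L) A <- matrix(A, 1L)
    heads[[i]] <- A %*% V[, sel, drop = FALSE]
  }
  do.call(cbind, heads) %*% proj$W_O
}
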