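# Trainable 3x3 post-reconstruction spatial filter, optimized by
# gradient descent (Adam) on an image-quality objective.

#' Construct a 3x3 filter kernel
#'
#' @param weights 3x3 numeric matrix of finite entries.
#' @param bias Scalar bias.
#' @return A `filter_kernel` object.
#' @export
filter_kernel <- function(weights, bias = 0) {
  if (!is.matrix(weights) || !identical(dim(weights), c(3L, 3L)) ||
      any(!is.finite(weights)) || !is.finite(bias)) {
    stop("`weights` must be a finite 3x3 matrix and `bias` finite",
         call. = FALSE)
  }
  structure(list(weights = weights, bias = bias), class = "filter_kernel")
}

#' Identity kernel (center 1, rest 0, zero bias)
#' @return A `filter_kernel` that leaves interior values unchanged.
#' @export
identity_kernel <- function() {
  w <- matrix(0, 3, 3)
  w[2, 2] <- 1
  filter_kernel(w)
}

reflect_pad1 <- function(x) {
  m <- nrow(x); n <- ncol(x)
  x[c(1L, 1:m, m), c(1L, 1:n, n)]
}

# cross-correlation + bias, before clipping
filter_raw <- function(image, kernel) {
  p <- reflect_pad1(image)
  m <- nrow(image); n <- ncol(image)
  out <- matrix(kernel$bias, m, n)
  for (a in 1:3) {
    for (b in 1:3) {
      if (kernel$weights[a, b] != 0) {
        out <- out + kernel$weights[a, b] *
          p[a:(a + m - 1L), b:(b + n - 1L)]
      }
    }
  }
  out
}

#' Apply a 3x3 spatial filter to an image
#'
#' 2-D cross-correlation with symmetric (edge-replicating) reflection
#' padding, plus bias, clipped to `[0, 1]`. Same-shape output; linear in the
#' kernel wherever the clipping is inactive.
#'
#' @param image Numeric matrix (at least 3x3) in `[0, 1]`.
#' @param kernel A [filter_kernel()].
#' @return Filtered image matrix.
#' @export
apply_filter <- function(image, kernel) {
  stopifnot_matrix(image)
  if (nrow(image) < 3L || ncol(image) < 3L) {
    stop("image must be at least 3x3", call. = FALSE)
  }
  pmin(pmax(filter_raw(image, kernel), 0), 1)
}

#' Objective weights for filter training
#'
#' @param w_mse Weight on the MSE term (0-255 scale).
#' @param w_ssim Weight on the `1 - SSIM` term.
#' @return A named numeric vector.
#' @export
filter_objective_weights <- function(w_mse = 1, w_ssim = 0) {
  if (w_mse < 0 || w_ssim < 0) {
    stop("objective weights must be non-negative", call. = FALSE)
  }
  c(w_mse = w_mse, w_ssim = w_ssim)
}

#' Filter-quality objective (lower is better)
#'
#' `w_mse * MSE + w_ssim * (1 - SSIM)`, both metrics computed on the 0-255
#' scale from `[0, 1]` inputs.
#'
#' @param filtered,original Numeric matrices in `[0, 1]` of equal shape.
#' @param weights From [filter_objective_weights()].
#' @return Scalar objective value.
#' @export
objective_value <- function(filtered, original,
                            weights = filter_objective_weights()) {
  v <- weights[["w_mse"]] * mse(filtered * 255, original * 255)
  if (weights[["w_ssim"]] > 0) {
    v <- v + weights[["w_ssim"]] * (1 - ssim(filtered * 255, original * 255))
  }
  v
}

mean_objective <- function(kernel, pairs, weights) {
  mean(vapply(pairs, function(p) {
    objective_value(apply_filter(p$reconstructed, kernel), p$original, weights)
  }, numeric(1)))
}

#' Train the spatial filter on (reconstructed, original) pairs
#'
#' Adam minimization of the weighted objective, starting from an identity
#' kernel plus small seeded noise. The returned kernel is the best iterate
#' seen, so its objective never exceeds the initial kernel's.
#'
#' @param pairs List of `list(reconstructed = ..., original = ...)` image
#'   pairs in `[0, 1]`.
#' @param weights From [filter_objective_weights()]. When `w_ssim > 0` the
#'   SSIM term's gradient is taken by central finite differences (10
#'   parameters); the MSE term's gradient is analytic.
#' @param epochs Number of Adam steps.
#' @param lr Learning rate.
#' @param seed Integer seed for the initialization noise.
#' @return `list(kernel, objective, initial_objective, history)`.
#' @export
train_filter <- function(pairs, weights = filter_objective_weights(),
                         epochs = 150L, lr = 5e-3, seed = 1L) {
  if (length(pairs) < 1L) stop("need at least one training pair", call. = FALSE)
  if (mean_objective(identity_kernel(), pairs, weights) == 0) {
    # already perfect at the identity initialization: training is a no-op
    return(list(kernel = identity_kernel(), objective = 0,
                initial_objective = 0, history = numeric(0)))
  }
  k0 <- identity_kernel()
  k0$weights <- k0$weights +
    matrix(with_seed(seed, stats::rnorm(9, sd = 0.01)), 3, 3)
  obj0 <- mean_objective(k0, pairs, weights)
  theta <- c(as.vector(k0$weights), k0$bias)
  as_kernel <- function(th) filter_kernel(matrix(th[1:9], 3, 3), th[10])
  best_theta <- theta
  best_obj <- obj0
  m_ <- numeric(10); v_ <- numeric(10)
  history <- numeric(epochs)
  npix <- vapply(pairs, function(p) length(p$original), numeric(1))
  for (e in seq_len(epochs)) {
    kern <- as_kernel(theta)
    grad <- numeric(10)
    for (ip in seq_along(pairs)) {
      p <- pairs[[ip]]
      raw <- filter_raw(p$reconstructed, kern)
      f <- pmin(pmax(raw, 0), 1)
      active <- raw > 0 & raw < 1
      dout <- weights[["w_mse"]] * 255^2 * 2 * (f - p$original) /
        npix[ip] * active / length(pairs)
      pad <- reflect_pad1(p$reconstructed)
      mi <- nrow(f); ni <- ncol(f)
      # grad[1:9] is column-major over the 3x3 weights; grad[10] is the bias
      for (col in 1:3) {
        for (row in 1:3) {
          grad[(col - 1L) * 3L + row] <- grad[(col - 1L) * 3L + row] +
            sum(dout * pad[row:(row + mi - 1L), col:(col + ni - 1L)])
        }
      }
      grad[10] <- grad[10] + sum(dout)
    }
    if (weights[["w_ssim"]] > 0) {
      h <- 1e-4
      for (j in 1:10) {
        tp <- theta; tm <- theta
        tp[j] <- tp[j] + h
        tm[j] <- tm[j] - h
        op <- mean(vapply(pairs, function(p) {
          1 - ssim(apply_filter(p$reconstructed, as_kernel(tp)) * 255,
                   p$original * 255)
        }, numeric(1)))
        om <- mean(vapply(pairs, function(p) {
          1 - ssim(apply_filter(p$reconstructed, as_kernel(tm)) * 255,
                   p$original * 255)
        }, numeric(1)))
        grad[j] <- grad[j] + weights[["w_ssim"]] * (op - om) / (2 * h)
      }
    }
    m_ <- 0.9 * m_ + 0.1 * grad
    v_ <- 0.999 * v_ + 0.001 * grad^2
    theta <- theta - lr * (m_ / (1 - 0.9^e)) /
      (sqrt(v_ / (1 - 0.999^e)) + 1e-8)
    obj <- mean_objective(as_kernel(theta), pairs, weights)
    history[e] <- obj
    if (obj < best_obj) {
      best_obj <- obj
      best_theta <- theta
    }
  }
  list(kernel = as_kernel(best_theta), objective = best_obj,
       initial_objective = obj0, history = history)
}
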