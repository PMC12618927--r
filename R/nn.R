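# Minimal feedforward network machinery: layers with analytic forward and
# backward passes, Xavier-normal initialization, and an Adam optimizer.
# Activations are stored as (H, W, C, N) arrays for spatial layers and
# (N, D) matrices for dense layers. Every backward pass is verified against
# finite differences in the test suite.

nn_conv <- function(c_in, c_out) {
  list(type = "conv", c_in = c_in, c_out = c_out, W = NULL, b = NULL)
}

# transposed convolution with stride 2: zero-insertion upsampling (x2)
# followed by a 3x3 convolution
nn_tconv <- function(c_in, c_out) {
  list(type = "tconv", c_in = c_in, c_out = c_out, W = NULL, b = NULL)
}

nn_dense <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out, W = NULL, b = NULL)
}

nn_bn <- function(c) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c),
       momentum = 0.1, eps = 1e-5)
}

nn_relu <- function() list(type = "relu")
nn_sigmoid <- function() list(type = "sigmoid")
nn_tanh <- function() list(type = "tanh")
nn_pool <- function() list(type = "pool")
nn_flatten <- function() list(type = "flatten")
nn_reshape <- function(h, w, c) list(type = "reshape", dims = c(h, w, c))
nn_dropout <- function(rate) list(type = "dropout", rate = rate)

#' Initialize network weights (Xavier normal), seeded
#'
#' @param net List of layer specs.
#' @param seed Integer seed.
#' @return The network with weights filled in.
#' @keywords internal
nn_init <- function(net, seed) {
  with_seed(seed, {
    for (i in seq_along(net)) {
      l <- net[[i]]
      if (l$type %in% c("conv", "tconv")) {
        fan_in <- 9 * l$c_in
        fan_out <- 9 * l$c_out
        sd <- sqrt(2 / (fan_in + fan_out))
        net[[i]]$W <- matrix(stats::rnorm(fan_in * l$c_out, sd = sd),
                             fan_in, l$c_out)
        net[[i]]$b <- rep(0, l$c_out)
      } else if (l$type == "dense") {
        sd <- sqrt(2 / (l$d_in + l$d_out))
        net[[i]]$W <- matrix(stats::rnorm(l$d_in * l$d_out, sd = sd),
                             l$d_in, l$d_out)
        net[[i]]$b <- rep(0, l$d_out)
      }
    }
    net
  })
}

# ---- convolution via im2col ------------------------------------------------

# patch matrix: rows ordered (i, j, n), columns ordered (offset within 3x3
# [column-major: di fastest], then channel)
im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- array(0, c(H + 2L, W + 2L, C, N))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  P <- matrix(0, H * W * N, 9L * C)
  for (o in 1:9) {
    di <- (o - 1L) %% 3L
    dj <- (o - 1L) %/% 3L
    slab <- xp[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
    dim(slab) <- c(H * W, C, N)
    for (c in seq_len(C)) {
      P[, (c - 1L) * 9L + o] <- slab[, c, ]
    }
  }
  P
}

col2im3 <- function(dP, H, W, C, N) {
  dxp <- array(0, c(H + 2L, W + 2L, C, N))
  for (o in 1:9) {
    di <- (o - 1L) %% 3L
    dj <- (o - 1L) %/% 3L
    for (c in seq_len(C)) {
      slab <- array(dP[, (c - 1L) * 9L + o], c(H, W, 1L, N))
      dxp[di + seq_len(H), dj + seq_len(W), c, ] <-
        dxp[di + seq_len(H), dj + seq_len(W), c, , drop = FALSE] + slab
    }
  }
  dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

conv_forward <- function(x, W, b) {
  d <- dim(x)
  P <- im2col3(x)
  out_mat <- P %*% W
  out_mat <- sweep(out_mat, 2, b, "+")
  c_out <- ncol(W)
  out <- array(out_mat, c(d[1], d[2], d[4], c_out))
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, cache = list(P = P, W = W, dims = d))
}

conv_backward <- function(dout, cache) {
  d <- cache$dims
  dmat <- aperm(dout, c(1, 2, 4, 3))
  dim(dmat) <- c(d[1] * d[2] * d[4], dim(dout)[3])
  dW <- crossprod(cache$P, dmat)
  db <- colSums(dmat)
  dP <- tcrossprod(dmat, cache$W)
  dx <- col2im3(dP, d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW, db = db)
}

upsample2_zero <- function(x) {
  d <- dim(x)
  up <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  up[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), , ] <- x
  up
}

# ---- 2x2 max pooling -------------------------------------------------------

pool_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  s <- list(x[ro, co, , , drop = FALSE], x[re, co, , , drop = FALSE],
            x[ro, ce, , , drop = FALSE], x[re, ce, , , drop = FALSE])
  out <- s[[1]]
  arg <- array(1L, dim(out))
  for (k in 2:4) {
    better <- s[[k]] > out
    out[better] <- s[[k]][better]
    arg[better] <- k
  }
  list(out = out, cache = list(arg = arg, dims = d))
}

pool_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  idx <- list(list(ro, co), list(re, co), list(ro, ce), list(re, ce))
  for (k in 1:4) {
    g <- dout
    g[cache$arg != k] <- 0
    dx[idx[[k]][[1]], idx[[k]][[2]], , ] <-
      dx[idx[[k]][[1]], idx[[k]][[2]], , , drop = FALSE] + g
  }
  dx
}

# ---- batch normalization (per channel, dim 3) ------------------------------

bn_forward <- function(x, l, training) {
  if (training) {
    mu <- apply(x, 3, mean)
    xc <- sweep(x, 3, mu)
    v <- apply(xc^2, 3, mean)
  } else {
    mu <- l$run_mean
    v <- l$run_var
    xc <- sweep(x, 3, mu)
  }
  inv_sd <- 1 / sqrt(v + l$eps)
  xhat <- sweep(xc, 3, inv_sd, "*")
  out <- sweep(sweep(xhat, 3, l$gamma, "*"), 3, l$beta, "+")
  list(out = out,
       cache = list(xhat = xhat, xc = xc, inv_sd = inv_sd, training = training,
                    gamma = l$gamma),
       batch_mean = mu, batch_var = v)
}

bn_backward <- function(dout, cache) {
  dgamma <- apply(dout * cache$xhat, 3, sum)
  dbeta <- apply(dout, 3, sum)
  d <- dim(dout)
  M <- d[1] * d[2] * d[4]
  dxhat <- sweep(dout, 3, cache$gamma, "*")
  if (!cache$training) {
    dx <- sweep(dxhat, 3, cache$inv_sd, "*")
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  sum_dxhat <- apply(dxhat, 3, sum)
  sum_dxhat_xhat <- apply(dxhat * cache$xhat, 3, sum)
  t1 <- sweep(dxhat, 3, sum_dxhat / M)
  t2 <- sweep(cache$xhat, 3, sum_dxhat_xhat / M, "*")
  dx <- sweep(t1 - t2, 3, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- network forward / backward --------------------------------------------

#' Forward pass through a layer list
#'
#' @param net Layer list (initialized).
#' @param x Input array `(H, W, C, N)` or matrix `(N, D)`.
#' @param training Logical; batch-norm uses batch statistics and dropout is
#'   active only when `TRUE` (dropout draws from the current RNG stream).
#' @return `list(out, caches, net)`; `net` carries updated batch-norm running
#'   statistics when `training = TRUE`.
#' @keywords internal
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    l <- net[[i]]
    r <- switch(
      l$type,
      conv = conv_forward(x, l$W, l$b),
      tconv = {
        up <- upsample2_zero(x)
        rr <- conv_forward(up, l$W, l$b)
        rr$cache$tconv_in_dims <- dim(x)
        rr
      },
      dense = {
        out <- sweep(x %*% l$W, 2, l$b, "+")
        list(out = out, cache = list(x = x, W = l$W))
      },
      bn = {
        rr <- bn_forward(x, l, training)
        if (training) {
          mom <- l$momentum
          net[[i]]$run_mean <- (1 - mom) * l$run_mean + mom * rr$batch_mean
          net[[i]]$run_var <- (1 - mom) * l$run_var + mom * rr$batch_var
        }
        rr
      },
      relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
      sigmoid = {
        s <- 1 / (1 + exp(-x))
        list(out = s, cache = list(s = s))
      },
      tanh = {
        s <- tanh(x)
        list(out = s, cache = list(s = s))
      },
      pool = pool_forward(x),
      flatten = {
        d <- dim(x)
        out <- t(matrix(x, prod(d[1:3]), d[4]))
        list(out = out, cache = list(dims = d))
      },
      reshape = {
        out <- array(t(x), c(l$dims, nrow(x)))
        list(out = out, cache = list(n = nrow(x), d_in = ncol(x)))
      },
      dropout = {
        if (training && l$rate > 0) {
          keep <- 1 - l$rate
          mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
          list(out = x * mask, cache = list(mask = mask))
        } else {
          list(out = x, cache = list(mask = NULL))
        }
      },
      stop("unknown layer type: ", l$type)
    )
    x <- r$out
    if (any(!is.finite(x))) {
      stop(sprintf("non-finite activations after layer %d (%s)", i, l$type),
           call. = FALSE)
    }
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches, net = net)
}

#' Backward pass through a layer list
#'
#' @param net Layer list.
#' @param caches Caches from [nn_forward()].
#' @param dout Gradient of the loss w.r.t. the network output.
#' @return `list(dx, grads)`; `grads[[i]]` holds the parameter gradients of
#'   layer `i` (or `NULL`).
#' @keywords internal
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    l <- net[[i]]
    ca <- caches[[i]]
    if (l$type == "conv") {
      r <- conv_backward(dout, ca)
      grads[[i]] <- list(W = r$dW, b = r$db)
      dout <- r$dx
    } else if (l$type == "tconv") {
      r <- conv_backward(dout, ca)
      grads[[i]] <- list(W = r$dW, b = r$db)
      d <- ca$tconv_in_dims
      dout <- r$dx[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), , ,
                   drop = FALSE]
    } else if (l$type == "dense") {
      grads[[i]] <- list(W = crossprod(ca$x, dout), b = colSums(dout))
      dout <- tcrossprod(dout, ca$W)
    } else if (l$type == "bn") {
      r <- bn_backward(dout, ca)
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dout <- r$dx
    } else if (l$type == "relu") {
      dout <- dout * ca$mask
    } else if (l$type == "sigmoid") {
      dout <- dout * ca$s * (1 - ca$s)
    } else if (l$type == "tanh") {
      dout <- dout * (1 - ca$s^2)
    } else if (l$type == "pool") {
      dout <- pool_backward(dout, ca)
    } else if (l$type == "flatten") {
      dout <- array(t(dout), ca$dims)
    } else if (l$type == "reshape") {
      dout <- t(matrix(dout, length(dout) / ca$n, ca$n))
    } else if (l$type == "dropout") {
      if (!is.null(ca$mask)) dout <- dout * ca$mask
    }
  }
  list(dx = dout, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

.param_names <- function(l) {
  switch(l$type,
         conv = c("W", "b"), tconv = c("W", "b"), dense = c("W", "b"),
         bn = c("gamma", "beta"), character(0))
}

adam_init <- function(net) {
  lapply(net, function(l) {
    nms <- .param_names(l)
    if (length(nms) == 0) return(NULL)
    st <- list()
    for (nm in nms) {
      st[[nm]] <- list(m = l[[nm]] * 0, v = l[[nm]] * 0)
    }
    st
  })
}

adam_step <- function(net, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net[[i]][[nm]] <- net[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}
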