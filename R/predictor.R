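# Neural pixel-context prediction: causal-context extraction, small
# feedforward regressors (tanh hidden layers, linear output), and
# regression-R evaluation. Standalone subsystem; not wired into the default
# codec bitstream.

#' Specify a pixel predictor
#'
#' Two context geometries are supported: `"square3x3"` uses the 8 pixels
#' surrounding an interior pixel to predict its center (hidden stack
#' 20-18-5, output width 1); `"linear1x8"` uses 8 consecutive pixels of a row
#' to predict the next two (hidden stack 20-18-5, output width 2).
#'
#' @param window `"square3x3"` or `"linear1x8"`.
#' @param hidden Hidden layer widths (default `c(20, 18, 5)`).
#' @param seed Integer seed for initialization and the held-out split.
#' @return A `predictor_spec` object.
#' @export
predictor_spec <- function(window = c("square3x3", "linear1x8"),
                           hidden = c(20L, 18L, 5L), seed = 1L) {
  window <- match.arg(window)
  structure(list(window = window, hidden = as.integer(hidden),
                 out_width = if (window == "square3x3") 1L else 2L,
                 seed = as.integer(seed)),
            class = "predictor_spec")
}

#' Extract prediction contexts from an image
#'
#' `square3x3`: one sample per interior pixel; the inputs are the 8
#' surrounding pixels in row-major order (NW, N, NE, W, E, SW, S, SE) and the
#' target is the center. `linear1x8`: within each row, every run of 10
#' consecutive pixels yields the first 8 as inputs and the trailing 2 as
#' targets. Samples are emitted in row-major scan order.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param spec A [predictor_spec()].
#' @return `list(inputs, targets)`: an `n x 8` input matrix and an
#'   `n x {1|2}` target matrix.
#' @export
extract_contexts <- function(image, spec) {
  stopifnot_matrix(image)
  m <- nrow(image); n <- ncol(image)
  if (spec$window == "square3x3") {
    if (m < 3L || n < 3L) {
      stop("image smaller than the 3x3 window", call. = FALSE)
    }
    ri <- 2:(m - 1L); ci <- 2:(n - 1L)
    offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
    rowmaj <- function(M) as.vector(t(M))
    inputs <- vapply(offs, function(o) {
      rowmaj(image[ri + o[1], ci + o[2], drop = FALSE])
    }, numeric(length(ri) * length(ci)))
    targets <- matrix(rowmaj(image[ri, ci, drop = FALSE]), ncol = 1L)
  } else {
    if (n < 10L) {
      stop("rows shorter than the 1x10 context run", call. = FALSE)
    }
    nwin <- n - 9L
    rowmaj <- function(M) as.vector(t(M))
    cols <- function(k) rowmaj(image[, (1L + k):(nwin + k), drop = FALSE])
    inputs <- vapply(0:7, cols, numeric(m * nwin))
    targets <- cbind(cols(8L), cols(9L))
  }
  list(inputs = inputs, targets = targets)
}

build_predictor_net <- function(spec) {
  widths <- c(8L, spec$hidden, spec$out_width)
  net <- list()
  for (i in seq_len(length(widths) - 1L)) {
    net <- c(net, list(nn_dense(widths[i], widths[i + 1L])))
    if (i < length(widths) - 1L) net <- c(net, list(nn_tanh()))
  }
  net
}

#' Train a pixel predictor
#'
#' Seeded deterministic full-batch training on an 85% split; the regression
#' report carries the final training MSE and the Pearson correlation `R`
#' between predictions and targets on the held-out 15% (both output columns
#' pooled for the 1x8 model).
#'
#' @param inputs `n x 8` input matrix (values in `[0, 1]`).
#' @param targets `n x {1|2}` target matrix.
#' @param spec A [predictor_spec()].
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param optimizer `"adam"` (default) or plain `"gd"`.
#' @return A `pixel_predictor`: fields `net`, `spec`, `report` (with `R`,
#'   `mse`, `n_samples`) and `loss_history`.
#' @export
train_predictor <- function(inputs, targets, spec, epochs = 400L, lr = 0.01,
                            optimizer = c("adam", "gd")) {
  optimizer <- match.arg(optimizer)
  if (!is.matrix(targets)) targets <- as.matrix(targets)
  n <- nrow(inputs)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  if (ncol(targets) != spec$out_width) {
    stop("target width does not match the predictor spec", call. = FALSE)
  }
  if (stats::var(as.vector(targets)) == 0) {
    stop("zero-variance targets: regression R is undefined", call. = FALSE)
  }
  perm <- with_seed(spec$seed, sample.int(n))
  n_hold <- max(1L, as.integer(round_half_away(0.15 * n)))
  hold <- perm[seq_len(n_hold)]
  tr <- perm[-seq_len(n_hold)]
  Xtr <- inputs[tr, , drop = FALSE]
  Ytr <- targets[tr, , drop = FALSE]

  net <- nn_init(build_predictor_net(spec), spec$seed)
  state <- adam_init(net)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    fw <- nn_forward(net, Xtr, training = FALSE)
    resid <- fw$out - Ytr
    history[e] <- mean(resid^2)
    bw <- nn_backward(net, fw$caches, 2 * resid / length(resid))
    if (optimizer == "adam") {
      st <- adam_step(net, bw$grads, state, t = e, lr = lr)
      net <- st$net
      state <- st$state
    } else {
      for (i in seq_along(net)) {
        g <- bw$grads[[i]]
        if (is.null(g)) next
        for (nm in names(g)) net[[i]][[nm]] <- net[[i]][[nm]] - lr * g[[nm]]
      }
    }
  }
  pred_hold <- nn_forward(net, inputs[hold, , drop = FALSE],
                          training = FALSE)$out
  final_mse <- mean((nn_forward(net, Xtr, training = FALSE)$out - Ytr)^2)
  structure(
    list(net = net, spec = spec,
         report = list(R = regression_r(pred_hold, targets[hold, , drop = FALSE]),
                       mse = final_mse, n_samples = n),
         loss_history = history),
    class = "pixel_predictor"
  )
}

#' Predict pixels from contexts
#'
#' Deterministic forward pass; outputs are clipped to `[0, 1]`.
#'
#' @param object A `pixel_predictor`.
#' @param inputs `n x 8` context matrix.
#' @param ... Unused.
#' @return `n x {1|2}` prediction matrix.
#' @export
predict.pixel_predictor <- function(object, inputs, ...) {
  if (!is.matrix(inputs)) inputs <- matrix(inputs, nrow = 1L)
  if (ncol(inputs) != 8L) {
    stop("predictor inputs must have width 8", call. = FALSE)
  }
  out <- nn_forward(object$net, inputs, training = FALSE)$out
  pmin(pmax(out, 0), 1)
}

#' Pearson regression correlation between predictions and targets
#'
#' All prediction/target pairs are pooled (both output columns for the 1x8
#' model). Invariant under positive affine rescaling of the predictions.
#'
#' @param predictions,targets Numeric vectors/matrices of equal length.
#' @return Scalar `R` in `[-1, 1]`.
#' @export
regression_r <- function(predictions, targets) {
  p <- as.vector(predictions)
  t_ <- as.vector(targets)
  if (length(p) != length(t_) || length(p) < 2L) {
    stop("need at least two prediction/target pairs", call. = FALSE)
  }
  if (stats::var(p) == 0 || stats::var(t_) == 0) {
    stop("zero variance: regression R is undefined", call. = FALSE)
  }
  stats::cor(p, t_)
}
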