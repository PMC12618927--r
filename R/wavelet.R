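# Multi-level 2-D discrete wavelet transform (orthonormal, periodized).

# Orthonormal analysis filter pairs. The highpass is the conjugate quadrature
# mirror h[n] = (-1)^n g[L-1-n], so the periodized transform is exactly
# orthogonal (perfect reconstruction and Parseval hold to rounding error).
.wavelet_bank <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db4 = c(0.230377813308855230, 0.714846570552541500,
          0.630880767929590400, -0.027983769416983849,
          -0.187034811718881140, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

.wavelet_ids <- c(haar = 1L, db2 = 2L, db4 = 3L)

#' Available wavelet names
#' @return Character vector of supported orthonormal wavelets.
#' @export
wavelet_names <- function() names(.wavelet_bank)

wavelet_filters <- function(wavelet_name) {
  g <- .wavelet_bank[[wavelet_name]]
  if (is.null(g)) {
    stop("unknown wavelet `", wavelet_name, "`; available: ",
         paste(wavelet_names(), collapse = ", "), call. = FALSE)
  }
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  list(lo = g, hi = h, length = L)
}

# one analysis step along the columns of X (length-N signals), periodized
dwt_step_cols <- function(X, flt) {
  N <- nrow(X)
  half <- N %/% 2L
  a <- matrix(0, half, ncol(X))
  d <- matrix(0, half, ncol(X))
  base <- 2L * (seq_len(half) - 1L)
  for (t in seq_len(flt$length)) {
    idx <- ((base + t - 1L) %% N) + 1L
    a <- a + flt$lo[t] * X[idx, , drop = FALSE]
    d <- d + flt$hi[t] * X[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

# inverse of dwt_step_cols (transpose of the orthogonal analysis operator)
idwt_step_cols <- function(a, d, flt) {
  half <- nrow(a)
  N <- 2L * half
  X <- matrix(0, N, ncol(a))
  base <- 2L * (seq_len(half) - 1L)
  for (t in seq_len(flt$length)) {
    idx <- ((base + t - 1L) %% N) + 1L
    X[idx, ] <- X[idx, ] + flt$lo[t] * a + flt$hi[t] * d
  }
  X
}

dwt2_level <- function(X, flt) {
  v <- dwt_step_cols(X, flt)              # filter along the vertical axis
  lo <- dwt_step_cols(t(v$a), flt)        # then along the horizontal axis
  hi <- dwt_step_cols(t(v$d), flt)
  # first letter: vertical filter; second: horizontal filter
  list(LL = t(lo$a), LH = t(lo$d), HL = t(hi$a), HH = t(hi$d))
}

idwt2_level <- function(bands, flt) {
  va <- t(idwt_step_cols(t(bands$LL), t(bands$LH), flt))
  vd <- t(idwt_step_cols(t(bands$HL), t(bands$HH), flt))
  idwt_step_cols(va, vd, flt)
}

#' Multi-level 2-D discrete wavelet transform
#'
#' Decomposes an image into `{LL, LH, HL, HH}` subbands per level using a
#' separable orthonormal filter bank with periodic boundary handling. Level 1
#' is the finest. The orientation convention is: the first letter names the
#' filter applied along the vertical (row) axis and the second the horizontal
#' (column) axis, so `LH` responds to variation across columns (vertical
#' edges) and `HL` to variation across rows (horizontal edges).
#'
#' For orthonormal filters the transform conserves energy exactly (Parseval)
#' and `idwt2(dwt2(I))` reproduces `I` to floating-point rounding.
#'
#' @param image Numeric matrix.
#' @param wavelet_name One of [wavelet_names()] (default `"haar"`).
#' @param levels Number of decomposition levels (>= 1).
#' @return An object of class `subband_set`: fields `detail` (list of levels,
#'   each with `LH`, `HL`, `HH`), `ll` (coarsest approximation),
#'   `wavelet_name`, `levels`, `boundary_mode`, `original_shape`.
#' @export
#' @examples
#' sb <- dwt2(matrix(1:16 / 16, 4, 4), "haar", 1)
#' max(abs(idwt2(sb) - matrix(1:16 / 16, 4, 4)))
dwt2 <- function(image, wavelet_name = "haar", levels = 1L) {
  stopifnot_matrix(image)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  flt <- wavelet_filters(wavelet_name)
  m <- nrow(image); n <- ncol(image)
  cur <- image
  detail <- vector("list", levels)
  for (k in seq_len(levels)) {
    if (nrow(cur) %% 2L != 0L || ncol(cur) %% 2L != 0L ||
        nrow(cur) < flt$length || ncol(cur) < flt$length) {
      stop(sprintf(
        "image of %d x %d is too small (or odd-sized) at level %d for wavelet `%s`",
        nrow(cur), ncol(cur), k, wavelet_name), call. = FALSE)
    }
    bands <- dwt2_level(cur, flt)
    detail[[k]] <- bands[c("LH", "HL", "HH")]
    cur <- bands$LL
  }
  structure(
    list(detail = detail, ll = cur, wavelet_name = wavelet_name,
         levels = as.integer(levels), boundary_mode = "periodic",
         original_shape = c(m, n)),
    class = "subband_set"
  )
}

#' Inverse multi-level 2-D discrete wavelet transform
#'
#' @param subbands A `subband_set` from [dwt2()] (possibly with modified
#'   coefficients).
#' @return Numeric matrix of shape `original_shape`.
#' @export
idwt2 <- function(subbands) {
  if (!inherits(subbands, "subband_set")) {
    stop("`subbands` must be a `subband_set`", call. = FALSE)
  }
  flt <- wavelet_filters(subbands$wavelet_name)
  K <- subbands$levels
  cur <- subbands$ll
  for (k in rev(seq_len(K))) {
    d <- subbands$detail[[k]]
    expect <- c(subbands$original_shape %/% (2L^k))
    for (nm in c("LH", "HL", "HH")) {
      if (!identical(dim(d[[nm]]), as.integer(expect)) ||
          !identical(dim(cur), as.integer(expect))) {
        stop(sprintf("inconsistent subband shapes at level %d", k),
             call. = FALSE)
      }
    }
    cur <- idwt2_level(list(LL = cur, LH = d$LH, HL = d$HL, HH = d$HH), flt)
  }
  cur
}

#' Total squared-coefficient energy of a subband set
#'
#' Equals the squared Frobenius norm of the original image for orthonormal
#' wavelets.
#'
#' @param subbands A `subband_set`.
#' @return Scalar energy.
#' @export
subband_energy <- function(subbands) {
  e <- sum(subbands$ll^2)
  for (lvl in subbands$detail) {
    e <- e + sum(lvl$LH^2) + sum(lvl$HL^2) + sum(lvl$HH^2)
  }
  e
}
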