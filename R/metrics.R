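# Image quality metrics: MSE, PSNR, SSIM, NCC, bpp accounting, aggregation.

#' Mean squared error between two images
#'
#' Computed on the scale of the arrays as given. The evaluation pipeline
#' ([evaluate_pair()]) converts internal `[0, 1]` images to the 0-255 scale
#' first, which keeps PSNR's hard-coded peak of 255 and the default SSIM
#' stabilization constants mutually consistent.
#'
#' @param x,y Numeric matrices of equal shape.
#' @return Scalar mean squared difference.
#' @export
mse <- function(x, y) {
  stopifnot_matrix(x); stopifnot_matrix(y)
  if (!identical(dim(x), dim(y))) stop("shape mismatch", call. = FALSE)
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 * log10(peak / sqrt(MSE))`. Identical images return `Inf` (a documented
#' sentinel, never `NaN`).
#'
#' @param x,y Numeric matrices on the 0-`peak` scale.
#' @param peak Peak signal value (255 for 8-bit images).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, peak = 255) {
  e <- mse(x, y)
  if (e == 0) return(Inf)
  20 * log10(peak / sqrt(e))
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# weighted local filtering at all fully-interior window positions ("valid"),
# implemented as a sum over taps of shifted submatrices
filter2_valid <- function(x, w) {
  k <- nrow(w)
  m <- nrow(x) - k + 1L
  n <- ncol(x) - k + 1L
  out <- matrix(0, m, n)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (w[i, j] != 0) {
        out <- out + w[i, j] * x[i:(i + m - 1L), j:(j + n - 1L)]
      }
    }
  }
  out
}

#' Structural similarity index (mean SSIM)
#'
#' Windowed SSIM with a Gaussian 11x11 (sigma 1.5) weighting, evaluated at all
#' fully-interior window positions and averaged. Local moments are weighted
#' (population) moments. Stabilization constants are `C1 = (K1*L)^2` and
#' `C2 = (K2*L)^2`.
#'
#' @param x,y Numeric matrices on the 0-`L` scale, at least as large as the
#'   window.
#' @param L Dynamic range (255 for 8-bit images).
#' @param K1,K2 Stabilization fractions.
#' @param window Weight matrix summing to 1 (default Gaussian 11x11).
#' @return Scalar mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, L = 255, K1 = 0.01, K2 = 0.03,
                 window = gaussian_window()) {
  stopifnot_matrix(x); stopifnot_matrix(y)
  if (!identical(dim(x), dim(y))) stop("shape mismatch", call. = FALSE)
  if (nrow(x) < nrow(window) || ncol(x) < ncol(window)) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  mu_x <- filter2_valid(x, window)
  mu_y <- filter2_valid(y, window)
  xx <- filter2_valid(x * x, window)
  yy <- filter2_valid(y * y, window)
  xy <- filter2_valid(x * y, window)
  var_x <- xx - mu_x^2
  var_y <- yy - mu_y^2
  cov_xy <- xy - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
  mean(s)
}

#' Normalized correlation coefficient (uncentered)
#'
#' The cosine similarity `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`.
#' Unlike Pearson correlation the means are *not* subtracted; the two agree
#' only for zero-mean images. Scale-invariant: `ncc(x, c*x) = 1` for `c > 0`.
#'
#' @param x,y Numeric matrices of equal shape, not both all-zero.
#' @return Scalar in `[-1, 1]` (in `[0, 1]` for non-negative images).
#' @export
ncc <- function(x, y) {
  stopifnot_matrix(x); stopifnot_matrix(y)
  if (!identical(dim(x), dim(y))) stop("shape mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("NCC undefined: an image has zero norm", call. = FALSE)
  }
  sum(x * y) / (nx * ny)
}

#' Evaluate a reconstruction against its original
#'
#' Converts both `[0, 1]` images to the 0-255 scale, computes the full metric
#' row, and (optionally) accounts the bitstream size as bits per pixel.
#'
#' @param original,reconstructed Numeric matrices in `[0, 1]`.
#' @param n_bits Total compressed size in bits (header + payload), or `NA`.
#' @param image_id Identifier for the record.
#' @param time_ms Wall time in milliseconds, or `NA`.
#' @return One-row `data.frame` with columns `image_id`, `mse`, `psnr_db`,
#'   `cc`, `ssim`, `bpp`, `time_ms` (Table-style header order).
#' @export
evaluate_pair <- function(original, reconstructed, n_bits = NA_real_,
                          image_id = "img", time_ms = NA_real_) {
  x <- original * 255
  y <- reconstructed * 255
  data.frame(
    image_id = image_id,
    mse = mse(x, y),
    psnr_db = psnr(x, y, peak = 255),
    cc = ncc(x, y),
    ssim = ssim(x, y, L = 255),
    bpp = if (is.na(n_bits)) NA_real_ else n_bits / length(original),
    time_ms = time_ms,
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-image metric records into a mean row
#'
#' Arithmetic mean of every numeric column; rounding happens only at display
#' time.
#'
#' @param records `data.frame` of per-image metric rows.
#' @return One-row `data.frame` with `image_id = "average"`.
#' @export
aggregate_metrics <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 1L) {
    stop("`records` must be a data.frame with at least one row", call. = FALSE)
  }
  num <- vapply(records, is.numeric, logical(1))
  out <- records[1, , drop = FALSE]
  out[["image_id"]] <- "average"
  for (nm in names(records)[num]) {
    out[[nm]] <- mean(records[[nm]])
  }
  rownames(out) <- NULL
  out
}
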