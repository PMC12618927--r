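# Seeded generator of anatomy-like grayscale phantoms and dataset splits.

#' Specify a synthetic grayscale phantom
#'
#' A phantom emulates a single-channel CT/MRI-like slice: a dark constant
#' background, a large rotated "head" ellipse with a bright bone-like rim and
#' a smooth low-frequency interior field, optional inner ellipses with graded
#' intensity offsets, small bright Gaussian-profile lesions, and additive
#' i.i.d. Gaussian noise. Intensities live on the `[0, 1]` scale.
#'
#' `n_ellipses` counts the background anatomy ellipses *including* the outer
#' head+rim ellipse, so `n_ellipses = 0` yields a constant background (plus
#' noise if requested). With `n_ellipses >= 1` the rim guarantees at least one
#' step edge of magnitude `>= edge_contrast` against the background, and the
#' corners remain a region of near-zero gradient.
#'
#' @param height,width Image dimensions in pixels; at least 16 and even
#'   (friendly to dyadic wavelet decomposition).
#' @param n_ellipses Number of anatomy ellipses (the first is the head+rim).
#' @param n_lesions Number of small bright Gaussian blobs.
#' @param edge_contrast Rim step height as a fraction of the dynamic range.
#' @param noise_sigma Standard deviation of additive Gaussian noise on the
#'   `[0, 1]` scale.
#' @param seed Integer seed; identical specs produce bitwise-identical images.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(64, 64, seed = 1)
#' img <- generate_phantom(spec)
#' range(img)
phantom_spec <- function(height = 64L, width = 64L, n_ellipses = 4L,
                         n_lesions = 2L, edge_contrast = 0.35,
                         noise_sigma = 0.01, seed = 1L) {
  check_dim <- function(d, nm) {
    if (!is.numeric(d) || length(d) != 1L || d < 16 || d %% 2 != 0) {
      stop(sprintf("`%s` must be a single even integer >= 16", nm),
           call. = FALSE)
    }
  }
  check_dim(height, "height")
  check_dim(width, "width")
  if (n_ellipses < 0 || n_lesions < 0) {
    stop("`n_ellipses` and `n_lesions` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  }
  if (edge_contrast < 0 || edge_contrast > 0.7) {
    stop("`edge_contrast` must lie in [0, 0.7]", call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_ellipses = as.integer(n_ellipses), n_lesions = as.integer(n_lesions),
         edge_contrast = edge_contrast, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a phantom image from a spec
#'
#' @param spec A [phantom_spec()].
#' @return A `height x width` numeric matrix with values in `[0, 1]`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a `phantom_spec` object", call. = FALSE)
  }
  m <- spec$height
  n <- spec$width
  # normalized coordinates in [-1, 1], x along columns, y along rows
  ys <- matrix(seq(-1, 1, length.out = m), nrow = m, ncol = n)
  xs <- matrix(seq(-1, 1, length.out = n), nrow = m, ncol = n, byrow = TRUE)

  background <- 0.05
  with_seed(spec$seed, {
    img <- matrix(background, m, n)

    ellipse_r2 <- function(cx, cy, a, b, theta) {
      xr <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
      yr <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
      (xr / a)^2 + (yr / b)^2
    }

    head_mask <- NULL
    if (spec$n_ellipses >= 1L) {
      # head ellipse with a bone-like rim one edge_contrast above its interior
      cx <- stats::runif(1, -0.04, 0.04)
      cy <- stats::runif(1, -0.04, 0.04)
      a <- stats::runif(1, 0.70, 0.80)
      b <- stats::runif(1, 0.80, 0.88)
      th <- stats::runif(1, -pi / 18, pi / 18)
      r2 <- ellipse_r2(cx, cy, a, b, th)
      interior_base <- 0.30
      rim <- r2 > 1 & r2 <= 1.25
      inside <- r2 <= 1
      # smooth low-frequency interior field
      field <- 0
      for (k in 1:3) {
        fx <- stats::runif(1, 0.2, 1.2)
        fy <- stats::runif(1, 0.2, 1.2)
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 0.02, 0.05)
        field <- field + amp * cos(2 * pi * (fx * xs + fy * ys) + ph)
      }
      img[inside] <- interior_base + field[inside]
      img[rim] <- interior_base + spec$edge_contrast
      head_mask <- inside
    }

    if (spec$n_ellipses >= 2L) {
      for (k in seq_len(spec$n_ellipses - 1L)) {
        cx <- stats::runif(1, -0.4, 0.4)
        cy <- stats::runif(1, -0.45, 0.45)
        a <- stats::runif(1, 0.08, 0.32)
        b <- stats::runif(1, 0.08, 0.32)
        th <- stats::runif(1, 0, pi)
        delta <- sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.16)
        r2 <- ellipse_r2(cx, cy, a, b, th)
        sel <- r2 <= 1
        if (!is.null(head_mask)) sel <- sel & head_mask
        img[sel] <- img[sel] + delta
      }
    }

    if (spec$n_lesions >= 1L) {
      for (k in seq_len(spec$n_lesions)) {
        cx <- stats::runif(1, -0.5, 0.5)
        cy <- stats::runif(1, -0.55, 0.55)
        sg <- stats::runif(1, 0.02, 0.06)
        amp <- stats::runif(1, 0.15, 0.35)
        d2 <- (xs - cx)^2 + (ys - cy)^2
        blob <- amp * exp(-d2 / (2 * sg^2))
        if (!is.null(head_mask)) blob[!head_mask] <- 0
        img <- img + blob
      }
    }

    if (spec$noise_sigma > 0) {
      img <- img + spec$noise_sigma * matrix(stats::rnorm(m * n), m, n)
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Split image indices into train / validation / test sets
#'
#' Indices are shuffled with the given seed, then partitioned. The train and
#' validation sizes are `n * fraction` rounded half away from zero; the test
#' set takes the remainder, so the three sets are disjoint and cover
#' `1:n_images` exactly. With the default fractions, `n = 100` gives sizes
#' (70, 15, 15) and `n = 10` gives (7, 2, 1).
#'
#' @param n_images Number of images (>= 10).
#' @param fractions Length-3 numeric vector (train, val, test) summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return An object of class `dataset_split` with fields `train_ids`,
#'   `val_ids`, `test_ids`, `fractions`, `seed`.
#' @export
make_split <- function(n_images, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (n_images < 10) stop("`n_images` must be >= 10", call. = FALSE)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  n_train <- as.integer(round_half_away(n_images * fractions[1]))
  n_val <- as.integer(round_half_away(n_images * fractions[2]))
  n_test <- n_images - n_train - n_val
  if (n_test < 0) stop("fractions leave no room for a test set", call. = FALSE)
  perm <- with_seed(seed, sample.int(n_images))
  structure(
    list(train_ids = sort(perm[seq_len(n_train)]),
         val_ids = sort(perm[n_train + seq_len(n_val)]),
         test_ids = sort(perm[n_train + n_val + seq_len(n_test)]),
         fractions = fractions, seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' Convert a `[0, 1]` image to 8-bit integers
#'
#' Uses round-half-away-from-zero, the same tie rule as the latent quantizer.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @return Integer matrix in `0:255`.
#' @export
to_uint8 <- function(img) {
  matrix(as.integer(pmin(pmax(floor(img * 255 + 0.5), 0), 255)),
         nrow(img), ncol(img))
}

#' Write a grayscale image to PNG or PGM
#'
#' The file type is chosen from the extension (`.png` or `.pgm`). Values are
#' quantized to 8 bits with [to_uint8()] before writing, so a written-then-read
#' image equals the 8-bit quantization of the input exactly.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot_matrix(img)
  v8 <- to_uint8(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(v8 / 255, target = path)
  } else if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
              eos = NULL)
    # PGM is row-major
    writeBin(as.raw(as.vector(t(v8))), con)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a grayscale image from PNG or PGM
#'
#' @param path Path to an 8-bit grayscale `.png` or `.pgm` file.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    x
  } else if (ext == "pgm") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 2L)
    if (!magic %in% c("P5", "P2")) {
      stop("not a PGM file: ", path, call. = FALSE)
    }
    toks <- character(0)
    while (length(toks) < 3L) {
      line <- readLines(con, n = 1L)
      line <- sub("#.*$", "", line)
      toks <- c(toks, strsplit(trimws(line), "[[:space:]]+")[[1]])
      toks <- toks[nzchar(toks)]
    }
    w <- as.integer(toks[1]); h <- as.integer(toks[2])
    maxval <- as.integer(toks[3])
    if (magic == "P5") {
      v <- as.integer(readBin(con, "raw", n = w * h))
    } else {
      v <- scan(con, what = integer(), n = w * h, quiet = TRUE)
    }
    matrix(v, nrow = h, ncol = w, byrow = TRUE) / maxval
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
}

#' Generate a reproducible set of phantoms
#'
#' Convenience wrapper producing `n` phantoms whose per-image seeds are drawn
#' deterministically from `seed`.
#'
#' @param n Number of images.
#' @param height,width Image dimensions.
#' @param seed Master integer seed.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return List of `n` image matrices.
#' @export
generate_phantom_set <- function(n, height = 64L, width = 64L, seed = 1L, ...) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seeds, function(s) {
    generate_phantom(phantom_spec(height = height, width = width, seed = s, ...))
  })
}
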