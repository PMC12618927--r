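# Shared internal helpers: seeded evaluation, rounding, checksums.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library randomness never leaks into
#' (or depends on) the caller's RNG state. All stochastic operations in the
#' package route their randomness through this helper with an explicit
#' integer seed.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Symmetric rounding used for quantization and for 8-bit conversion, where
#' R's default round-half-even would bias symbol counts around zero.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Adler-32 checksum of a raw vector, returned as a double in [0, 2^32).
# Used for payload integrity in the bitstream container and (doubled up)
# for the model identity hash; implemented here because base R exposes no
# checksum over raw bytes.
adler32 <- function(raw_bytes) {
  MOD <- 65521
  a <- 1
  b <- 0
  n <- length(raw_bytes)
  if (n > 0L) {
    v <- as.integer(raw_bytes)
    # process in chunks so the running sums stay exactly representable
    chunk <- 3000L
    i <- 1L
    while (i <= n) {
      j <- min(i + chunk - 1L, n)
      seg <- v[i:j]
      # b accumulates a * len + cumulative sums
      a_seq <- a + cumsum(seg)
      b <- (b + sum(a_seq %% MOD)) %% MOD
      a <- a_seq[length(a_seq)] %% MOD
      i <- j + 1L
    }
  }
  b * 65536 + a
}

# 8-byte identity hash of an R object (two Adler-32 passes over its
# serialization, forward and reversed), as a raw vector of length 8.
object_hash8 <- function(obj) {
  s <- serialize(obj, connection = NULL, version = 2)
  h1 <- adler32(s)
  h2 <- adler32(rev(s))
  c(uint32_to_raw(h1), uint32_to_raw(h2))
}

# little-endian uint32 <-> raw[4], via doubles (R integers are signed 32-bit)
uint32_to_raw <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

raw_to_uint32 <- function(r) {
  v <- as.integer(r)
  v[1] + v[2] * 256 + v[3] * 65536 + v[4] * 16777216
}

# little-endian uint16 <-> raw[2]
uint16_to_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
raw_to_uint16 <- function(r) as.integer(r[1]) + as.integer(r[2]) * 256

stopifnot_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
}
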