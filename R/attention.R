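# Scaled dot-product and multi-head cross-attention, and the cross-attention
# (CAL) block that reweights high-frequency subband features against
# low-frequency structural queries.

softmax_rows <- function(logits) {
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, rows of the weight matrix summing to 1.
#' Each output row is a convex combination of the rows of `V`.
#'
#' @param Q Query matrix (`n_q x d_k`).
#' @param K Key matrix (`n_kv x d_k`).
#' @param V Value matrix (`n_kv x d_v`).
#' @param return_weights If `TRUE`, also return the attention weights.
#' @return Attended features (`n_q x d_v`), or
#'   `list(out, weights)` when `return_weights = TRUE`.
#' @export
#' @examples
#' scaled_dot_attention(matrix(2), matrix(c(0, 1)), matrix(c(0, 1)))
scaled_dot_attention <- function(Q, K, V, return_weights = FALSE) {
  if (!is.matrix(Q)) Q <- as.matrix(Q)
  if (!is.matrix(K)) K <- as.matrix(K)
  if (!is.matrix(V)) V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) {
    stop("Q and K must have the same number of columns (d_k)", call. = FALSE)
  }
  if (nrow(K) != nrow(V)) {
    stop("K and V must have the same number of rows", call. = FALSE)
  }
  d_k <- ncol(Q)
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(d_k))
  out <- A %*% V
  if (return_weights) list(out = out, weights = A) else out
}

#' Multi-head attention configuration
#'
#' @param h Number of heads (default 8).
#' @param embed_dim Total embedding dimension (default 64); must be divisible
#'   by `h`.
#' @return A `multi_head_config` object.
#' @export
multi_head_config <- function(h = 8L, embed_dim = 64L) {
  if (embed_dim %% h != 0) {
    stop("`embed_dim` must be divisible by the head count `h`", call. = FALSE)
  }
  structure(list(h = as.integer(h), embed_dim = as.integer(embed_dim),
                 d_head = as.integer(embed_dim %/% h)),
            class = "multi_head_config")
}

#' Seeded projection matrices for multi-head cross-attention
#'
#' Xavier-normal `W_Q` (`d_x x embed_dim`), `W_K`, `W_V` (`d_y x embed_dim`)
#' and output projection `W_O` (`embed_dim x d_out`). No bias terms.
#'
#' @param d_x Query-source feature width.
#' @param d_y Key/value-source feature width.
#' @param config A [multi_head_config()].
#' @param d_out Output feature width (default `d_y`).
#' @param seed Integer seed.
#' @return List with `W_Q`, `W_K`, `W_V`, `W_O`.
#' @export
attention_projections <- function(d_x, d_y, config, d_out = d_y, seed = 1L) {
  e <- config$embed_dim
  xav <- function(fi, fo) {
    matrix(stats::rnorm(fi * fo, sd = sqrt(2 / (fi + fo))), fi, fo)
  }
  with_seed(seed, list(
    W_Q = xav(d_x, e), W_K = xav(d_y, e), W_V = xav(d_y, e),
    W_O = xav(e, d_out)
  ))
}

#' Multi-head cross-attention
#'
#' Queries are projected from `X`, keys and values from `Y`; each head runs
#' scaled dot-product attention on its `embed_dim / h` column slice and the
#' concatenated heads are mapped through the output projection `W_O`.
#'
#' @param X Query-source token matrix (`n_q x d_x`).
#' @param Y Key/value-source token matrix (`n_kv x d_y`).
#' @param config A [multi_head_config()].
#' @param projections Projection matrices, e.g. from [attention_projections()].
#' @return Attended feature matrix (`n_q x ncol(W_O)`).
#' @export
multi_head <- function(X, Y, config, projections) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  Q <- X %*% projections$W_Q
  K <- Y %*% projections$W_K
  V <- Y %*% projections$W_V
  h <- config$h
  dh <- config$d_head
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    sel <- ((i - 1L) * dh + 1L):(i * dh)
    heads[[i]] <- scaled_dot_attention(Q[, sel, drop = FALSE],
                                       K[, sel, drop = FALSE],
                                       V[, sel, drop = FALSE])
  }
  do.call(cbind, heads) %*% projections$W_O
}

#' Build the cross-attention weights for a codec model
#'
#' @param config A [multi_head_config()].
#' @param n_hf_channels Number of high-frequency channels (3 per level).
#' @param seed Integer seed.
#' @return List with the config and projections (class `cal_weights`).
#' @export
cal_weights <- function(config = multi_head_config(), n_hf_channels = 3L,
                        seed = 1L) {
  structure(
    list(config = config,
         projections = attention_projections(1L, n_hf_channels, config,
                                             d_out = n_hf_channels,
                                             seed = seed)),
    class = "cal_weights"
  )
}

#' Cross-attention reweighting of high-frequency subband features
#'
#' Queries come from the low-frequency (structural) feature map, keys and
#' values from the high-frequency detail channels. Feature maps are tokenized
#' as one token per spatial position (channels as features). The attended
#' features are added back onto the input through a residual connection, so a
#' zero value projection leaves the details untouched.
#'
#' @param ll_features `m x n` low-frequency feature matrix.
#' @param hf_features `m x n x c` array of high-frequency feature channels.
#' @param weights A [cal_weights()] object.
#' @return Reweighted `m x n x c` array.
#' @export
cal_block <- function(ll_features, hf_features, weights) {
  stopifnot_matrix(ll_features)
  dh <- dim(hf_features)
  if (length(dh) != 3L || !identical(dh[1:2], dim(ll_features))) {
    stop("`hf_features` must be an (m, n, c) array matching `ll_features`",
         call. = FALSE)
  }
  n_tok <- dh[1] * dh[2]
  X <- matrix(as.vector(ll_features), n_tok, 1L)
  Y <- matrix(hf_features, n_tok, dh[3])
  attended <- multi_head(X, Y, weights$config, weights$projections)
  array(Y + attended, dh)
}
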