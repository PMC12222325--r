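#' Initialize feature aggregation (cross-attention) parameters
#'
#' The feature aggregation module (FAM) projects query and support RoI
#' features into query/key/value spaces with bias-free linear maps, computes
#' scaled dot-product attention of queries over support samples, aggregates
#' support values with the attention weights, and residually fuses the
#' aggregate into the query features:
#' \deqn{Q = F_q W_Q,\quad K = F_s W_K,\quad V = F_s W_V}
#' \deqn{A = \mathrm{softmax}(Q K^\top / \sqrt{d_k}),\quad F_{agg} = A V}
#' \deqn{F_{enh} = F_q + \alpha\, F_{agg} W_O}
#' where \eqn{\alpha} is a learnable scalar and \eqn{W_O} (identity when
#' `d_k == D`) maps the aggregate back to the feature dimension so the
#' residual sum is well defined.
#'
#' @param D Input feature dimension.
#' @param d_k Attention head dimension (defaults to `D`).
#' @param alpha Initial value of the fusion scale (default 0.5: midway
#'   between ignoring and fully trusting the aggregate).
#' @param seed Integer seed for the Kaiming-style initialization.
#' @return List of class `fam_params` with `W_q`, `W_k`, `W_v`, `W_o`,
#'   `alpha`, `d_k`.
#' @export
fam_params <- function(D, d_k = D, alpha = 0.5, seed = NULL) {
  assert_that(is_count(D) && D >= 1, "D must be a positive count")
  assert_that(is_count(d_k) && d_k >= 1, "d_k must be a positive count")
  assert_that(alpha >= 0, "alpha must be >= 0 at init")
  with_seed(seed, {
    sdv <- sqrt(2 / D)
    W_o <- if (d_k == D) diag(D) else matrix(rnorm(d_k * D, 0, sqrt(2 / d_k)), d_k, D)
    structure(list(
      W_q = matrix(rnorm(D * d_k, 0, sdv), D, d_k),
      W_k = matrix(rnorm(D * d_k, 0, sdv), D, d_k),
      W_v = matrix(rnorm(D * d_k, 0, sdv), D, d_k),
      W_o = W_o, alpha = alpha, d_k = as.integer(d_k)
    ), class = "fam_params")
  })
}

#' Project query/support features to Q, K, V spaces
#'
#' Pure (bias-free) linear maps. `query` and `support` are numeric matrices
#' with one RoI feature per row and `ncol == nrow(params$W_q)`.
#'
#' @param query `N_q x D` query feature matrix.
#' @param support `N_s x D` support feature matrix.
#' @param params A [fam_params()].
#' @return List with matrices `Q` (`N_q x d_k`), `K` and `V` (`N_s x d_k`).
#' @export
project_qkv <- function(query, support, params) {
  query <- as.matrix(query); support <- as.matrix(support)
  assert_that(ncol(query) == nrow(params$W_q) && ncol(support) == nrow(params$W_k),
              "feature dimension does not match FAM parameters")
  assert_that(all(is.finite(query)) && all(is.finite(support)),
              "features must be finite")
  list(Q = query %*% params$W_q, K = support %*% params$W_k,
       V = support %*% params$W_v)
}

#' Scaled dot-product attention weights
#'
#' Computes similarity scores `s = Q K' / sqrt(d_k)` and row-softmax
#' attention weights. Each weight row is a probability distribution over the
#' support samples (rows sum to one); the `1/sqrt(d_k)` scaling keeps scores
#' from growing with the head dimension.
#'
#' @param Q `N_q x d_k` query matrix.
#' @param K `N_s x d_k` key matrix; `N_s` must be at least 1.
#' @param d_k Key dimension used for scaling (defaults to `ncol(K)`).
#' @return List with `scores` and `weights`, both `N_q x N_s`.
#' @export
attention_weights <- function(Q, K, d_k = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K)
  assert_that(nrow(K) >= 1, "attention is undefined with an empty support set")
  assert_that(ncol(Q) == ncol(K), "Q and K must share their column dimension")
  assert_that(d_k >= 1, "d_k must be >= 1")
  s <- tcrossprod(Q, K) / sqrt(d_k)
  A <- row_softmax(s)
  list(scores = s, weights = A)
}

# Numerically stable row-wise softmax.
row_softmax <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Aggregate support values and fuse into query features
#'
#' `F_agg = A V` is a convex combination of support value rows per query;
#' `F_enhanced = F_query + alpha * (F_agg W_o)`. With `alpha = 0` the query
#' features pass through unchanged.
#'
#' @param A `N_q x N_s` row-stochastic attention weights.
#' @param V `N_s x d_k` value matrix.
#' @param F_query `N_q x D` original query features.
#' @param alpha Scalar fusion weight.
#' @param W_o `d_k x D` output projection (identity if omitted and
#'   `d_k == D`).
#' @return List with `F_agg` (`N_q x d_k`) and `F_enhanced` (`N_q x D`).
#' @export
aggregate_and_fuse <- function(A, V, F_query, alpha, W_o = NULL) {
  A <- as.matrix(A); V <- as.matrix(V); F_query <- as.matrix(F_query)
  if (is.null(W_o)) {
    assert_that(ncol(V) == ncol(F_query),
                "W_o is required when d_k differs from the feature dimension")
    W_o <- diag(ncol(V))
  }
  F_agg <- A %*% V
  F_enhanced <- F_query + alpha * (F_agg %*% W_o)
  list(F_agg = F_agg, F_enhanced = F_enhanced)
}

#' Full FAM forward pass
#'
#' Convenience composition of [project_qkv()], [attention_weights()] and
#' [aggregate_and_fuse()], returning every intermediate needed for the
#' aggregation loss and for backpropagation.
#'
#' @inheritParams project_qkv
#' @return List with `Q`, `K`, `V`, `scores`, `weights`, `F_agg`,
#'   `F_enhanced` plus the inputs (as a backward cache).
#' @export
fam_forward <- function(query, support, params) {
  pr <- project_qkv(query, support, params)
  at <- attention_weights(pr$Q, pr$K, params$d_k)
  ag <- aggregate_and_fuse(at$weights, pr$V, query, params$alpha, params$W_o)
  c(pr, at, ag, list(F_query = as.matrix(query), F_support = as.matrix(support),
                     params = params))
}

# Backward pass through the FAM.
#
# dE: gradient of the loss w.r.t. F_enhanced (N_q x D).
# dS_extra / dA_extra: direct gradients w.r.t. scores and attention weights
# contributed by the aggregation regularizer (may be NULL).
# Returns gradients for W_q, W_k, W_v, W_o, alpha (and dF_query for
# completeness; the backbone is frozen so it is unused by the trainer).
fam_backward <- function(cache, dE, dS_extra = NULL, dA_extra = NULL) {
  p <- cache$params
  A <- cache$weights; V <- cache$V; G <- cache$F_agg
  dE <- as.matrix(dE)
  M <- G %*% p$W_o
  d_alpha <- sum(dE * M)
  dM <- p$alpha * dE
  dW_o <- crossprod(G, dM)
  dG <- tcrossprod(dM, p$W_o)          # N_q x d_k ( = dM %*% t(W_o) )
  dA <- tcrossprod(dG, V)              # N_q x N_s
  dV <- crossprod(A, dG)               # N_s x d_k
  if (!is.null(dA_extra)) dA <- dA + dA_extra
  # softmax backward per row: dS = A * (dA - rowSums(dA * A))
  dS <- A * (dA - rowSums(dA * A))
  if (!is.null(dS_extra)) dS <- dS + dS_extra
  scale <- 1 / sqrt(p$d_k)
  dQ <- (dS %*% cache$K) * scale
  dK <- (crossprod(dS, cache$Q)) * scale
  list(
    W_q = crossprod(cache$F_query, dQ),
    W_k = crossprod(cache$F_support, dK),
    W_v = crossprod(cache$F_support, dV),
    W_o = dW_o,
    alpha = d_alpha,
    F_query = dE + tcrossprod(dQ, p$W_q)
  )
}
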