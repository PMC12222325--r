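#' Initialize the contrastive projection head
#'
#' A one-hidden-layer MLP (`D -> D` with ReLU, then `D -> d_e`) whose output
#' is L2-normalized onto the unit hypersphere. The head is active only during
#' training; inference ignores it.
#'
#' @param D Input feature dimension.
#' @param d_e Embedding dimension (default 128, the convention of
#'   contrastive detection heads).
#' @param seed Integer seed for Kaiming-style initialization.
#' @return List of class `scl_head` with `W1`, `b1`, `W2`, `b2`.
#' @export
scl_head_params <- function(D, d_e = 128, seed = NULL) {
  with_seed(seed, {
    structure(list(
      W1 = matrix(rnorm(D * D, 0, sqrt(2 / D)), D, D),
      b1 = numeric(D),
      W2 = matrix(rnorm(D * d_e, 0, sqrt(2 / D)), D, d_e),
      b2 = numeric(d_e)
    ), class = "scl_head")
  })
}

#' Project features through a head and L2-normalize rows
#'
#' Applies `head` (or the identity when `head = NULL`) and normalizes every
#' row to unit Euclidean norm. A zero-norm row is a degenerate embedding and
#' raises an error naming the row.
#'
#' @param features `N x D` feature matrix (finite values).
#' @param head Optional [scl_head_params()]; `NULL` means identity.
#' @return `N x d_e` matrix of unit-norm embeddings.
#' @export
embed_normalize <- function(features, head = NULL) {
  X <- as.matrix(features)
  assert_that(all(is.finite(X)), "features must be finite")
  Z <- if (is.null(head)) X else {
    H <- pmax(sweep(X %*% head$W1, 2, head$b1, "+"), 0)
    sweep(H %*% head$W2, 2, head$b2, "+")
  }
  nrm <- sqrt(rowSums(Z^2))
  bad <- which(nrm < 1e-12)
  if (length(bad) > 0) {
    abort(sprintf("zero-norm embedding at row %d", bad[1]))
  }
  Z / nrm
}

#' (Class-weighted) supervised contrastive loss
#'
#' For unit-norm embeddings `z` with labels `y`, each anchor i with positive
#' set P(i) (same-label rows, excluding i) and candidate set A(i) (all rows
#' except i) contributes
#' \deqn{\frac{w_{y_i}}{|P(i)|} \sum_{p \in P(i)} -\log
#'   \frac{\exp(z_i \cdot z_p/\tau)}{\sum_{a \in A(i)} \exp(z_i \cdot z_a/\tau)}}
#' summed over anchors. The class weight is `w_y = 1/N_y` (inverse class
#' frequency in `class_counts`) when `weighted = TRUE` and 1 otherwise.
#' Anchors with no positives are skipped (their normalizer is undefined);
#' if no anchor has a positive, the loss is 0 with a warning.
#'
#' @param z `N x d_e` matrix of unit-norm embeddings (`N >= 2`).
#' @param labels Integer class label per row.
#' @param tau Temperature (> 0); smaller values sharpen the distribution.
#' @param weighted Apply inverse-frequency class weights?
#' @param class_counts Named vector mapping label -> reference-set count
#'   (defaults to label counts within the batch).
#' @return Non-negative finite scalar.
#' @export
supcon_loss <- function(z, labels, tau = 0.2, weighted = FALSE,
                        class_counts = NULL) {
  z <- as.matrix(z)
  N <- nrow(z)
  assert_that(N >= 2, "supervised contrastive loss needs at least 2 rows")
  assert_that(tau > 0, "tau must be positive")
  assert_that(length(labels) == N, "one label per embedding row")
  w <- supcon_row_weights(labels, weighted, class_counts)
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  if (all(n_pos == 0)) {
    warn("no anchor has a positive; supervised contrastive loss is 0")
    return(0)
  }
  S <- tcrossprod(z) / tau
  diag(S) <- -Inf                      # exclude self from A(i)
  lse <- apply(S, 1, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  })
  Sz <- S
  diag(Sz) <- 0                        # avoid -Inf * 0 in the positive sum
  loss_i <- ifelse(n_pos > 0,
                   w * (lse - rowSums(Sz * same) / pmax(n_pos, 1)),
                   0)
  sum(loss_i)
}

supcon_row_weights <- function(labels, weighted, class_counts) {
  if (!weighted) return(rep(1, length(labels)))
  if (is.null(class_counts)) {
    class_counts <- table(labels)
  }
  cnt <- as.numeric(class_counts[as.character(labels)])
  assert_that(all(is.finite(cnt) & cnt >= 1),
              "class_counts must cover every label with a count >= 1")
  1 / cnt
}

# Gradient of supcon_loss w.r.t. z (same arguments). For anchor i define
# q_ia = softmax over A(i) of z_i.z_a/tau; then
#   dL/ds_ia = w_i * (q_ia - [a in P(i)]/|P(i)|)
# and s_ia = z_i.z_a/tau contributes z_a/tau to dz_i and z_i/tau to dz_a.
supcon_grad <- function(z, labels, tau = 0.2, weighted = FALSE,
                        class_counts = NULL) {
  z <- as.matrix(z)
  N <- nrow(z)
  w <- supcon_row_weights(labels, weighted, class_counts)
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  S <- tcrossprod(z) / tau
  diag(S) <- -Inf
  m <- apply(S, 1, max)
  E <- exp(S - m)
  Q <- E / rowSums(E)
  P <- same / pmax(n_pos, 1)
  G <- (Q - P) * w                     # row-scaled dL/ds
  G[n_pos == 0, ] <- 0
  (G %*% z + crossprod(G, z)) / tau    # anchor + candidate contributions
}
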