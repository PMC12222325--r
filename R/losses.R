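#' Focal classification loss
#'
#' Cross-entropy modulated by `(1 - p_t)^gamma` and a class weight `alpha_t`,
#' down-weighting easy examples so training concentrates on hard and
#' minority-class samples:
#' \deqn{L = \frac{1}{N}\sum_i -\alpha_{t,i} (1 - p_{t,i})^\gamma \log p_{t,i}}
#' where `p_t` is the predicted probability of the true class. With
#' `gamma = 0` and `alpha_t = 1` this reduces exactly to mean cross-entropy.
#'
#' @param p `N x C` matrix of predicted class probabilities (rows sum to 1
#'   within 1e-5).
#' @param y Integer true-class index per row (1-based column of `p`).
#' @param gamma Non-negative focusing exponent (default 2).
#' @param alpha_t Scalar class weight, or a length-C positive vector indexed
#'   by class.
#' @return Mean-reduced non-negative scalar.
#' @export
focal_loss <- function(p, y, gamma = 2, alpha_t = 1) {
  p <- as.matrix(p)
  assert_that(gamma >= 0, "gamma must be non-negative")
  assert_that(all(alpha_t > 0), "alpha_t must be positive")
  assert_that(length(y) == nrow(p), "one label per probability row")
  assert_that(all(abs(rowSums(p) - 1) < 1e-5), "probability rows must sum to 1")
  pt <- p[cbind(seq_len(nrow(p)), y)]
  if (any(pt <= 0)) {
    warn("p_t of 0 clamped to 1e-12")
    pt <- pmax(pt, 1e-12)
  }
  at <- if (length(alpha_t) == 1) rep(alpha_t, length(y)) else alpha_t[y]
  mean(-at * (1 - pt)^gamma * log(pt))
}

# Gradient of the (mean-reduced) focal loss w.r.t. the logits that produced
# p via row-softmax. Derivative through u = p_t:
#   dL/du = -alpha * ( (1-u)^g / u - g (1-u)^(g-1) log u )
# and du/dz_j = u (1[j==y] - p_j).
focal_grad_logits <- function(p, y, gamma = 2, alpha_t = 1) {
  p <- as.matrix(p)
  N <- nrow(p)
  pt <- pmax(p[cbind(seq_len(N), y)], 1e-12)
  at <- if (length(alpha_t) == 1) rep(alpha_t, N) else alpha_t[y]
  gl <- if (gamma == 0) rep(0, N) else gamma * (1 - pt)^(gamma - 1) * log(pt)
  dldu <- -at * ((1 - pt)^gamma / pt - gl)
  onehot <- matrix(0, N, ncol(p))
  onehot[cbind(seq_len(N), y)] <- 1
  (dldu * pt) * (onehot - p) / N
}

#' Smooth-L1 (Huber) box regression loss
#'
#' Per component `x = t_i - v_i`, the conventional detection form
#' `0.5 x^2` for `|x| < beta`, `|x| - 0.5 beta` otherwise (`beta = 1`),
#' summed over the four box parameters and averaged over boxes. Quadratic
#' near zero for stable gradients, linear in the tails for robustness to
#' outlier boxes.
#'
#' @param t `N x 4` matrix of predicted box deltas.
#' @param v `N x 4` matrix of target deltas.
#' @param beta Transition point between quadratic and linear regimes.
#' @return Non-negative scalar (0 when `t == v`).
#' @export
smooth_l1_loss <- function(t, v, beta = 1) {
  t <- matrix(as.numeric(t), ncol = 4)
  v <- matrix(as.numeric(v), ncol = 4)
  assert_that(all(dim(t) == dim(v)), "t and v must have matching shapes")
  x <- abs(t - v)
  per <- ifelse(x < beta, 0.5 * x^2, x - 0.5 * beta)
  mean(rowSums(per))
}

# Gradient of smooth_l1_loss w.r.t. t.
smooth_l1_grad <- function(t, v, beta = 1) {
  t <- matrix(as.numeric(t), ncol = 4)
  v <- matrix(as.numeric(v), ncol = 4)
  d <- t - v
  g <- ifelse(abs(d) < beta, d, sign(d))
  g / nrow(t)
}

#' Attention aggregation regularizer
#'
#' Combines a (negative) attention-entropy term with an L1 sparsity penalty
#' on the raw similarity scores:
#' \deqn{L_{agg} = \frac{1}{N_q}\sum_{ij} a_{ij}\log a_{ij}
#'   + \frac{1}{N_q}\sum_{ij} |s_{ij}|}
#' Minimizing the first term maximizes attention entropy (weights spread over
#' the support set); the second shrinks raw scores. The per-row entropy
#' contribution lies in `[-log N_s, 0]`, so `L_agg` may be negative. The
#' convention `0 log 0 = 0` applies. `entropy_mode = "minimize"` flips the
#' entropy sign for the opposite reading (concentrating attention).
#'
#' @param s `N_q x N_s` raw score matrix (finite).
#' @param A `N_q x N_s` row-stochastic attention weights (rows sum to 1
#'   within 1e-4).
#' @param entropy_mode `"maximize"` (default: negative entropy enters the
#'   loss) or `"minimize"`.
#' @return List with `attn_entropy` (mean per-query attention entropy,
#'   `>= 0`), `sparsity` (mean per-query L1 score mass, `>= 0`) and `L_agg`.
#' @export
aggregation_loss <- function(s, A, entropy_mode = c("maximize", "minimize")) {
  entropy_mode <- match.arg(entropy_mode)
  s <- as.matrix(s); A <- as.matrix(A)
  assert_that(all(is.finite(s)), "scores must be finite")
  assert_that(all(abs(rowSums(A) - 1) < 1e-4),
              "attention rows must sum to 1 (within 1e-4)")
  assert_that(all(A >= -1e-12), "attention weights must be non-negative")
  N_q <- nrow(A)
  alog <- ifelse(A > 0, A * log(A), 0)
  neg_entropy <- sum(alog) / N_q       # in [-log N_s, 0] per row
  sparsity <- sum(abs(s)) / N_q
  sgn <- if (entropy_mode == "maximize") 1 else -1
  list(attn_entropy = -neg_entropy, sparsity = sparsity,
       L_agg = sgn * neg_entropy + sparsity)
}

# Gradients of aggregation_loss w.r.t. s (direct sparsity term) and A
# (entropy term). The softmax dependence of A on s is handled by the FAM
# backward pass, so these are the *partial* derivatives.
aggregation_grad <- function(s, A, entropy_mode = "maximize") {
  N_q <- nrow(as.matrix(A))
  sgn <- if (entropy_mode == "maximize") 1 else -1
  list(dS = sign(s) / N_q,
       dA = sgn * (log(pmax(A, 1e-300)) + 1) / N_q)
}

#' Assemble the weighted multi-task loss bundle
#'
#' \deqn{L_{total} = L_{cls} + L_{reg} + \lambda_1 L_{agg} + \lambda_2 L_{SCL}}
#' The returned bundle satisfies the arithmetic identity exactly; any
#' non-finite component aborts with the component's name.
#'
#' @param cls,reg,agg,scl Scalar loss components.
#' @param lambda1 Weight of the aggregation regularizer.
#' @param lambda2 Weight of the supervised contrastive loss.
#' @return One-row tibble of class `loss_bundle` with columns `cls`, `reg`,
#'   `agg`, `scl`, `lambda1`, `lambda2`, `total`.
#' @export
total_loss <- function(cls, reg, agg = 0, scl = 0, lambda1 = 0.5, lambda2 = 0.5) {
  comps <- c(cls = cls, reg = reg, agg = agg, scl = scl)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad) > 0) {
    abort(sprintf("non-finite loss component: %s", paste(bad, collapse = ", ")))
  }
  out <- tibble(cls = cls, reg = reg, agg = agg, scl = scl,
                lambda1 = lambda1, lambda2 = lambda2,
                total = cls + reg + lambda1 * agg + lambda2 * scl)
  class(out) <- c("loss_bundle", class(out))
  out
}
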