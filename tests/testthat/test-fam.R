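test_that("qkv projection matches hand-computed linear maps", {
  p <- fam_params(2, 2, seed = 1)
  p$W_q <- diag(2)
  q <- matrix(c(1, 0, 0.5, 2), 2, 2, byrow = TRUE)
  s <- matrix(c(0, 0), 1, 2)
  pr <- project_qkv(q, s, p)
  expect_equal(pr$Q, q)                       # identity map passes through
  expect_true(all(pr$K == 0) && all(pr$V == 0))  # zero support -> zero K, V
  p$W_q <- matrix(c(2, 0, 0, 3), 2, 2)
  pr2 <- project_qkv(matrix(c(1, 0), 1, 2), s, p)
  expect_equal(pr2$Q, matrix(c(2, 0), 1, 2))  # hand matrix multiply
})

test_that("attention weights follow the scaled softmax closed forms", {
  # orthogonal query: zero scores -> uniform weights
  aw <- attention_weights(matrix(c(0, 0), 1, 2), rbind(c(1, 0), c(0, 1)))
  expect_equal(as.vector(aw$weights), c(0.5, 0.5))
  # single support row -> weight 1
  aw1 <- attention_weights(matrix(c(3, 1), 1, 2), matrix(c(1, 2), 1, 2))
  expect_equal(as.vector(aw1$weights), 1)
  # hand softmax: s = [0.5, 0] at d_k = 4
  aw2 <- attention_weights(matrix(c(1, 0), 1, 2), rbind(c(1, 0), c(0, 1)),
                           d_k = 4)
  sig <- exp(0.5) / (exp(0.5) + 1)
  expect_equal(as.vector(aw2$scores), c(0.5, 0))
  expect_equal(as.vector(aw2$weights), c(sig, 1 - sig), tolerance = 1e-9)
  expect_error(attention_weights(matrix(1, 1, 2),
                                 matrix(numeric(0), 0, 2)), "empty support")
})

test_that("aggregation and fusion satisfy their contracts", {
  A <- matrix(c(0.25, 0.75), 1, 2)
  V <- rbind(c(0, 4), c(4, 0))
  Fq <- matrix(c(1, 1), 1, 2)
  ag <- aggregate_and_fuse(A, V, Fq, alpha = 1)
  expect_equal(ag$F_agg, matrix(c(3, 1), 1, 2))   # hand weighted sum
  # alpha = 0: enhanced equals query bit-for-bit
  ag0 <- aggregate_and_fuse(A, V, Fq, alpha = 0)
  expect_identical(ag0$F_enhanced, Fq)
  # identical value rows: any convex combination returns that row
  Vc <- rbind(c(2, 5), c(2, 5))
  agc <- aggregate_and_fuse(matrix(c(0.5, 0.5), 1, 2), Vc, Fq, alpha = 1)
  expect_equal(agc$F_agg, matrix(c(2, 5), 1, 2))
})

test_that("attention rows are stochastic and shift-invariant", {
  set.seed(3)
  for (rep in 1:5) {
    Q <- matrix(rnorm(4 * 6), 4, 6)
    K <- matrix(rnorm(7 * 6), 7, 6)
    aw <- attention_weights(Q, K)
    expect_true(all(abs(rowSums(aw$weights) - 1) < 1e-6))
    expect_true(all(aw$weights >= 0 & aw$weights <= 1))
    # adding a constant to a score row leaves that row's weights unchanged
    s2 <- aw$scores; s2[2, ] <- s2[2, ] + 3.7
    w2 <- pestfsod:::row_softmax(s2)
    expect_equal(w2[2, ], aw$weights[2, ], tolerance = 1e-6)
  }
})

test_that("permuting support rows leaves the aggregate unchanged", {
  set.seed(4)
  D <- 5
  p <- fam_params(D, D, seed = 2)
  Fq <- matrix(rnorm(3 * D), 3, D)
  Fs <- matrix(rnorm(6 * D), 6, D)
  out1 <- fam_forward(Fq, Fs, p)
  perm <- sample(6)
  out2 <- fam_forward(Fq, Fs[perm, ], p)
  expect_equal(out2$F_agg, out1$F_agg, tolerance = 1e-10)
  expect_equal(out2$F_enhanced, out1$F_enhanced, tolerance = 1e-10)
})

test_that("each aggregated row lies in the convex hull of the value rows", {
  set.seed(5)
  # d_k = 1: hull is the interval [min V, max V]
  A <- pestfsod:::row_softmax(matrix(rnorm(12), 4, 3))
  V1 <- matrix(rnorm(3), 3, 1)
  g1 <- A %*% V1
  expect_true(all(g1 >= min(V1) - 1e-12 & g1 <= max(V1) + 1e-12))
  # d_k = 2: vertex enumeration via the convex-hull polygon
  V2 <- matrix(rnorm(8), 4, 2)
  A2 <- pestfsod:::row_softmax(matrix(rnorm(12), 3, 4))
  G <- A2 %*% V2
  hull <- grDevices::chull(V2)
  poly <- V2[hull, , drop = FALSE]
  inside <- pracma::inpolygon(G[, 1], G[, 2], poly[, 1], poly[, 2],
                              boundary = TRUE)
  expect_true(all(inside))
})

test_that("analytic FAM gradients match finite differences", {
  set.seed(6)
  D <- 5; dk <- 3
  Fq <- matrix(rnorm(3 * D), 3, D)
  Fs <- matrix(rnorm(4 * D), 4, D)
  p <- fam_params(D, dk, alpha = 0.6, seed = 3)
  loss_fn <- function(p) sum(sin(fam_forward(Fq, Fs, p)$F_enhanced))
  fc <- fam_forward(Fq, Fs, p)
  gb <- pestfsod:::fam_backward(fc, cos(fc$F_enhanced))
  eps <- 1e-6
  for (nm in c("W_q", "W_k", "W_v", "W_o")) {
    th <- p[[nm]]
    for (i in sample(length(th), 4)) {
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      expect_equal(gb[[nm]][i], fd, tolerance = 1e-4)
    }
  }
  p1 <- p; p1$alpha <- p$alpha + eps
  p2 <- p; p2$alpha <- p$alpha - eps
  expect_equal(gb$alpha, (loss_fn(p1) - loss_fn(p2)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("gradients through the aggregation regularizer match finite differences", {
  set.seed(7)
  D <- 4; dk <- 3
  Fq <- matrix(rnorm(2 * D), 2, D)
  Fs <- matrix(rnorm(3 * D), 3, D)
  p <- fam_params(D, dk, alpha = 0.5, seed = 4)
  agg_of <- function(p) {
    fc <- fam_forward(Fq, Fs, p)
    aggregation_loss(fc$scores, fc$weights)$L_agg
  }
  fc <- fam_forward(Fq, Fs, p)
  ag <- pestfsod:::aggregation_grad(fc$scores, fc$weights)
  gb <- pestfsod:::fam_backward(fc, matrix(0, 2, D),
                                dS_extra = ag$dS, dA_extra = ag$dA)
  eps <- 1e-6
  for (nm in c("W_q", "W_k")) {
    for (i in sample(length(p[[nm]]), 3)) {
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (agg_of(p1) - agg_of(p2)) / (2 * eps)
      expect_equal(gb[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})
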