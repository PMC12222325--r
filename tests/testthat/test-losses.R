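test_that("focal loss matches its closed forms", {
  p <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(focal_loss(p, 1, gamma = 0, alpha_t = 1), log(2))
  expect_equal(focal_loss(p, 1, gamma = 2, alpha_t = 1), 0.25 * log(2))
  # perfect prediction contributes zero regardless of gamma / alpha
  p1 <- matrix(c(1, 0), 1, 2)
  expect_equal(focal_loss(p1, 1, gamma = 2, alpha_t = 3), 0)
  expect_warning(focal_loss(matrix(c(0, 1), 1, 2), 1), "clamped")
})

test_that("with gamma = 0 focal loss reduces exactly to cross-entropy", {
  set.seed(1)
  logits <- matrix(rnorm(20 * 4), 20, 4)
  P <- exp(logits) / rowSums(exp(logits))
  y <- sample(1:4, 20, replace = TRUE)
  ce <- mean(-log(P[cbind(1:20, y)]))
  expect_equal(focal_loss(P, y, gamma = 0, alpha_t = 1), ce, tolerance = 1e-12)
})

test_that("focal loss is bounded above by cross-entropy for gamma > 0", {
  set.seed(2)
  for (rep in 1:5) {
    P <- matrix(runif(15 * 3) + 0.05, 15, 3)
    P <- P / rowSums(P)
    y <- sample(1:3, 15, replace = TRUE)
    expect_lte(focal_loss(P, y, gamma = 2, alpha_t = 1),
               focal_loss(P, y, gamma = 0, alpha_t = 1) + 1e-12)
  }
})

test_that("smooth-L1 matches closed forms and is C1 at the transition", {
  z4 <- matrix(0, 1, 4)
  expect_equal(smooth_l1_loss(z4, z4), 0)
  expect_equal(smooth_l1_loss(matrix(c(0.5, 0, 0, 0), 1), z4), 0.125)
  expect_equal(smooth_l1_loss(matrix(c(2, 0, 0, 0), 1), z4), 1.5)
  # continuity and matching one-sided derivatives at |x| = beta
  f <- function(x) smooth_l1_loss(matrix(c(x, 0, 0, 0), 1), z4)
  eps <- 1e-6
  expect_equal(f(1 - eps), f(1 + eps), tolerance = 1e-5)
  d_lo <- (f(1 - eps) - f(1 - 2 * eps)) / eps
  d_hi <- (f(1 + 2 * eps) - f(1 + eps)) / eps
  expect_equal(d_lo, d_hi, tolerance = 1e-4)
})

test_that("focal and smooth-L1 gradients match finite differences", {
  set.seed(3)
  logits <- matrix(rnorm(8 * 3), 8, 3)
  y <- sample(1:3, 8, replace = TRUE)
  sm <- function(l) exp(l) / rowSums(exp(l))
  g <- pestfsod:::focal_grad_logits(sm(logits), y, gamma = 2, alpha_t = c(1, 2, 0.5))
  eps <- 1e-6
  for (i in sample(length(logits), 6)) {
    l1 <- logits; l1[i] <- l1[i] + eps
    l2 <- logits; l2[i] <- l2[i] - eps
    fd <- (focal_loss(sm(l1), y, 2, c(1, 2, 0.5)) -
             focal_loss(sm(l2), y, 2, c(1, 2, 0.5))) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
  t0 <- matrix(rnorm(12), 3, 4); v0 <- matrix(rnorm(12), 3, 4)
  gs <- pestfsod:::smooth_l1_grad(t0, v0)
  for (i in sample(12, 5)) {
    t1 <- t0; t1[i] <- t1[i] + eps
    t2 <- t0; t2[i] <- t2[i] - eps
    fd <- (smooth_l1_loss(t1, v0) - smooth_l1_loss(t2, v0)) / (2 * eps)
    expect_equal(gs[i], fd, tolerance = 1e-4)
  }
})

test_that("aggregation loss matches its closed forms", {
  # one-hot attention with zero scores: everything vanishes
  A1 <- rbind(c(1, 0, 0), c(0, 0, 1))
  r1 <- aggregation_loss(matrix(0, 2, 3), A1)
  expect_equal(r1$L_agg, 0)
  expect_equal(r1$attn_entropy, 0)
  # uniform attention over 4 support samples: L_agg = -log 4
  A2 <- matrix(0.25, 1, 4)
  r2 <- aggregation_loss(matrix(0, 1, 4), A2)
  expect_equal(r2$L_agg, -log(4), tolerance = 1e-12)
  expect_equal(r2$attn_entropy, log(4), tolerance = 1e-12)
  # sparsity: sum of absolute scores per query
  r3 <- aggregation_loss(matrix(c(1, -1), 1, 2), matrix(0.5, 1, 2))
  expect_equal(r3$sparsity, 2)
  # entropy sign switch
  r4 <- aggregation_loss(matrix(0, 1, 4), A2, entropy_mode = "minimize")
  expect_equal(r4$L_agg, log(4), tolerance = 1e-12)
  expect_error(aggregation_loss(matrix(0, 1, 2), matrix(c(0.9, 0.3), 1, 2)),
               "sum to 1")
})

test_that("entropy term stays within [-log N_s, 0] per row and sparsity is non-negative", {
  set.seed(4)
  for (rep in 1:5) {
    s <- matrix(rnorm(4 * 5), 4, 5)
    A <- pestfsod:::row_softmax(s)
    r <- aggregation_loss(s, A)
    alog <- sum(A * log(A)) / 4
    expect_gte(alog, -log(5))
    expect_lte(alog, 0)
    expect_gte(r$sparsity, 0)
    # double-loop oracle
    ent <- 0; spr <- 0
    for (i in 1:4) for (j in 1:5) {
      ent <- ent + A[i, j] * log(A[i, j]); spr <- spr + abs(s[i, j])
    }
    expect_equal(r$L_agg, ent / 4 + spr / 4, tolerance = 1e-6)
  }
})

test_that("the total loss is the exact weighted sum of its components", {
  b <- total_loss(1, 2, 3, 4, lambda1 = 0.5, lambda2 = 0.5)
  expect_equal(b$total, 6.5)
  expect_equal(b$total, b$cls + b$reg + b$lambda1 * b$agg + b$lambda2 * b$scl,
               tolerance = 1e-12)
  expect_equal(total_loss(0, 0, 0, 0)$total, 0)
  b2 <- total_loss(1.3, 0.7, 5, 9, lambda1 = 0, lambda2 = 0)
  expect_equal(b2$total, 2)                  # plain detection objective
  expect_error(total_loss(1, NaN, 0, 0), "reg")
})
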