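test_that("IoU matches closed forms and a pixel-grid oracle", {
  a <- c(0, 0, 10, 10)
  expect_equal(as.vector(box_iou(a, a)), 1)
  expect_equal(as.vector(box_iou(a, c(20, 20, 30, 30))), 0)
  b <- c(5, 0, 15, 10)
  expect_equal(as.vector(box_iou(a, b)), 1 / 3, tolerance = 1e-12)
  expect_equal(iou_pixel_oracle(a, b), 1 / 3, tolerance = 0.01)
  expect_warning(z <- box_iou(c(0, 0, 0, 5), a), "degenerate")
  expect_equal(as.vector(z), 0)
})

test_that("greedy matching enforces one-to-one assignment", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  m1 <- match_detections(gt, 0.9, gt)
  expect_equal(sum(m1$tp), 1)
  expect_equal(m1$fn, 0L)
  # two detections on one ground truth: second is a false positive
  dets <- rbind(c(0, 0, 10, 10), c(0.5, 0, 10.5, 10))
  m2 <- match_detections(dets, c(0.9, 0.8), gt)
  expect_equal(sum(m2$tp), 1)
})

test_that("greedy TP count never exceeds the optimal assignment", {
  brute_optimal <- function(iou, thr = 0.5) {
    nd <- nrow(iou); ng <- ncol(iou)
    best <- 0
    assignments <- function(d, used) {
      if (d > nd) return(0)
      res <- assignments(d + 1, used)
      for (g in seq_len(ng)) {
        if (!used[g] && iou[d, g] > thr) {
          u2 <- used; u2[g] <- TRUE
          res <- max(res, 1 + assignments(d + 1, u2))
        }
      }
      res
    }
    assignments(1, rep(FALSE, ng))
  }
  set.seed(10)
  for (rep in 1:25) {
    nd <- sample(1:6, 1); ng <- sample(1:6, 1)
    mk <- function(n) {
      x <- runif(n, 0, 30); y <- runif(n, 0, 30)
      cbind(x, y, x + runif(n, 5, 15), y + runif(n, 5, 15))
    }
    d <- mk(nd); g <- mk(ng)
    sc <- runif(nd)
    mm <- match_detections(d, sc, g)
    opt <- brute_optimal(box_iou(d[order(sc, decreasing = TRUE), , drop = FALSE], g))
    expect_lte(sum(mm$tp), opt)
    expect_equal(mm$fn, ng - as.integer(sum(mm$tp)))
  }
})

test_that("average precision integrates the monotone PR envelope", {
  expect_equal(average_precision(TRUE, 1)$ap, 1)
  expect_equal(average_precision(c(FALSE, FALSE), 3)$ap, 0)
  # the hand-worked ranked [TP, FP, TP] case with 2 ground truths
  r <- average_precision(c(TRUE, FALSE, TRUE), 2)
  expect_equal(r$ap, 1 * 0.5 + (2 / 3) * 0.5, tolerance = 1e-12)
  expect_equal(r$pr$recall, c(0.5, 0.5, 1))
  expect_equal(r$pr$precision, c(1, 0.5, 2 / 3))
})

test_that("AP depends only on the ranking, not the score scale", {
  m <- toy_manifest(list(1, 1, 1))
  mk_dets <- function(scores) tibble::tibble(
    image_id = 1:3, category_id = 1, score = scores,
    x = c(7, 30, 7), y = c(6, 30, 6), w = 10, h = 12)
  d1 <- mk_dets(c(0.9, 0.5, 0.3))
  d2 <- mk_dets(plogis(5 * c(0.9, 0.5, 0.3) - 2))   # monotone transform
  e1 <- evaluate_detections(d1, m)
  e2 <- evaluate_detections(d2, m)
  expect_equal(e1$per_class$ap, e2$per_class$ap, tolerance = 1e-12)
})

test_that("precision/recall identities hold on the accumulated counts", {
  m <- toy_manifest(list(1, 1, 2, 2))
  dets <- tibble::tibble(
    image_id = c(1, 2, 2, 3), category_id = c(1, 1, 1, 2),
    score = c(0.9, 0.8, 0.7, 0.6),
    x = c(7, 7, 40, 7), y = c(6, 6, 40, 6), w = 10, h = 12)
  ev <- evaluate_detections(dets, m)
  pc <- ev$per_class
  expect_equal(pc$tp + pc$fp, pc$n_det)
  expect_equal(pc$tp + pc$fn, pc$n_gt)
  c1 <- ev$pr_curves[["1"]]
  expect_equal(tail(c1$precision, 1), pc$tp[1] / (pc$tp[1] + pc$fp[1]))
  expect_equal(tail(c1$recall, 1), pc$tp[1] / pc$n_gt[1])
})

test_that("split means obey their definitions and the consistency identity", {
  split <- make_split(1:20, 15, seed = 2)
  set.seed(11)
  ap <- setNames(runif(20), 1:20)
  sm <- split_map(ap, split)
  expect_equal(sm$bap, mean(ap[as.character(split$base)]), tolerance = 1e-12)
  expect_equal(sm$nap, mean(ap[as.character(split$novel)]), tolerance = 1e-12)
  expect_equal(sm$map, (15 * sm$bap + 5 * sm$nap) / 20, tolerance = 1e-9)
  # all APs equal -> all three means equal that value
  smc <- split_map(setNames(rep(0.6, 20), 1:20), split)
  expect_equal(unlist(smc), c(bap = 0.6, nap = 0.6, map = 0.6))
  expect_error(split_map(ap[1:19], split), "missing")
})

test_that("the confusion matrix books every ground truth and detection once", {
  m <- toy_manifest(list(1, 2, 1))
  perfect <- m$annotations |>
    dplyr::mutate(score = 0.95) |>
    dplyr::select("image_id", "category_id", "score", "x", "y", "w", "h")
  cm <- confusion_matrix(perfect, m)
  expect_equal(diag(cm)[1:2], setNames(c(2L, 1L), c("1", "2")))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # no detections: every ground truth falls in the background column
  cm0 <- confusion_matrix(perfect[0, ], m)
  expect_equal(cm0[, "background"], setNames(c(2L, 1L, 0L), c("1", "2", "background")))
  # row sums over true classes equal the per-class ground-truth counts
  noisy <- perfect
  noisy$category_id[1] <- 2
  cm2 <- confusion_matrix(noisy, m)
  expect_equal(unname(rowSums(cm2)[1:2]), c(2, 1))
})

test_that("per-class AP agrees with an independent naive evaluator", {
  naive_ap <- function(dets, manifest, cls, thr = 0.5) {
    g <- manifest$annotations[manifest$annotations$category_id == cls, ]
    d <- dets[dets$category_id == cls, ]
    d <- d[order(-d$score), ]
    used <- rep(FALSE, nrow(g))
    tp <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      gi <- which(g$image_id == d$image_id[i] & !used)
      if (length(gi) == 0) next
      ious <- sapply(gi, function(k) as.vector(box_iou(
        c(d$x[i], d$y[i], d$x[i] + d$w[i], d$y[i] + d$h[i]),
        c(g$x[k], g$y[k], g$x[k] + g$w[k], g$y[k] + g$h[k]))))
      j <- gi[which.max(ious)]
      if (max(ious) > thr) { tp[i] <- TRUE; used[j] <- TRUE }
    }
    rec <- cumsum(tp) / nrow(g)
    prec <- cumsum(tp) / seq_along(tp)
    env <- rev(cummax(rev(prec)))
    sum((rec - c(0, head(rec, -1))) * env)
  }
  set.seed(12)
  m <- toy_manifest(lapply(1:8, function(i) sample(1:2, 1)), boxes_per_image = 2)
  dets <- m$annotations |>
    dplyr::mutate(score = runif(dplyr::n()),
                  x = .data$x + runif(dplyr::n(), -4, 4),
                  y = .data$y + runif(dplyr::n(), -4, 4)) |>
    dplyr::select("image_id", "category_id", "score", "x", "y", "w", "h")
  extra <- dets[1:3, ] |> dplyr::mutate(x = .data$x + 30, score = runif(3))
  dets <- dplyr::bind_rows(dets, extra)
  ev <- evaluate_detections(dets, m)
  for (cls in 1:2) {
    expect_equal(ev$per_class$ap[ev$per_class$category_id == cls],
                 naive_ap(dets, m, cls), tolerance = 1e-6)
  }
})

test_that("tidy, glance and autoplot work on an evaluation report", {
  m <- toy_manifest(list(1, 2))
  dets <- m$annotations |>
    dplyr::mutate(score = 0.9) |>
    dplyr::select("image_id", "category_id", "score", "x", "y", "w", "h")
  ev <- evaluate_detections(dets, m)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(glance(ev)$map, 1)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})
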