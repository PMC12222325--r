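# Small configurations keep these tests fast; the full-scale pipeline run
# lives in test-acceptance.R.

small_cfg <- function(...) model_config(image_size = 64, ...)

make_small_data <- function(n_per_class = 4, n_classes = 3, seed = 1) {
  sp <- scene_spec(n_classes = n_classes, image_size = c(64, 64),
                   size_range_px = c(14, 28), objects_per_image = c(1, 2))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  m <- generate_dataset(sp, rep(n_per_class, n_classes), dir, seed = seed)
  m
}

test_that("target assignment matches IoU closed forms and tie rules", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  a <- assign_targets(gt, gt, 5L, iou_pos = 0.6)
  expect_equal(a$labels, 5L)
  expect_equal(as.vector(a$targets), rep(0, 4))
  # IoU 1/3 below the 0.6 threshold: background
  b <- assign_targets(matrix(c(0, 0, 10, 10), 1),
                      matrix(c(5, 0, 15, 10), 1), 2L, iou_pos = 0.6)
  expect_equal(b$labels, 0L)
  # two ground truths tying in IoU: the lower index wins
  gts <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  d <- assign_targets(matrix(c(0, 0, 10, 10), 1), gts, c(7L, 9L), iou_pos = 0.5)
  expect_equal(d$gt_index, 1L)
  expect_equal(d$labels, 7L)
  # no ground truths: everything background
  e <- assign_targets(gt, NULL, integer(0), iou_pos = 0.5)
  expect_equal(e$labels, 0L)
})

test_that("assignment agrees with a brute-force double loop on random boxes", {
  set.seed(20)
  mk <- function(n) {
    x <- runif(n, 0, 40); y <- runif(n, 0, 40)
    cbind(x, y, x + runif(n, 4, 20), y + runif(n, 4, 20))
  }
  for (rep in 1:5) {
    props <- mk(50); gts <- mk(8); labs <- sample(1:4, 8, replace = TRUE)
    a <- assign_targets(props, gts, labs, iou_pos = 0.5)
    for (i in seq_len(nrow(props))) {
      ious <- sapply(seq_len(nrow(gts)), function(j)
        as.vector(box_iou(props[i, ], gts[j, ])))
      if (max(ious) >= 0.5) {
        expect_equal(a$labels[i], labs[which.max(ious)])
      } else {
        expect_equal(a$labels[i], 0L)
      }
    }
  }
})

test_that("box delta encoding and decoding are inverse maps", {
  set.seed(21)
  p <- cbind(runif(10, 0, 30), runif(10, 0, 30), 0, 0)
  p[, 3] <- p[, 1] + runif(10, 5, 20); p[, 4] <- p[, 2] + runif(10, 5, 20)
  g <- p + matrix(rnorm(40, 0, 2), 10, 4)
  g[, 3] <- pmax(g[, 3], g[, 1] + 2); g[, 4] <- pmax(g[, 4], g[, 2] + 2)
  d <- pestfsod:::encode_deltas(p, g)
  back <- pestfsod:::decode_deltas(p, d)
  expect_equal(back, unname(g), tolerance = 1e-9)
})

test_that("NMS keeps the higher-scoring duplicate", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  keep <- nms(b, c(0.9, 0.8), 0.5)
  expect_equal(keep, 1L)
  # disjoint boxes all survive
  b2 <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30))
  expect_length(nms(b2, c(0.5, 0.9), 0.5), 2)
})

test_that("one training iteration on a toy set yields finite losses and a checkpoint", {
  m <- make_small_data()
  mod <- init_detector(small_cfg(), 1:3, seed = 1)
  cfg <- train_config(lr = 0.1, iters = 2, eval_interval = 10, batch_size = 2)
  tr <- pestfsod:::train_detector(model = mod, manifest = m, cfg = cfg)
  expect_true(all(is.finite(tr$history$total)))
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(tr, p)
  expect_true(file.exists(p))
})

test_that("training is deterministic under a fixed seed", {
  m <- make_small_data()
  cfg <- train_config(lr = 0.1, iters = 5, eval_interval = 100, batch_size = 2,
                      seed = 3)
  t1 <- pestfsod:::train_detector(init_detector(small_cfg(), 1:3, seed = 1), m, cfg)
  t2 <- pestfsod:::train_detector(init_detector(small_cfg(), 1:3, seed = 1), m, cfg)
  expect_equal(t1$history$total, t2$history$total, tolerance = 1e-12)
  expect_equal(t1$par, t2$par, tolerance = 1e-12)
})

test_that("checkpoint round-trip reproduces predictions bit-for-bit", {
  m <- make_small_data()
  mod <- pestfsod:::train_detector(init_detector(small_cfg(), 1:3, seed = 1), m,
                        train_config(lr = 0.1, iters = 10, eval_interval = 100,
                                     batch_size = 2))
  d1 <- detect(mod, m)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(mod, p)
  mod2 <- load_checkpoint(p)
  d2 <- detect(mod2, m)
  expect_identical(d1, d2)
})

test_that("ground-truth proposals with an imprinted classifier give mAP 1 (plumbing oracle)", {
  m <- make_small_data(n_per_class = 3)
  mod <- init_detector(small_cfg(), 1:3, seed = 2)
  # perfect-classifier stub: imprint each class column with the mean RoI
  # feature of its ground-truth boxes; zero regression leaves boxes intact
  cache <- pestfsod:::prepare_image_cache(mod, m)
  bank <- pestfsod:::build_support_bank(mod, m, cache)
  for (cl in 1:3) {
    proto <- colMeans(bank$features[bank$labels == cl, , drop = FALSE])
    mod$par$W_cls[, cl] <- 8 * proto / sqrt(sum(proto^2))
  }
  dets <- detect(mod, m, proposal_source = "groundtruth", cache = cache)
  ev <- evaluate_detections(dets, m)
  expect_equal(ev$map, 1)
})

test_that("enabling FAM and SCL in any combination keeps training finite", {
  m <- make_small_data(n_per_class = 3)
  split <- make_split(1:3, 2, seed = 1)
  mod <- init_detector(small_cfg(), split$base, seed = 1)
  bm <- train_base(mod, m, train_config(lr = 0.1, iters = 5,
                                        eval_interval = 100, batch_size = 2))
  ks <- suppressWarnings(sample_kshot(m, split, 2, seed = 1))
  for (fam in c(FALSE, TRUE)) {
    for (scl in c(FALSE, TRUE)) {
      ft <- suppressWarnings(finetune(
        bm, ks, split, shot_config(3),
        train_config(lr = 0.05, iters = 5, eval_interval = 100, batch_size = 2),
        use_fam = fam, use_scl = scl))
      expect_true(all(is.finite(ft$history$total)))
      if (fam) expect_gt(mean(ft$history$agg != 0), 0)
      if (!fam && !scl) {
        expect_true(all(ft$history$agg == 0) && all(ft$history$scl == 0))
      }
    }
  }
})

test_that("fine-tuning fails loudly when a novel class has no shots", {
  m <- make_small_data(n_per_class = 3)
  split <- make_split(1:3, 2, seed = 1)
  mod <- init_detector(small_cfg(), split$base, seed = 1)
  bm <- train_base(mod, m, train_config(lr = 0.1, iters = 3,
                                        eval_interval = 100, batch_size = 2))
  ks <- suppressWarnings(sample_kshot(m, split, 2, seed = 1))
  ks$annotations <- ks$annotations[ks$annotations$category_id %in% split$base, ]
  expect_error(finetune(bm, ks, split, shot_config(3),
                        train_config(lr = 0.05, iters = 2, batch_size = 2)),
               "absent")
})

test_that("identical inputs give identical detections", {
  m <- make_small_data(n_per_class = 2)
  mod <- pestfsod:::train_detector(init_detector(small_cfg(), 1:3, seed = 1), m,
                        train_config(lr = 0.1, iters = 5, eval_interval = 100,
                                     batch_size = 2))
  expect_identical(detect(mod, m), detect(mod, m))
})
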