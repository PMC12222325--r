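test_that("generated datasets meet the requested per-class image profile exactly", {
  sp <- tiny_spec()
  out <- withr::local_tempdir()
  m <- generate_dataset(sp, c(3, 2, 4), out, seed = 7)
  cnt <- manifest_counts(m)
  expect_equal(cnt$n_images, c(3L, 2L, 4L))
  expect_true(all(cnt$n_boxes >= cnt$n_images))
})

test_that("re-parsing the emitted COCO JSON reproduces the counts (recount oracle)", {
  sp <- tiny_spec()
  out <- withr::local_tempdir()
  m <- generate_dataset(sp, c(5, 5, 0), out, seed = 3)
  m2 <- read_coco(file.path(out, "annotations.json"))
  expect_equal(manifest_counts(m), manifest_counts(m2))
  expect_equal(nrow(m2$annotations), nrow(m$annotations))
})

test_that("identical spec and seed give a byte-identical annotation file", {
  sp <- tiny_spec()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(sp, c(2, 2, 2), d1, seed = 11)
  generate_dataset(sp, c(2, 2, 2), d2, seed = 11)
  h1 <- unname(tools::md5sum(file.path(d1, "annotations.json")))
  h2 <- unname(tools::md5sum(file.path(d2, "annotations.json")))
  expect_identical(h1, h2)
})

test_that("an all-zero profile yields a valid empty COCO file with categories only", {
  sp <- tiny_spec()
  out <- withr::local_tempdir()
  m <- generate_dataset(sp, c(0, 0, 0), out, seed = 1)
  m2 <- read_coco(file.path(out, "annotations.json"))
  expect_equal(nrow(m2$images), 0)
  expect_equal(nrow(m2$annotations), 0)
  expect_equal(m2$categories$category_id, 1:3)
})

test_that("all emitted boxes satisfy the image-bound invariant", {
  sp <- tiny_spec()
  out <- withr::local_tempdir()
  m <- generate_dataset(sp, c(4, 4, 4), out, seed = 9)
  wh <- m$images[match(m$annotations$image_id, m$images$image_id), ]
  expect_true(all(m$annotations$x >= 0 & m$annotations$y >= 0))
  expect_true(all(m$annotations$x + m$annotations$w <= wh$width))
  expect_true(all(m$annotations$y + m$annotations$h <= wh$height))
})

test_that("box-count imbalance follows the requested image-count imbalance", {
  sp <- scene_spec(n_classes = 2, image_size = c(64, 64),
                   size_range_px = c(12, 20), objects_per_image = c(1, 1))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  m1 <- generate_dataset(sp, c(4, 4), out1, seed = 5)
  m2 <- generate_dataset(sp, c(2, 8), out2, seed = 5)
  r1 <- with(manifest_counts(m1), max(n_boxes) / min(n_boxes))
  r2 <- with(manifest_counts(m2), max(n_boxes) / min(n_boxes))
  expect_gt(r2, r1)
})

test_that("stratified split is disjoint and respects the ratio per class", {
  classes <- rep(1:3, times = c(10, 15, 5))
  m <- toy_manifest(as.list(classes))
  tt <- split_train_test(m, ratio = 0.8, seed = 4)
  expect_length(intersect(tt$train$images$image_id, tt$test$images$image_id), 0)
  expect_equal(sort(c(tt$train$images$image_id, tt$test$images$image_id)),
               m$images$image_id)
  for (cl in 1:3) {
    n_tr <- manifest_counts(tt$train)$n_images[cl]
    n_all <- manifest_counts(m)$n_images[cl]
    expect_lte(abs(n_tr - round(0.8 * n_all)), 1)
  }
})

test_that("a class with a single image goes to train with a warning", {
  m <- toy_manifest(list(1, 1, 1, 2))
  expect_warning(tt <- split_train_test(m, 0.8, seed = 1), "< 2 images")
  expect_true(2 %in% tt$train$annotations$category_id)
})

test_that("published benchmark counts load and sum to the printed totals", {
  cnt <- pestdet20_counts()
  expect_equal(nrow(cnt), 20)
  expect_equal(sum(cnt$train_images), 5076)
  expect_equal(sum(cnt$test_images), 1177)
  expect_equal(sum(cnt$train_boxes), 5590)
  expect_equal(sum(cnt$test_boxes), 1292)
  expect_equal(range(cnt$train_images), c(92, 400))
})

test_that("a 10% scaled profile preserves the benchmark's shape", {
  cnt <- pestdet20_counts()
  p <- scale_profile(cnt$train_images, 0.1)
  expect_equal(p, as.integer(round(cnt$train_images * 0.1)))
  expect_equal(range(p), c(9, 40))
  expect_lte(abs(sum(p) - 508), 2)
})
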