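#' Specify a procedural pest-scene generator
#'
#' A `scene_spec` describes how synthetic detection scenes are rendered:
#' image geometry, the per-class shape/colour palette, object size range,
#' objects per image, background texture, and how much same-image boxes may
#' overlap. The generator emulates the structural difficulties of small
#' field-collected pest benchmarks — small targets, multiple scales, clutter,
#' class imbalance — with procedurally separable classes, so that few-shot
#' detection sanity runs can succeed in principle while remaining non-trivial.
#'
#' @param image_size Integer `c(width, height)` in pixels.
#' @param n_classes Number of object classes (category ids are `1:n_classes`).
#' @param size_range_px Numeric `c(min, max)` object side length in pixels;
#'   `min` must be at least 4 and `max` at most `min(image_size)`.
#' @param objects_per_image Integer `c(min, max)` objects rendered per image.
#' @param background List with `color` (RGB in \[0,1\]) and `noise_sd`
#'   (per-pixel Gaussian texture amplitude), plus `clutter`, the number of
#'   unannotated faint distractor blobs per image.
#' @param overlap_max_iou Maximum pairwise IoU allowed between same-image
#'   objects, in \[0, 1).
#' @param hard_background Fraction in \[0,1\] blending object colour toward
#'   the background colour (camouflage knob); 0 disables it.
#' @param texture_amp Amplitude of within-object texture noise.
#' @param palette Optional tibble overriding the default per-class palette;
#'   needs columns `category_id`, `shape`, `r`, `g`, `b`.
#'
#' @return An object of class `scene_spec`.
#' @export
#' @examples
#' spec <- scene_spec(n_classes = 4, image_size = c(96, 96))
#' sc <- generate_scene(spec, class_quota = c(1, 0, 1, 0), seed = 1)
#' dim(sc$image)
#' sc$boxes
scene_spec <- function(image_size = c(96, 96),
                       n_classes = 6,
                       size_range_px = c(16, 40),
                       objects_per_image = c(1, 3),
                       background = list(color = c(0.45, 0.42, 0.38),
                                         noise_sd = 0.03, clutter = 3),
                       overlap_max_iou = 0.1,
                       hard_background = 0,
                       texture_amp = 0.06,
                       palette = NULL) {
  image_size <- as.integer(image_size)
  assert_that(length(image_size) == 2 && all(image_size >= 16),
              "image_size must be two integers >= 16")
  assert_that(is_count(n_classes) && n_classes >= 1, "n_classes must be a positive count")
  assert_that(size_range_px[1] >= 4 && size_range_px[2] <= min(image_size),
              "size_range_px must satisfy min >= 4 and max <= min(image_size)")
  assert_that(size_range_px[1] <= size_range_px[2], "size_range_px must be increasing")
  assert_that(overlap_max_iou >= 0 && overlap_max_iou < 1,
              "overlap_max_iou must be in [0, 1)")
  assert_that(hard_background >= 0 && hard_background <= 1,
              "hard_background must be in [0, 1]")
  assert_that(all(objects_per_image >= 0) && objects_per_image[1] <= objects_per_image[2],
              "objects_per_image must be a non-negative increasing range")
  background$color <- background$color %||% c(0.45, 0.42, 0.38)
  background$noise_sd <- background$noise_sd %||% 0.03
  background$clutter <- background$clutter %||% 3
  if (is.null(palette)) palette <- default_palette(n_classes)
  assert_that(nrow(palette) == n_classes, "palette must have one row per class")
  structure(
    list(image_size = image_size, n_classes = as.integer(n_classes),
         size_range_px = as.numeric(size_range_px),
         objects_per_image = as.integer(objects_per_image),
         background = background, overlap_max_iou = overlap_max_iou,
         hard_background = hard_background, texture_amp = texture_amp,
         palette = palette),
    class = "scene_spec"
  )
}

# Per-class procedural signature: a base shape cycled through a small set and
# a saturated colour spread around the hue wheel. Classes are separable by
# colour+shape; texture and size variation preserve difficulty.
default_palette <- function(n_classes) {
  shapes <- c("ellipse", "rectangle", "triangle", "diamond", "blob")
  hues <- (seq_len(n_classes) - 1) / n_classes
  cols <- grDevices::hsv(hues, s = 0.85, v = 0.9)
  rgb <- t(grDevices::col2rgb(cols)) / 255
  tibble(
    category_id = seq_len(n_classes),
    shape = shapes[((seq_len(n_classes) - 1) %% length(shapes)) + 1],
    r = rgb[, 1], g = rgb[, 2], b = rgb[, 3]
  )
}

#' Render one synthetic scene
#'
#' Draws `class_quota[c]` objects of each class `c` onto a textured
#' background using rejection sampling for placement: a candidate position is
#' accepted only if its box overlaps every already-placed box with IoU at most
#' `spec$overlap_max_iou`. After 50 failed attempts an object is skipped with
#' a warning (bounded runtime, never an infinite loop). Each rendered object
#' contributes one tight bounding box (the pixel extent of its mask).
#'
#' @param spec A [scene_spec()].
#' @param class_quota Non-negative integer vector of length `spec$n_classes`:
#'   number of objects of each class to place.
#' @param seed Optional integer seed; a fixed seed gives bit-identical output.
#' @return List with `image` (height x width x 3 array in \[0,1\]) and
#'   `boxes`, a tibble with columns `category_id`, `x`, `y`, `w`, `h`
#'   (COCO-style 0-based pixel floats).
#' @export
generate_scene <- function(spec, class_quota, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  assert_that(length(class_quota) == spec$n_classes && all(class_quota >= 0),
              "class_quota must be non-negative with one entry per class")
  with_seed(seed, {
    W <- spec$image_size[1]; H <- spec$image_size[2]
    img <- render_background(spec, W, H)
    order_cls <- rep(seq_len(spec$n_classes), times = class_quota)
    placed <- matrix(numeric(0), ncol = 4) # xyxy of accepted candidate extents
    rows <- list()
    for (cls in order_cls) {
      obj <- place_object(spec, cls, placed, W, H)
      if (is.null(obj)) {
        warn(sprintf("placement failed for an object of class %d after 50 retries; skipped", cls))
        next
      }
      placed <- rbind(placed, obj$extent)
      img <- paint_object(img, spec, obj)
      rows[[length(rows) + 1L]] <- tibble(
        category_id = cls, x = obj$bbox[1], y = obj$bbox[2],
        w = obj$bbox[3], h = obj$bbox[4]
      )
    }
    boxes <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble(category_id = integer(), x = numeric(), y = numeric(),
             w = numeric(), h = numeric())
    list(image = img, boxes = boxes)
  })
}

render_background <- function(spec, W, H) {
  bg <- spec$background
  img <- array(rep(bg$color, each = H * W), dim = c(H, W, 3))
  img <- img + array(rnorm(H * W * 3, 0, bg$noise_sd), dim = c(H, W, 3))
  # unannotated clutter: faint blobs near the background colour
  n_cl <- bg$clutter
  if (n_cl > 0) {
    for (i in seq_len(n_cl)) {
      s <- runif(1, 6, 18)
      cx <- runif(1, s, W - s); cy <- runif(1, s, H - s)
      m <- shape_mask("ellipse", cx, cy, s / 2, s / 2 * runif(1, 0.6, 1.6), W, H)
      tint <- pmin(pmax(bg$color + rnorm(3, 0, 0.08), 0), 1)
      for (ch in 1:3) {
        layer <- img[, , ch]
        layer[m] <- 0.5 * layer[m] + 0.5 * tint[ch]
        img[, , ch] <- layer
      }
    }
  }
  pmin(pmax(img, 0), 1)
}

# Sample a placement for one object; NULL if 50 rejections.
place_object <- function(spec, cls, placed, W, H) {
  for (attempt in 1:50) {
    s <- runif(1, spec$size_range_px[1], spec$size_range_px[2])
    ar <- runif(1, 0.75, 1.35)
    a <- s / 2; b <- s * ar / 2
    if (2 * b > H || 2 * a > W) next
    cx <- runif(1, a, W - a); cy <- runif(1, b, H - b)
    ext <- c(cx - a, cy - b, cx + a, cy + b)
    if (nrow(placed) > 0) {
      ious <- box_iou(matrix(ext, nrow = 1), placed)
      if (any(ious > spec$overlap_max_iou)) next
    }
    shape <- spec$palette$shape[cls]
    mask <- shape_mask(shape, cx, cy, a, b, W, H)
    if (!any(mask)) next
    bbox <- mask_bbox(mask)
    return(list(class = cls, cx = cx, cy = cy, a = a, b = b,
                shape = shape, mask = mask, extent = ext, bbox = bbox))
  }
  NULL
}

# Pixel mask of a shape; pixel (row i, col j) has centre (j - 0.5, i - 0.5).
shape_mask <- function(shape, cx, cy, a, b, W, H) {
  xs <- seq_len(W) - 0.5; ys <- seq_len(H) - 0.5
  X <- matrix(xs, nrow = H, ncol = W, byrow = TRUE)
  Y <- matrix(ys, nrow = H, ncol = W)
  u <- (X - cx) / a; v <- (Y - cy) / b
  switch(shape,
    ellipse = u^2 + v^2 <= 1,
    rectangle = abs(u) <= 1 & abs(v) <= 1,
    diamond = abs(u) + abs(v) <= 1,
    triangle = v <= 1 & v >= -1 & abs(u) <= (v + 1) / 2,
    blob = {
      th <- atan2(v, u)
      ph <- runif(3, 0, 2 * pi)
      r <- 1 + 0.22 * (sin(2 * th + ph[1]) + 0.6 * sin(3 * th + ph[2]) +
                         0.4 * sin(5 * th + ph[3])) / 2
      sqrt(u^2 + v^2) <= pmax(r, 0.3)
    },
    abort(sprintf("unknown shape '%s'", shape))
  )
}

# Tight 0-based COCO xywh box around a pixel mask.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  c(c0 - 1, r0 - 1, c1 - c0 + 1, r1 - r0 + 1)
}

paint_object <- function(img, spec, obj) {
  pal <- spec$palette[obj$class, ]
  col <- c(pal$r, pal$g, pal$b)
  hb <- spec$hard_background
  if (hb > 0) col <- (1 - hb) * col + hb * spec$background$color
  m <- obj$mask
  n <- sum(m)
  tex <- rnorm(n, 0, spec$texture_amp)
  for (ch in 1:3) {
    layer <- img[, , ch]
    layer[m] <- pmin(pmax(col[ch] + tex, 0), 1)
    img[, , ch] <- layer
  }
  img
}
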