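# Shared fixtures, all built in code.

tiny_spec <- function(n_classes = 3, image_size = c(64, 64), ...) {
  scene_spec(n_classes = n_classes, image_size = image_size,
             size_range_px = c(12, 24), ...)
}

# A manifest assembled directly from tibbles (no images on disk).
toy_manifest <- function(img_classes, boxes_per_image = 1, width = 64,
                         height = 64) {
  n <- length(img_classes)
  images <- tibble::tibble(image_id = seq_len(n),
                           file_name = sprintf("img%03d.png", seq_len(n)),
                           width = width, height = height)
  ann <- list()
  aid <- 0L
  for (i in seq_len(n)) {
    for (b in seq_len(boxes_per_image)) {
      aid <- aid + 1L
      ann[[aid]] <- tibble::tibble(
        ann_id = aid, image_id = i, category_id = img_classes[[i]][
          ((b - 1) %% length(img_classes[[i]])) + 1],
        x = 4 + 3 * b, y = 4 + 2 * b, w = 10, h = 12)
    }
  }
  cats <- sort(unique(unlist(img_classes)))
  fs_manifest(images, dplyr::bind_rows(ann),
              tibble::tibble(category_id = cats,
                             name = paste0("c", cats)))
}

random_unit_rows <- function(n, d, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * d), n, d)
  z / sqrt(rowSums(z^2))
}

# Independent double-loop oracle for the weighted supervised contrastive loss.
supcon_oracle <- function(z, labels, tau = 0.2, weighted = FALSE,
                          class_counts = NULL) {
  n <- nrow(z)
  if (is.null(class_counts)) class_counts <- table(labels)
  total <- 0
  for (i in seq_len(n)) {
    P <- setdiff(which(labels == labels[i]), i)
    if (length(P) == 0) next
    A <- setdiff(seq_len(n), i)
    w <- if (weighted) 1 / as.numeric(class_counts[as.character(labels[i])]) else 1
    for (p in P) {
      num <- exp(sum(z[i, ] * z[p, ]) / tau)
      den <- sum(sapply(A, function(a) exp(sum(z[i, ] * z[a, ]) / tau)))
      total <- total + w / length(P) * (-log(num / den))
    }
  }
  total
}

# Independent pixel-grid IoU oracle (counts covered pixel centres).
iou_pixel_oracle <- function(a, b, res = 400) {
  xs <- seq(min(a[1], b[1]), max(a[3], b[3]), length.out = res)
  ys <- seq(min(a[2], b[2]), max(a[4], b[4]), length.out = res)
  g <- expand.grid(x = xs, y = ys)
  ina <- g$x >= a[1] & g$x <= a[3] & g$y >= a[2] & g$y <= a[4]
  inb <- g$x >= b[1] & g$x <= b[3] & g$y >= b[2] & g$y <= b[4]
  sum(ina & inb) / sum(ina | inb)
}
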