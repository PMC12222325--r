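#' Construct a dataset manifest
#'
#' A manifest is the in-memory form of a COCO-style detection dataset:
#' three tibbles (`images`, `annotations`, `categories`) plus a cached
#' per-class count table. All boxes are COCO `x, y, w, h` (0-based pixel
#' floats, width/height strictly positive).
#'
#' @param images Tibble with columns `image_id`, `file_name`, `width`, `height`.
#' @param annotations Tibble with columns `ann_id`, `image_id`, `category_id`,
#'   `x`, `y`, `w`, `h`.
#' @param categories Tibble with columns `category_id`, `name`.
#' @param root Optional directory that `file_name` entries are relative to.
#' @return An object of class `fs_manifest`.
#' @export
fs_manifest <- function(images, annotations, categories, root = NULL) {
  images <- as_tibble(images); annotations <- as_tibble(annotations)
  categories <- as_tibble(categories)
  assert_that(!anyDuplicated(images$image_id), "duplicate image ids")
  assert_that(!anyDuplicated(categories$category_id), "duplicate category ids")
  if (nrow(annotations) > 0) {
    assert_that(all(annotations$image_id %in% images$image_id),
                "annotation references a missing image id")
    assert_that(all(annotations$category_id %in% categories$category_id),
                "annotation references a missing category id")
    assert_that(all(annotations$w > 0 & annotations$h > 0),
                "all box widths/heights must be strictly positive")
    ok <- annotations$x >= 0 & annotations$y >= 0
    wh <- images[match(annotations$image_id, images$image_id), ]
    ok <- ok & (annotations$x + annotations$w <= wh$width + 1e-6) &
      (annotations$y + annotations$h <= wh$height + 1e-6)
    assert_that(all(ok), "boxes must lie fully inside their image bounds")
  }
  m <- structure(list(images = images, annotations = annotations,
                      categories = categories, root = root),
                 class = "fs_manifest")
  m$per_class_counts <- manifest_counts(m)
  m
}

#' Recount per-class image and box totals from the annotation table
#'
#' This is the self-consistency oracle for a manifest: counts are always
#' recomputed from the raw annotations, never trusted from a cache.
#'
#' @param manifest An `fs_manifest`, or a path to a COCO JSON file.
#' @return Tibble with `category_id`, `n_images`, `n_boxes` (one row per
#'   category, including categories with zero annotations).
#' @export
manifest_counts <- function(manifest) {
  if (is.character(manifest)) manifest <- read_coco(manifest)
  ann <- manifest$annotations
  cats <- manifest$categories
  if (nrow(ann) == 0) {
    return(tibble(category_id = cats$category_id, n_images = 0L, n_boxes = 0L))
  }
  counts <- ann |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(n_images = dplyr::n_distinct(.data$image_id),
                     n_boxes = dplyr::n(), .groups = "drop")
  out <- tibble(category_id = cats$category_id) |>
    dplyr::left_join(counts, by = "category_id")
  out$n_images <- as.integer(ifelse(is.na(out$n_images), 0L, out$n_images))
  out$n_boxes <- as.integer(ifelse(is.na(out$n_boxes), 0L, out$n_boxes))
  out
}

#' @export
print.fs_manifest <- function(x, ...) {
  cat(sprintf("<fs_manifest> %d images, %d boxes, %d categories\n",
              nrow(x$images), nrow(x$annotations), nrow(x$categories)))
  print(x$per_class_counts, n = 5)
  invisible(x)
}

#' Write a manifest as a COCO JSON annotation file
#'
#' @param manifest An `fs_manifest`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(manifest, path) {
  ann <- manifest$annotations
  out <- list(
    images = purrr::pmap(manifest$images, function(image_id, file_name, width, height, ...) {
      list(id = image_id, file_name = file_name, width = width, height = height)
    }),
    annotations = purrr::pmap(ann, function(ann_id, image_id, category_id, x, y, w, h, ...) {
      list(id = ann_id, image_id = image_id, category_id = category_id,
           bbox = c(x, y, w, h), area = w * h, iscrowd = 0L)
    }),
    categories = purrr::pmap(manifest$categories, function(category_id, name, ...) {
      list(id = category_id, name = name)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO JSON annotation file into a manifest
#'
#' @param path Path to a COCO JSON file.
#' @param root Optional image root directory (defaults to the JSON's folder).
#' @return An `fs_manifest`.
#' @export
read_coco <- function(path, root = dirname(path)) {
  j <- jsonlite::read_json(path)
  images <- purrr::map_dfr(j$images, \(im) tibble(
    image_id = im$id, file_name = im$file_name,
    width = im$width, height = im$height))
  if (length(j$images) == 0) {
    images <- tibble(image_id = integer(), file_name = character(),
                     width = integer(), height = integer())
  }
  annotations <- purrr::map_dfr(j$annotations, \(a) tibble(
    ann_id = a$id, image_id = a$image_id, category_id = a$category_id,
    x = a$bbox[[1]], y = a$bbox[[2]], w = a$bbox[[3]], h = a$bbox[[4]]))
  if (length(j$annotations) == 0) {
    annotations <- tibble(ann_id = integer(), image_id = integer(),
                          category_id = integer(), x = numeric(),
                          y = numeric(), w = numeric(), h = numeric())
  }
  categories <- purrr::map_dfr(j$categories, \(cc) tibble(
    category_id = cc$id, name = cc$name))
  fs_manifest(images, annotations, categories, root = root)
}

#' Generate a full synthetic detection dataset on disk
#'
#' Renders `class_profile[c]` images for each class `c` — every object in an
#' image belongs to the image's class (pest photos are typically
#' single-species), with the number of instances drawn from the spec's
#' objects-per-image range — writes PNG images and a COCO JSON annotation
#' file, and returns the manifest. Per-class image counts in the result
#' match `class_profile` exactly, so the induced class imbalance is
#' controlled by the caller; per-class box counts are at least the image
#' counts.
#'
#' @param spec A [scene_spec()].
#' @param class_profile Integer vector of per-class image counts
#'   (length `spec$n_classes`).
#' @param out_dir Output directory (created if needed); images go to
#'   `out_dir/images/`, annotations to `out_dir/annotations.json`.
#' @param seed Integer seed; fixed seed gives a byte-identical annotation file.
#' @param write_images If `FALSE`, skip PNG encoding (annotation-only runs).
#' @return An `fs_manifest` with `root = out_dir`.
#' @export
generate_dataset <- function(spec, class_profile, out_dir, seed = NULL,
                             write_images = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  assert_that(length(class_profile) == spec$n_classes,
              "class_profile length must equal n_classes")
  assert_that(all(class_profile >= 0), "class_profile must be non-negative")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(file.path(out_dir, "images")),
              sprintf("cannot create output directory '%s'", out_dir))
  with_seed(seed, {
    primary <- rep(seq_len(spec$n_classes), times = class_profile)
    n_img <- length(primary)
    images <- list(); anns <- list(); ann_id <- 0L
    for (i in seq_len(n_img)) {
      # every object in an image belongs to the image's class, so per-class
      # image counts equal the requested profile exactly (and pest photos
      # are typically single-species); multi-instance images still occur
      quota <- integer(spec$n_classes)
      lo <- spec$objects_per_image[1]; hi <- spec$objects_per_image[2]
      n_obj <- if (hi > lo) sample(lo:hi, 1) else lo
      quota[primary[i]] <- max(n_obj, 1L)
      sc <- generate_scene(spec, quota)
      fn <- sprintf("images/img_%05d.png", i)
      if (write_images) {
        png::writePNG(aperm(sc$image, c(1, 2, 3)), file.path(out_dir, fn))
      }
      images[[i]] <- tibble(image_id = i, file_name = fn,
                            width = spec$image_size[1], height = spec$image_size[2])
      if (nrow(sc$boxes) > 0) {
        anns[[length(anns) + 1L]] <- sc$boxes |>
          dplyr::mutate(image_id = i,
                        ann_id = ann_id + dplyr::row_number()) |>
          dplyr::select("ann_id", "image_id", "category_id", "x", "y", "w", "h")
        ann_id <- ann_id + nrow(sc$boxes)
      }
    }
    annotations <- if (length(anns)) dplyr::bind_rows(anns) else
      tibble(ann_id = integer(), image_id = integer(), category_id = integer(),
             x = numeric(), y = numeric(), w = numeric(), h = numeric())
    if (length(images) == 0) {
      images <- list(tibble(image_id = integer(), file_name = character(),
                            width = integer(), height = integer()))
    }
    categories <- tibble(category_id = seq_len(spec$n_classes),
                         name = sprintf("class_%02d", seq_len(spec$n_classes)))
    m <- fs_manifest(dplyr::bind_rows(images), annotations, categories,
                     root = out_dir)
    write_coco(m, file.path(out_dir, "annotations.json"))
    m
  })
}

#' Stratified image-level train/test split
#'
#' Splits a manifest at the image level so that each image (with all of its
#' annotations) lands in exactly one side and, for each class, the fraction
#' of that class's images assigned to train is within one image of `ratio`.
#' Classes are processed from rarest to most frequent; images containing
#' several classes are assigned once and count toward every class they
#' contain. A class with fewer than two images cannot appear on both sides:
#' it is placed entirely in train with a warning.
#'
#' @param manifest An `fs_manifest`.
#' @param ratio Train fraction, strictly between 0 and 1 (the conventional
#'   benchmark split is 8:2).
#' @param seed Integer seed controlling the shuffle.
#' @return List with elements `train` and `test`, both `fs_manifest`s.
#' @export
split_train_test <- function(manifest, ratio = 0.8, seed = NULL) {
  assert_that(ratio > 0 && ratio < 1, "ratio must be in (0, 1)")
  ann <- manifest$annotations
  with_seed(seed, {
    img_classes <- split(ann$category_id, ann$image_id)
    class_sizes <- manifest$per_class_counts |>
      dplyr::filter(.data$n_images > 0) |> dplyr::arrange(.data$n_images)
    assign <- setNames(rep(NA_character_, nrow(manifest$images)),
                       manifest$images$image_id)
    for (cls in class_sizes$category_id) {
      imgs <- unique(ann$image_id[ann$category_id == cls])
      n_c <- length(imgs)
      if (n_c < 2) {
        warn(sprintf("class %d has < 2 images; placed entirely in train", cls))
        assign[as.character(imgs)] <- "train"
        next
      }
      target <- round(ratio * n_c)
      have <- sum(assign[as.character(imgs)] == "train", na.rm = TRUE)
      open <- imgs[is.na(assign[as.character(imgs)])]
      open <- if (length(open) > 1) sample(open) else open
      n_add <- min(max(target - have, 0L), length(open))
      assign[as.character(open[seq_len(n_add)])] <- "train"
      if (n_add < length(open)) {
        assign[as.character(open[(n_add + 1):length(open)])] <- "test"
      }
    }
    assign[is.na(assign)] <- ifelse(runif(sum(is.na(assign))) < ratio, "train", "test")
    subset_side <- function(side) {
      ids <- as.integer(names(assign)[assign == side])
      subset_manifest(manifest, ids)
    }
    list(train = subset_side("train"), test = subset_side("test"))
  })
}

# Restrict a manifest to a set of image ids (keeping all their annotations).
subset_manifest <- function(manifest, image_ids) {
  fs_manifest(
    images = dplyr::filter(manifest$images, .data$image_id %in% image_ids),
    annotations = dplyr::filter(manifest$annotations, .data$image_id %in% image_ids),
    categories = manifest$categories,
    root = manifest$root
  )
}

#' Published per-class image counts of the PestDet20 benchmark
#'
#' Returns the per-class training/test image and annotation-box counts of the
#' 20-class tropical pest detection benchmark this package's generator
#' emulates (20 classes, training images ranging 92–400 per class). Used as
#' the reference class-imbalance profile for synthetic datasets and as the
#' fixture behind the manifest-recount checks.
#'
#' @return Tibble with columns `category_id`, `name`, `train_images`,
#'   `test_images`, `train_boxes`, `test_boxes`.
#' @export
pestdet20_counts <- function() {
  path <- system.file("extdata", "pestdet20_counts.csv", package = "pestfsod")
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(tb)
}

#' Scale a per-class image-count profile
#'
#' Rounds `scale * counts` half away from zero toward the nearest integer
#' (base R `round`), used to shrink a published benchmark profile to desk
#' scale while preserving its imbalance ratio.
#'
#' @param counts Integer vector of per-class image counts.
#' @param scale Positive scaling factor.
#' @return Integer vector, same length as `counts`.
#' @export
scale_profile <- function(counts, scale) {
  assert_that(scale > 0, "scale must be positive")
  as.integer(round(counts * scale))
}
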