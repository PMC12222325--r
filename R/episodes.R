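#' Create a base/novel class split
#'
#' Shuffles the class ids deterministically under `seed` and takes the first
#' `n_base` of the shuffled order as base classes and the remainder as novel
#' classes — the standard construction for few-shot detection benchmarks
#' (e.g. 20 classes with 15 base / 5 novel).
#'
#' @param class_ids Vector of distinct category ids.
#' @param n_base Number of base classes, strictly less than the number of ids.
#' @param seed Integer seed for the shuffle.
#' @return An object of class `class_split`: list with `all`, `base`,
#'   `novel`, `seed`.
#' @export
make_split <- function(class_ids, n_base, seed = NULL) {
  assert_that(!anyDuplicated(class_ids), "class_ids must be distinct")
  assert_that(is_count(n_base) && n_base >= 1 && n_base < length(class_ids),
              "n_base must be a count < length(class_ids)")
  with_seed(seed, {
    shuffled <- sample(class_ids)
    new_class_split(all = shuffled,
                    base = shuffled[seq_len(n_base)],
                    novel = shuffled[(n_base + 1):length(shuffled)],
                    seed = seed)
  })
}

new_class_split <- function(all, base, novel, seed = NULL) {
  assert_that(setequal(all, union(base, novel)) &&
                length(intersect(base, novel)) == 0 &&
                length(base) + length(novel) == length(all),
              "base and novel must partition all classes")
  structure(list(all = all, base = base, novel = novel, seed = seed),
            class = "class_split")
}

#' @export
print.class_split <- function(x, ...) {
  cat(sprintf("<class_split> %d classes: %d base / %d novel\n",
              length(x$all), length(x$base), length(x$novel)))
  cat(" base:", paste(x$base, collapse = " "), "\n")
  cat(" novel:", paste(x$novel, collapse = " "), "\n")
  invisible(x)
}

#' Published class splits of the PestDet20 benchmark
#'
#' The three published 15-base / 5-novel splits of the 20 selected pest
#' classes, shipped as fixtures (the shuffle seed behind them is unknown, so
#' they are loaded, not re-derived).
#'
#' @param id Split number (1, 2 or 3); `NULL` returns the list of all three.
#' @return A `class_split`, or a list of them.
#' @export
pestdet20_splits <- function(id = NULL) {
  path <- system.file("extdata", "pestdet20_splits.yaml", package = "pestfsod")
  y <- yaml::read_yaml(path)
  splits <- lapply(y$splits, function(s)
    new_class_split(all = as.integer(s$all), base = as.integer(s$base),
                    novel = as.integer(s$novel)))
  names(splits) <- vapply(y$splits, function(s) as.character(s$id), "")
  if (is.null(id)) splits else splits[[as.character(id)]]
}

#' Write / read a class split as YAML
#'
#' @param split A `class_split`.
#' @param path YAML file path.
#' @return `path` (write) or a `class_split` (read).
#' @export
write_split <- function(split, path) {
  yaml::write_yaml(list(all = split$all, base = split$base,
                        novel = split$novel, seed = split$seed), path)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  s <- yaml::read_yaml(path)
  new_class_split(as.integer(s$all), as.integer(s$base), as.integer(s$novel),
                  seed = s$seed)
}

#' Shot-dependent fine-tuning configuration
#'
#' Bundles the hyperparameters that the fine-tuning protocol ties to the
#' number of shots K: the positive-sample IoU threshold (0.6 / 0.7 / 0.8 for
#' 3 / 5 / 10 shots), the contrastive temperature (0.2 for all shots) and the
#' contrastive loss weight lambda2 (0.2 / 0.5 / 0.5). The aggregation-loss
#' weight lambda1 defaults to 0.5 for every shot.
#'
#' @param K Shots per class (any positive integer; 3, 5 and 10 carry the
#'   published per-shot settings).
#' @param iou_pos,tau,lambda1,lambda2 Optional overrides.
#' @return A list of class `shot_config`.
#' @export
shot_config <- function(K, iou_pos = NULL, tau = 0.2, lambda1 = 0.5,
                        lambda2 = NULL) {
  assert_that(is_count(K) && K >= 1, "K must be a positive count")
  iou_default <- c(`3` = 0.6, `5` = 0.7, `10` = 0.8)
  l2_default <- c(`3` = 0.2, `5` = 0.5, `10` = 0.5)
  iou_pos <- iou_pos %||% unname(iou_default[as.character(K)]) %||% 0.7
  if (is.na(iou_pos)) iou_pos <- 0.7
  lambda2 <- lambda2 %||% unname(l2_default[as.character(K)]) %||% 0.5
  if (is.na(lambda2)) lambda2 <- 0.5
  assert_that(iou_pos > 0 && iou_pos < 1, "iou_pos must be in (0, 1)")
  assert_that(tau > 0, "tau must be positive")
  assert_that(lambda1 >= 0 && lambda2 >= 0, "lambda weights must be non-negative")
  structure(list(K = as.integer(K), iou_pos = iou_pos, tau = tau,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "shot_config")
}

#' Sample a balanced K-shot fine-tuning set
#'
#' For every class in `split` (base and novel alike, keeping the fine-tuning
#' set balanced), selects K images that contain at least one instance of that
#' class; images already selected for another class they contain count toward
#' a class's K and are included only once. A class with fewer than K images
#' contributes all of them with a warning; a class with none is an error.
#'
#' @param manifest An `fs_manifest` (typically the training side).
#' @param split A `class_split`.
#' @param K Shots (images) per class.
#' @param seed Integer seed; sampling is deterministic under it.
#' @return An `fs_manifest` restricted to the selected images (with all their
#'   annotations).
#' @export
sample_kshot <- function(manifest, split, K, seed = NULL) {
  assert_that(is_count(K) && K >= 1, "K must be a positive count")
  ann <- manifest$annotations
  with_seed(seed, {
    selected <- integer(0)
    for (cls in c(split$base, split$novel)) {
      imgs <- unique(ann$image_id[ann$category_id == cls])
      if (length(imgs) == 0) {
        abort(sprintf("class %d has no images in the manifest", cls))
      }
      have <- sum(selected %in% imgs)
      need <- K - have
      if (need <= 0) next
      open <- setdiff(imgs, selected)
      if (length(open) < need) {
        warn(sprintf("class %d has only %d images; taking all (requested %d shots)",
                     cls, length(imgs), K))
        need <- length(open)
      }
      open <- if (length(open) > 1) sample(open) else open
      selected <- c(selected, open[seq_len(need)])
    }
    subset_manifest(manifest, selected)
  })
}
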