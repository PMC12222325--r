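#' Intersection-over-union of axis-aligned boxes
#'
#' Vectorized over all pairs: returns the `n x m` matrix of IoU values
#' between the rows of `a` and the rows of `b` (boxes as `x1, y1, x2, y2`).
#' A degenerate (zero-area) box has IoU 0 with everything (with a warning).
#'
#' @param a,b Matrices with one `x1,y1,x2,y2` box per row (a single box may
#'   be given as a length-4 vector).
#' @return `nrow(a) x nrow(b)` matrix of values in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  a <- if (is.null(dim(a))) matrix(a, nrow = 1) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, nrow = 1) else as.matrix(b)
  area_a <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  area_b <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  if (any(area_a == 0) || any(area_b == 0)) {
    warn("degenerate zero-area box; IoU taken as 0")
  }
  iw <- pmax(outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax), 0)
  ih <- pmax(outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax), 0)
  inter <- iw * ih
  un <- outer(area_a, area_b, "+") - inter
  out <- ifelse(un > 0, inter / un, 0)
  matrix(out, nrow = nrow(a))
}

#' Greedy one-to-one detection/ground-truth matching
#'
#' Detections (already restricted to one image and one class) are processed
#' in descending score order; each matches the unmatched ground-truth box of
#' highest IoU when that IoU exceeds `iou_thr` (strictly, by default), else
#' it is a false positive. Unmatched ground truths are false negatives.
#'
#' @param det_boxes `n x 4` matrix of detection boxes (`x1,y1,x2,y2`).
#' @param scores Detection scores (length `n`).
#' @param gt_boxes `m x 4` matrix of ground-truth boxes.
#' @param iou_thr IoU threshold (default 0.5).
#' @param strict If `TRUE` (default) a match requires `IoU > iou_thr`;
#'   otherwise `>=`.
#' @return List with `tp` (logical per detection, in descending-score
#'   order), `order` (the score ordering used), `fn` (count of unmatched
#'   ground truths).
#' @export
match_detections <- function(det_boxes, scores, gt_boxes, iou_thr = 0.5,
                             strict = TRUE) {
  det_boxes <- if (is.null(dim(det_boxes))) matrix(det_boxes, nrow = 1) else as.matrix(det_boxes)
  n <- nrow(det_boxes)
  m <- if (is.null(gt_boxes) || length(gt_boxes) == 0) 0 else nrow(as.matrix(gt_boxes))
  ord <- order(scores, decreasing = TRUE)
  tp <- logical(n)
  if (m == 0) return(list(tp = tp, order = ord, fn = 0L))
  gt_boxes <- as.matrix(gt_boxes)
  used <- logical(m)
  iou <- box_iou(det_boxes, gt_boxes)
  for (i in ord) {
    cand <- which(!used)
    if (length(cand) == 0) break
    vals <- iou[i, cand]
    j <- cand[which.max(vals)]
    hit <- if (strict) iou[i, j] > iou_thr else iou[i, j] >= iou_thr
    if (hit) {
      tp[which(ord == i)] <- TRUE
      used[j] <- TRUE
    }
  }
  list(tp = tp, order = ord, fn = as.integer(sum(!used)))
}

#' Average precision by all-points PR interpolation
#'
#' Given true/false-positive flags of a class's detections ranked by
#' descending score and the number of ground truths, computes precision and
#' recall cumulatively and integrates the area under the monotone
#' (right-to-left maximum) precision envelope over recall — the continuous
#' integral definition of AP, not the 11-point approximation.
#'
#' @param tp_flags Logical vector, ranked by descending score.
#' @param n_gt Number of ground-truth boxes of the class (must be > 0).
#' @return List with `ap` and a `pr` tibble (`recall`, `precision`).
#' @export
average_precision <- function(tp_flags, n_gt) {
  assert_that(n_gt > 0, "AP is undefined for a class with zero ground truths")
  if (length(tp_flags) == 0) {
    return(list(ap = 0, pr = tibble(recall = numeric(), precision = numeric())))
  }
  tp_cum <- cumsum(tp_flags)
  fp_cum <- cumsum(!tp_flags)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # monotone non-increasing precision envelope, integrated over recall
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, head(recall, -1))
  ap <- sum((recall - r_prev) * env)
  list(ap = ap, pr = tibble(recall = recall, precision = precision))
}

#' Evaluate detections against a manifest
#'
#' Runs greedy matching per image and class at the given IoU threshold,
#' accumulates ranked TP/FP flags per class, and computes per-class AP with
#' all-points interpolation plus TP/FP/FN counts and PR curves. Classes with
#' zero ground truths in `manifest` are excluded from summary means with a
#' warning (their AP is undefined).
#'
#' @param detections Tibble with columns `image_id`, `category_id`, `score`,
#'   `x`, `y`, `w`, `h` (COCO-style boxes).
#' @param manifest An `fs_manifest` holding the ground truth.
#' @param iou_thr IoU threshold (default 0.5, i.e. AP50).
#' @param strict Strict (`>`) IoU comparison; see [match_detections()].
#' @return An object of class `fs_eval`: list with `per_class` tibble
#'   (`category_id`, `n_gt`, `n_det`, `tp`, `fp`, `fn`, `ap`), `pr_curves`,
#'   `map` (mean AP over evaluable classes), `iou_threshold`.
#' @export
evaluate_detections <- function(detections, manifest, iou_thr = 0.5,
                                strict = TRUE) {
  gt <- manifest$annotations
  cats <- manifest$categories$category_id
  per <- list(); curves <- list()
  for (cls in cats) {
    g <- gt[gt$category_id == cls, ]
    d <- detections[detections$category_id == cls, , drop = FALSE]
    n_gt <- nrow(g)
    if (n_gt == 0) {
      warn(sprintf("class %d has no ground truths; excluded from mean AP", cls))
      per[[length(per) + 1L]] <- tibble(category_id = cls, n_gt = 0L,
                                        n_det = nrow(d), tp = 0L,
                                        fp = nrow(d), fn = 0L, ap = NA_real_)
      next
    }
    flags <- logical(0); scores <- numeric(0); fn_extra <- 0L
    for (img in unique(c(g$image_id, d$image_id))) {
      gi <- g[g$image_id == img, ]
      di <- d[d$image_id == img, , drop = FALSE]
      if (nrow(di) == 0) { fn_extra <- fn_extra + nrow(gi); next }
      mm <- match_detections(
        xywh_to_xyxy(di[, c("x", "y", "w", "h")]), di$score,
        if (nrow(gi)) xywh_to_xyxy(gi[, c("x", "y", "w", "h")]) else NULL,
        iou_thr = iou_thr, strict = strict)
      flags <- c(flags, mm$tp)
      scores <- c(scores, sort(di$score, decreasing = TRUE))
      fn_extra <- fn_extra + mm$fn
    }
    ord <- order(scores, decreasing = TRUE)
    flags <- flags[ord]
    apr <- average_precision(flags, n_gt)
    per[[length(per) + 1L]] <- tibble(
      category_id = cls, n_gt = as.integer(n_gt),
      n_det = length(flags), tp = as.integer(sum(flags)),
      fp = as.integer(sum(!flags)),
      fn = as.integer(n_gt - sum(flags)), ap = apr$ap)
    curves[[as.character(cls)]] <- apr$pr
  }
  per_class <- dplyr::bind_rows(per)
  structure(list(per_class = per_class, pr_curves = curves,
                 map = mean(per_class$ap, na.rm = TRUE),
                 iou_threshold = iou_thr),
            class = "fs_eval")
}

#' @export
print.fs_eval <- function(x, ...) {
  cat(sprintf("<fs_eval> mAP%g = %.3f over %d classes\n",
              100 * x$iou_threshold, x$map,
              sum(!is.na(x$per_class$ap))))
  print(x$per_class)
  invisible(x)
}

#' Base/novel/overall mean average precision
#'
#' Unweighted arithmetic means of per-class AP over the base classes (bAP),
#' the novel classes (nAP) and all classes of the split (mAP). Accepts an
#' [evaluate_detections()] result, a tibble with `category_id` and `ap`
#' columns, or a named numeric vector of APs. A split class missing from the
#' AP table is an error naming it; classes whose AP is `NA` (no ground
#' truths) are dropped from the means with a warning.
#'
#' @param per_class_ap `fs_eval`, tibble, or named numeric vector.
#' @param split A `class_split`.
#' @return One-row tibble with `bap`, `nap`, `map`.
#' @export
split_map <- function(per_class_ap, split) {
  ap <- if (inherits(per_class_ap, "fs_eval")) {
    setNames(per_class_ap$per_class$ap, per_class_ap$per_class$category_id)
  } else if (is.data.frame(per_class_ap)) {
    setNames(per_class_ap$ap, per_class_ap$category_id)
  } else {
    assert_that(!is.null(names(per_class_ap)), "AP vector must be named by class id")
    per_class_ap
  }
  missing <- setdiff(as.character(split$all), names(ap))
  if (length(missing) > 0) {
    abort(sprintf("class %s missing from per-class AP", paste(missing, collapse = ", ")))
  }
  if (anyNA(ap[as.character(split$all)])) {
    warn("classes with undefined AP dropped from the means")
  }
  m <- function(ids) mean(ap[as.character(ids)], na.rm = TRUE)
  tibble(bap = m(split$base), nap = m(split$novel), map = m(split$all))
}

#' Detection confusion matrix
#'
#' Builds a `(C+1) x (C+1)` count matrix (rows = true class, columns =
#' predicted class, last index = background) from score-thresholded
#' detections: each ground truth is assigned the class of its best-IoU
#' unmatched detection above the IoU threshold (any class); unmatched ground
#' truths fall in the background column, unmatched detections in the
#' background row.
#'
#' @inheritParams evaluate_detections
#' @param score_thr Minimum detection score considered (default 0.5).
#' @param normalize `"none"` (raw counts) or `"row"` (rates per true class).
#' @return A square matrix with dimnames of category ids plus "background".
#' @export
confusion_matrix <- function(detections, manifest, iou_thr = 0.5,
                             score_thr = 0.5, normalize = c("none", "row")) {
  normalize <- match.arg(normalize)
  cats <- manifest$categories$category_id
  C <- length(cats)
  idx <- setNames(seq_len(C), cats)
  M <- matrix(0L, C + 1, C + 1,
              dimnames = list(c(cats, "background"), c(cats, "background")))
  dets <- detections[detections$score >= score_thr, , drop = FALSE]
  for (img in unique(manifest$images$image_id)) {
    gi <- manifest$annotations[manifest$annotations$image_id == img, ]
    di <- dets[dets$image_id == img, , drop = FALSE]
    used <- logical(nrow(di))
    if (nrow(gi) > 0) {
      gb <- xywh_to_xyxy(gi[, c("x", "y", "w", "h")])
      db <- if (nrow(di)) xywh_to_xyxy(di[, c("x", "y", "w", "h")]) else NULL
      iou <- if (nrow(di)) box_iou(gb, db) else matrix(0, nrow(gi), 0)
      for (k in seq_len(nrow(gi))) {
        r <- idx[as.character(gi$category_id[k])]
        cand <- which(!used & iou[k, ] > iou_thr)
        if (length(cand) > 0) {
          j <- cand[which.max(iou[k, cand])]
          used[j] <- TRUE
          M[r, idx[as.character(di$category_id[j])]] <-
            M[r, idx[as.character(di$category_id[j])]] + 1L
        } else {
          M[r, C + 1] <- M[r, C + 1] + 1L
        }
      }
    }
    for (j in which(!used)) {
      cc <- idx[as.character(di$category_id[j])]
      M[C + 1, cc] <- M[C + 1, cc] + 1L
    }
  }
  if (normalize == "row") {
    rs <- rowSums(M)
    M <- sweep(M, 1, pmax(rs, 1), "/")
  }
  M
}

#' @export
tidy.fs_eval <- function(x, ...) x$per_class

#' @export
glance.fs_eval <- function(x, ...) {
  tibble(map = x$map,
         n_classes = sum(!is.na(x$per_class$ap)),
         n_gt = sum(x$per_class$n_gt),
         n_det = sum(x$per_class$n_det),
         iou_threshold = x$iou_threshold)
}

#' Plot per-class precision-recall curves
#'
#' @param object An `fs_eval` result.
#' @param ... Unused.
#' @return A ggplot object (one facet per class).
#' @export
autoplot.fs_eval <- function(object, ...) {
  df <- purrr::imap_dfr(object$pr_curves, \(pr, cls)
                        dplyr::mutate(pr, category = cls))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", colour = "#2b8cbe") +
    ggplot2::facet_wrap(~category) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("PR curves at IoU %.2f", object$iou_threshold)) +
    ggplot2::theme_minimal()
}
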