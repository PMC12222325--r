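#' Detector architecture configuration
#'
#' Desk-scale two-stage detector: a frozen random convolutional pyramid
#' (4 stages, FPN-style top-down fusion at strides 4/8/16), an anchor-based
#' RPN-lite, RoI Align to a `roi_size x roi_size` grid, optional feature
#' aggregation (FAM) over a support bank, and linear classification /
#' class-agnostic box-regression heads on the (enhanced) RoI features.
#'
#' @param image_size Square input image side in pixels.
#' @param channels Backbone stage widths.
#' @param fpn_dim Common pyramid channel count after lateral projection.
#' @param roi_size RoI Align output grid side (7 is the convention).
#' @param d_k FAM attention head dimension.
#' @param d_e Contrastive embedding dimension.
#' @param anchor_scales Anchor side lengths per pyramid level.
#' @param proposal_source `"rpn"` (default), `"groundtruth"` or
#'   `"jittered_groundtruth"` — the last two bypass the RPN so that losses,
#'   assignment, FAM and SCL can be exercised in isolation.
#' @param score_thr Minimum kept detection score.
#' @param nms_iou Class-wise NMS IoU threshold at inference.
#' @param refine_rounds Number of head passes at inference: with 2 (default)
#'   the regressed boxes are re-pooled and re-scored once, tightening
#'   localization.
#' @return List of class `model_config`; `feature_dim` is derived.
#' @export
model_config <- function(image_size = 96, channels = c(16, 32, 64, 128),
                         fpn_dim = 12, roi_size = 7, d_k = 64, d_e = 64,
                         anchor_scales = list(c(12, 18, 26), c(36, 52), c(72)),
                         proposal_source = c("rpn", "groundtruth",
                                             "jittered_groundtruth"),
                         score_thr = 0.05, nms_iou = 0.3, refine_rounds = 3) {
  proposal_source <- match.arg(proposal_source)
  assert_that(roi_size >= 1, "roi_size must be >= 1")
  structure(list(
    image_size = as.integer(image_size), channels = channels,
    fpn_dim = as.integer(fpn_dim), roi_size = as.integer(roi_size),
    d_k = as.integer(d_k), d_e = as.integer(d_e),
    anchor_scales = anchor_scales, strides = c(4L, 8L, 16L),
    proposal_source = proposal_source,
    score_thr = score_thr, nms_iou = nms_iou,
    refine_rounds = as.integer(refine_rounds),
    feature_dim = as.integer(roi_size^2 * fpn_dim)
  ), class = "model_config")
}

#' Training configuration
#'
#' Defaults mirror the published protocol (SGD momentum, base learning rate
#' 0.02 dropped to 0.001 for fine-tuning, batch size 4, 18,000 base
#' iterations with evaluation every 3,000); desk-scale runs pass much
#' smaller `iters`/`eval_interval`.
#'
#' @param lr Initial learning rate.
#' @param momentum SGD momentum factor.
#' @param weight_decay L2 penalty on weight matrices.
#' @param batch_size Images per iteration.
#' @param iters Training iterations.
#' @param eval_interval Iterations between validation evaluations
#'   (checkpoint selection keeps the best validation mAP50).
#' @param lr_schedule `"step"` (x0.1 at 2/3 of iterations) or `"cosine"`.
#' @param gamma Focal-loss focusing exponent.
#' @param alpha_mode `"inverse"` (normalized inverse class frequency focal
#'   weights) or `"none"`.
#' @param beta Smooth-L1 transition point.
#' @param lambda1,lambda2 Aggregation / contrastive loss weights (overridden
#'   by a `shot_config` during fine-tuning).
#' @param use_fam,use_scl Enable the feature aggregation module / the
#'   supervised contrastive loss (defaults follow the two-stage protocol:
#'   off at the base stage, on during fine-tuning).
#' @param n_jitter Jittered copies of each ground-truth box used as head
#'   training proposals.
#' @param seed Integer seed for the training loop.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 0.02, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 4, iters = 18000, eval_interval = 3000,
                         lr_schedule = c("step", "cosine"), gamma = 2,
                         alpha_mode = c("inverse", "none"), beta = 1,
                         lambda1 = 0.5, lambda2 = 0.5,
                         use_fam = FALSE, use_scl = FALSE,
                         n_jitter = 3, seed = 0) {
  lr_schedule <- match.arg(lr_schedule)
  alpha_mode <- match.arg(alpha_mode)
  assert_that(lr > 0 && iters >= 1, "lr must be positive and iters >= 1")
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), iters = as.integer(iters),
                 eval_interval = as.integer(eval_interval),
                 lr_schedule = lr_schedule, gamma = gamma,
                 alpha_mode = alpha_mode, beta = beta,
                 lambda1 = lambda1, lambda2 = lambda2,
                 use_fam = use_fam, use_scl = use_scl,
                 n_jitter = as.integer(n_jitter), seed = seed),
            class = "train_config")
}

#' Initialize a detector
#'
#' Builds the frozen backbone and the trainable parameter set (RPN-lite,
#' heads, FAM, contrastive head) for the given foreground classes.
#' Classifier columns map to `class_ids` in order; the last column is
#' background. Heads start at zero (uniform initial probabilities); FAM and
#' the contrastive head use Kaiming-style initialization.
#'
#' @param cfg A [model_config()].
#' @param class_ids Foreground category ids the classifier predicts.
#' @param seed Integer seed (backbone filters and head init).
#' @return List of class `fs_detector`.
#' @export
init_detector <- function(cfg, class_ids, seed = 0) {
  stopifnot(inherits(cfg, "model_config"))
  D <- cfg$feature_dim
  C <- length(class_ids)
  rpn_dim <- 9L * cfg$fpn_dim
  bb <- backbone_init(cfg$channels, cfg$fpn_dim, seed = seed)
  fam <- fam_params(D, cfg$d_k, alpha = 0.5, seed = derive_seed(seed, "fam"))
  scl <- scl_head_params(D, cfg$d_e, seed = derive_seed(seed, "scl"))
  anchors <- build_anchors(cfg)
  n_types <- anchors$n_types
  par <- list(
    rpn_w = matrix(0, rpn_dim, n_types), rpn_b = numeric(n_types),
    rpn_dw = matrix(0, rpn_dim, 4 * n_types), rpn_db = numeric(4 * n_types),
    W_cls = matrix(0, D, C + 1), b_cls = numeric(C + 1),
    W_reg = matrix(0, D, 4), b_reg = numeric(4),
    fam_Wq = fam$W_q, fam_Wk = fam$W_k, fam_Wv = fam$W_v, fam_Wo = fam$W_o,
    fam_alpha = fam$alpha,
    scl_W1 = scl$W1, scl_b1 = scl$b1, scl_W2 = scl$W2, scl_b2 = scl$b2
  )
  structure(list(cfg = cfg, class_ids = class_ids, backbone = bb, par = par,
                 anchors = anchors, support_bank = NULL, seed = seed),
            class = "fs_detector")
}

#' @export
print.fs_detector <- function(x, ...) {
  cat(sprintf("<fs_detector> %d classes, D = %d, %d anchors, proposals: %s\n",
              length(x$class_ids), x$cfg$feature_dim, nrow(x$anchors$boxes),
              x$cfg$proposal_source))
  invisible(x)
}

# Dense anchor grid over the pyramid levels: xyxy boxes plus the level,
# feature-cell index and anchor-type index (each scale at each level is a
# distinct type with its own RPN score/delta weights, as in a standard RPN
# where the k anchors per cell have k score and 4k delta outputs).
build_anchors <- function(cfg) {
  boxes <- list(); level <- list(); cell <- list(); type <- list()
  sz <- cfg$image_size
  ty <- 0L
  for (l in seq_along(cfg$strides)) {
    st <- cfg$strides[l]
    n <- sz %/% st
    cx <- (rep(seq_len(n), each = n) - 0.5) * st   # column-major over (row, col)
    cy <- (rep(seq_len(n), times = n) - 0.5) * st
    cid <- (rep(seq_len(n), each = n) - 1) * n + rep(seq_len(n), times = n)
    for (s in cfg$anchor_scales[[l]]) {
      ty <- ty + 1L
      boxes[[length(boxes) + 1L]] <-
        cbind(cx - s / 2, cy - s / 2, cx + s / 2, cy + s / 2)
      level[[length(level) + 1L]] <- rep(l, n * n)
      cell[[length(cell) + 1L]] <- cid
      type[[length(type) + 1L]] <- rep(ty, n * n)
    }
  }
  list(boxes = do.call(rbind, boxes), level = unlist(level),
       cell = unlist(cell), type = unlist(type), n_types = ty)
}

# RPN outputs (objectness logit + 4 deltas) for anchors with features `af`
# (unit-norm rows): per-type weight columns. Objectness reads the raw
# features (colour matters for object-vs-background); the delta branch reads
# spatially standardized features (`af_reg`) so localization is
# appearance-invariant.
rpn_forward <- function(par, af, types, af_reg = NULL) {
  if (is.null(af_reg)) af_reg <- af
  n <- nrow(af)
  z <- numeric(n); deltas <- matrix(0, n, 4)
  for (t in unique(types)) {
    r <- which(types == t)
    z[r] <- af[r, , drop = FALSE] %*% par$rpn_w[, t] + par$rpn_b[t]
    deltas[r, ] <- af_reg[r, , drop = FALSE] %*%
      par$rpn_dw[, (4 * t - 3):(4 * t)] +
      matrix(par$rpn_db[(4 * t - 3):(4 * t)], length(r), 4, byrow = TRUE)
  }
  list(logit = z, deltas = deltas)
}

# 3x3-neighbourhood RPN features for every cell of every level:
# list per level of (H_l*W_l) x (9*fpn_dim) matrices.
rpn_cell_features <- function(pyramid, fpn_dim) {
  lapply(pyramid, function(P) {
    Hf <- dim(P)[1]; Wf <- dim(P)[2]
    Pm <- matrix(P, Hf * Wf, fpn_dim)
    cols <- list()
    idx_r <- rep(seq_len(Hf), times = Wf)
    idx_c <- rep(seq_len(Wf), each = Hf)
    for (dr in -1:1) for (dc in -1:1) {
      rr <- pmin(pmax(idx_r + dr, 1), Hf)
      cc <- pmin(pmax(idx_c + dc, 1), Wf)
      cols[[length(cols) + 1L]] <- Pm[(cc - 1) * Hf + rr, , drop = FALSE]
    }
    do.call(cbind, cols)
  })
}

# Standard box-delta encoding (dx, dy, dw, dh) from proposals to targets.
encode_deltas <- function(proposals, gts) {
  pw <- proposals[, 3] - proposals[, 1]; ph <- proposals[, 4] - proposals[, 2]
  px <- proposals[, 1] + pw / 2; py <- proposals[, 2] + ph / 2
  gw <- gts[, 3] - gts[, 1]; gh <- gts[, 4] - gts[, 2]
  gx <- gts[, 1] + gw / 2; gy <- gts[, 2] + gh / 2
  cbind((gx - px) / pw, (gy - py) / ph, log(gw / pw), log(gh / ph))
}

decode_deltas <- function(boxes, deltas, image_size = NULL, clamp = 2) {
  pw <- boxes[, 3] - boxes[, 1]; ph <- boxes[, 4] - boxes[, 2]
  px <- boxes[, 1] + pw / 2; py <- boxes[, 2] + ph / 2
  d <- as.matrix(deltas)
  d <- pmin(pmax(d, -clamp), clamp)
  gx <- px + d[, 1] * pw; gy <- py + d[, 2] * ph
  gw <- pw * exp(d[, 3]); gh <- ph * exp(d[, 4])
  out <- cbind(gx - gw / 2, gy - gh / 2, gx + gw / 2, gy + gh / 2)
  if (!is.null(image_size)) {
    out[, c(1, 3)] <- pmin(pmax(out[, c(1, 3)], 0), image_size)
    out[, c(2, 4)] <- pmin(pmax(out[, c(2, 4)], 0), image_size)
  }
  out
}

#' Assign classification and regression targets to proposals
#'
#' A proposal is positive iff its maximum IoU over the ground-truth boxes
#' reaches `iou_pos`; it is labeled by the arg-max ground truth (ties break
#' toward the lower ground-truth index) and receives the standard
#' `(dx, dy, dw, dh)` delta encoding toward it. All other proposals are
#' background. With no ground truths everything is background.
#'
#' @param proposals `N x 4` matrix of `x1,y1,x2,y2` proposal boxes.
#' @param gt_boxes `M x 4` matrix of ground-truth boxes (or NULL).
#' @param gt_labels Length-M ground-truth class labels.
#' @param iou_pos Positive IoU threshold in (0, 1).
#' @return List with `labels` (0 = background, else the matched
#'   `gt_labels` value), `targets` (`N x 4` deltas, zero rows for
#'   background), `positive` (logical), `gt_index` (matched row or NA).
#' @export
assign_targets <- function(proposals, gt_boxes, gt_labels, iou_pos) {
  assert_that(iou_pos > 0 && iou_pos < 1, "iou_pos must be in (0, 1)")
  proposals <- if (is.null(dim(proposals))) matrix(proposals, nrow = 1) else as.matrix(proposals)
  N <- nrow(proposals)
  labels <- rep(0L, N); targets <- matrix(0, N, 4)
  gt_index <- rep(NA_integer_, N)
  if (!is.null(gt_boxes) && length(gt_boxes) > 0 && nrow(as.matrix(gt_boxes)) > 0) {
    gt_boxes <- as.matrix(gt_boxes)
    iou <- box_iou(proposals, gt_boxes)
    best <- max.col(iou, ties.method = "first")
    best_iou <- iou[cbind(seq_len(N), best)]
    pos <- best_iou >= iou_pos
    if (any(pos)) {
      labels[pos] <- gt_labels[best[pos]]
      gt_index[pos] <- best[pos]
      targets[pos, ] <- encode_deltas(proposals[pos, , drop = FALSE],
                                      gt_boxes[best[pos], , drop = FALSE])
    }
  }
  list(labels = labels, targets = targets, positive = labels > 0L,
       gt_index = gt_index)
}

#' Greedy non-maximum suppression
#'
#' Suppresses any box whose IoU with an already-kept higher-scoring box
#' exceeds `iou_thr`, and optionally (`contain_thr < 1`) any box mostly
#' contained in a kept box — intersection over the smaller area above
#' `contain_thr` — which removes part-detections nested inside a stronger
#' full-object detection even when their IoU is small.
#'
#' @param boxes `N x 4` `x1,y1,x2,y2` matrix.
#' @param scores Length-N scores.
#' @param iou_thr Suppression IoU threshold.
#' @param contain_thr Intersection-over-minimum-area suppression threshold;
#'   1 (default) disables containment suppression.
#' @return Integer indices of the kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_thr = 0.5, contain_thr = 1) {
  boxes <- if (is.null(dim(boxes))) matrix(boxes, nrow = 1) else as.matrix(boxes)
  area <- pmax(boxes[, 3] - boxes[, 1], 0) * pmax(boxes[, 4] - boxes[, 2], 0)
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    iw <- pmax(pmin(boxes[rest, 3], boxes[i, 3]) -
                 pmax(boxes[rest, 1], boxes[i, 1]), 0)
    ih <- pmax(pmin(boxes[rest, 4], boxes[i, 4]) -
                 pmax(boxes[rest, 2], boxes[i, 2]), 0)
    inter <- iw * ih
    iou <- inter / (area[i] + area[rest] - inter)
    iomin <- inter / pmin(area[i], area[rest])
    ord <- rest[iou <= iou_thr & iomin <= contain_thr]
  }
  keep
}

# ---------------------------------------------------------------------------
# Image cache: pyramid + RPN cell features + ground truth per image.

prepare_image_cache <- function(model, manifest, images = NULL) {
  cfg <- model$cfg
  ids <- manifest$images$image_id
  cache <- vector("list", length(ids))
  names(cache) <- as.character(ids)
  for (k in seq_along(ids)) {
    id <- ids[k]
    img <- if (!is.null(images)) images[[as.character(id)]] else {
      path <- file.path(manifest$root %||% ".",
                        manifest$images$file_name[k])
      arr <- png::readPNG(path)
      if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
      arr[, , 1:3, drop = FALSE]
    }
    pyr <- backbone_forward(img, model$backbone)
    ann <- manifest$annotations[manifest$annotations$image_id == id, ]
    gtb <- if (nrow(ann)) xywh_to_xyxy(ann[, c("x", "y", "w", "h")]) else NULL
    cache[[k]] <- list(
      pyramid = pyr,
      rpn_feat = rpn_cell_features(pyr, cfg$fpn_dim),
      gt_boxes = gtb, gt_labels = ann$category_id
    )
  }
  cache
}

anchor_features <- function(model, entry) {
  an <- model$anchors
  feats <- matrix(0, nrow(an$boxes), 9L * model$cfg$fpn_dim)
  for (l in unique(an$level)) {
    sel <- an$level == l
    feats[sel, ] <- entry$rpn_feat[[l]][an$cell[sel], , drop = FALSE]
  }
  feats / pmax(sqrt(rowSums(feats^2)), 1e-8)
}

# ---------------------------------------------------------------------------
# Support bank: pooled (and optionally FAM-input) features of every
# ground-truth box of a support manifest, with labels and class counts.

build_support_bank <- function(model, manifest, cache = NULL) {
  if (is.null(cache)) cache <- prepare_image_cache(model, manifest)
  feats <- list(); labels <- integer(0); cells <- list()
  for (id in names(cache)) {
    e <- cache[[id]]
    if (is.null(e$gt_boxes)) next
    f <- roi_align(e$pyramid, e$gt_boxes, model$cfg$strides, model$cfg$roi_size)
    feats[[length(feats) + 1L]] <- f
    labels <- c(labels, e$gt_labels)
    # centre-cell 3x3 neighbourhood feature at the box's pyramid level, for
    # support-prototype proposal matching
    lev <- roi_level(e$gt_boxes)
    for (k in seq_len(nrow(e$gt_boxes))) {
      st <- model$cfg$strides[lev[k]]
      n <- model$cfg$image_size %/% st
      cxy <- (e$gt_boxes[k, 1:2] + e$gt_boxes[k, 3:4]) / 2
      col <- pmin(pmax(ceiling(cxy[1] / st), 1), n)
      row <- pmin(pmax(ceiling(cxy[2] / st), 1), n)
      cells[[length(cells) + 1L]] <- e$rpn_feat[[lev[k]]][(col - 1) * n + row, ]
    }
  }
  features <- do.call(rbind, feats)
  cellm <- do.call(rbind, cells)
  cellm <- cellm / pmax(sqrt(rowSums(cellm^2)), 1e-8)
  protos <- t(vapply(sort(unique(labels)), function(cl) {
    v <- colMeans(cellm[labels == cl, , drop = FALSE])
    v / max(sqrt(sum(v^2)), 1e-8)
  }, numeric(ncol(cellm))))
  counts <- table(labels)
  list(features = features, labels = labels,
       cell_prototypes = protos,
       class_counts = setNames(as.numeric(counts), names(counts)))
}

# ---------------------------------------------------------------------------
# One training batch: forward, losses, analytic gradients.

fam_params_from_par <- function(par, d_k) {
  structure(list(W_q = par$fam_Wq, W_k = par$fam_Wk, W_v = par$fam_Wv,
                 W_o = par$fam_Wo, alpha = par$fam_alpha,
                 d_k = as.integer(d_k)),
            class = "fam_params")
}

zero_grads <- function(par) lapply(par, function(p) p * 0)

# Sample training proposals for one image: ground-truth boxes, jittered
# copies, and background anchors with low IoU.
sample_proposals <- function(model, entry, n_jitter, n_neg = 16) {
  gtb <- entry$gt_boxes
  props <- NULL
  if (!is.null(gtb)) {
    jit <- list(gtb)
    for (j in seq_len(n_jitter)) {
      # widening jitter spectrum: early copies stay tight (IoU ~0.8+), later
      # ones are loose (IoU ~0.5), covering the proposal quality range the
      # regression head must correct at inference
      s_shift <- 0.04 + 0.06 * (j - 1)
      s_scale <- 0.06 + 0.08 * (j - 1)
      w <- gtb[, 3] - gtb[, 1]; h <- gtb[, 4] - gtb[, 2]
      cx <- (gtb[, 1] + gtb[, 3]) / 2 + rnorm(nrow(gtb), 0, s_shift) * w
      cy <- (gtb[, 2] + gtb[, 4]) / 2 + rnorm(nrow(gtb), 0, s_shift) * h
      sw <- w * exp(rnorm(nrow(gtb), 0, s_scale))
      sh <- h * exp(rnorm(nrow(gtb), 0, s_scale))
      jit[[j + 1L]] <- cbind(cx - sw / 2, cy - sh / 2, cx + sw / 2, cy + sh / 2)
    }
    # interior part-crops of each object as explicit background negatives:
    # on colour-homogeneous objects a sub-patch classifies like the whole
    # object, so the classifier must be taught that partial boxes are not
    # detections (their IoU with the ground truth stays below any positive
    # threshold in use)
    w <- gtb[, 3] - gtb[, 1]; h <- gtb[, 4] - gtb[, 2]
    for (j in 1:2) {
      sc <- runif(nrow(gtb), 0.35, 0.55)
      ox <- runif(nrow(gtb), 0, 1 - sc); oy <- runif(nrow(gtb), 0, 1 - sc)
      jit[[length(jit) + 1L]] <- cbind(gtb[, 1] + ox * w, gtb[, 2] + oy * h,
                                       gtb[, 1] + (ox + sc) * w,
                                       gtb[, 2] + (oy + sc) * h)
    }
    props <- do.call(rbind, jit)
  }
  an <- model$anchors$boxes
  cand <- an[sample(nrow(an), min(4 * n_neg, nrow(an))), , drop = FALSE]
  if (!is.null(gtb)) {
    maxiou <- apply(box_iou(cand, gtb), 1, max)
    cand <- cand[maxiou < 0.3, , drop = FALSE]
  }
  if (nrow(cand) > n_neg) cand <- cand[seq_len(n_neg), , drop = FALSE]
  sz <- model$cfg$image_size
  props <- rbind(props, cand)
  props[, c(1, 3)] <- pmin(pmax(props[, c(1, 3)], 0), sz)
  props[, c(2, 4)] <- pmin(pmax(props[, c(2, 4)], 0), sz)
  ok <- (props[, 3] - props[, 1]) >= 2 & (props[, 4] - props[, 2]) >= 2
  props[ok, , drop = FALSE]
}

batch_step <- function(model, cache, batch_ids, cfg, opts) {
  par <- model$par
  grads <- zero_grads(par)
  C <- length(model$class_ids)
  cls_col <- setNames(seq_len(C), model$class_ids)
  loss_rpn_cls <- 0; loss_rpn_reg <- 0
  E_all <- list(); y_all <- list(); pos_tgt <- list(); pos_rows <- list()
  fam_caches <- list()
  n_rpn <- 0
  for (id in batch_ids) {
    e <- cache[[as.character(id)]]
    # --- RPN-lite: objectness + deltas on sampled anchors -------------------
    an <- model$anchors
    lab <- assign_targets(an$boxes, e$gt_boxes, rep(1L, length(e$gt_labels)),
                          iou_pos = 0.5)
    neg_mask <- rep(TRUE, nrow(an$boxes))
    if (!is.null(e$gt_boxes)) {
      maxiou <- apply(box_iou(an$boxes, e$gt_boxes), 1, max)
      neg_mask <- maxiou < 0.3
    }
    pos_idx <- which(lab$positive)
    neg_idx <- which(neg_mask)
    if (length(pos_idx) > 16) pos_idx <- sample(pos_idx, 16)
    neg_idx <- sample(neg_idx, min(16, length(neg_idx)))
    sel <- c(pos_idx, neg_idx)
    if (length(sel) > 0) {
      af <- anchor_features(model, e)[sel, , drop = FALSE]
      af_std <- spatial_standardize_cells(af, model$cfg$fpn_dim)
      types <- an$type[sel]
      t_obj <- c(rep(1, length(pos_idx)), rep(0, length(neg_idx)))
      fw <- rpn_forward(par, af, types, af_reg = af_std)
      p <- 1 / (1 + exp(-fw$logit))
      loss_rpn_cls <- loss_rpn_cls - sum(t_obj * log(pmax(p, 1e-12)) +
                                           (1 - t_obj) * log(pmax(1 - p, 1e-12)))
      dz <- (p - t_obj)
      np <- length(pos_idx)
      dT <- NULL
      if (np > 0) {
        tgt <- lab$targets[pos_idx, , drop = FALSE]
        pred <- fw$deltas[seq_len(np), , drop = FALSE]
        loss_rpn_reg <- loss_rpn_reg + smooth_l1_loss(pred, tgt, cfg$beta) * np
        dT <- smooth_l1_grad(pred, tgt, cfg$beta) * np
      }
      for (t in unique(types)) {
        r <- which(types == t)
        grads$rpn_w[, t] <- grads$rpn_w[, t] +
          as.vector(crossprod(af[r, , drop = FALSE], dz[r]))
        grads$rpn_b[t] <- grads$rpn_b[t] + sum(dz[r])
        rp <- r[r <= np]
        if (length(rp) > 0) {
          cols <- (4 * t - 3):(4 * t)
          grads$rpn_dw[, cols] <- grads$rpn_dw[, cols] +
            crossprod(af_std[rp, , drop = FALSE], dT[rp, , drop = FALSE])
          grads$rpn_db[cols] <- grads$rpn_db[cols] +
            colSums(dT[rp, , drop = FALSE])
        }
      }
      n_rpn <- n_rpn + length(sel)
    }
    # --- Head proposals ----------------------------------------------------
    # In "rpn" mode the head trains on the live RPN proposals plus jittered
    # ground truth (guaranteeing positives early in training), matching the
    # proposal distribution the head sees at inference.
    props <- switch(cfg_proposal_source(model, opts),
      groundtruth = e$gt_boxes,
      jittered_groundtruth = sample_proposals(model, e, cfg$n_jitter),
      rpn = {
        pr <- sample_proposals(model, e, cfg$n_jitter)
        rp <- rpn_propose(model, e, pre_nms = 100, post_nms = 12)
        pr <- if (!is.null(rp)) rbind(pr, rp) else pr
        # with a support bank, support-guided proposals appear at inference;
        # train the head on them too so partial matches learn their labels
        if (!is.null(opts$support) && !is.null(model$support_bank)) {
          sg <- prototype_propose(model, e, top_cells = 4)
          if (!is.null(sg)) {
            keep_sg <- sample(nrow(sg$boxes), min(8, nrow(sg$boxes)))
            pr <- rbind(pr, sg$boxes[keep_sg, , drop = FALSE])
          }
        }
        pr
      })
    if (is.null(props) || nrow(props) == 0) next
    asg <- assign_targets(props, e$gt_boxes, e$gt_labels, opts$iou_pos)
    Fq <- roi_align(e$pyramid, props, model$cfg$strides, model$cfg$roi_size)
    E_all[[length(E_all) + 1L]] <- Fq
    y <- ifelse(asg$labels == 0L, C + 1L, cls_col[as.character(asg$labels)])
    y_all[[length(y_all) + 1L]] <- as.integer(y)
    pos_tgt[[length(pos_tgt) + 1L]] <- asg$targets[asg$positive, , drop = FALSE]
    pos_rows[[length(pos_rows) + 1L]] <- asg$positive
  }
  if (length(E_all) == 0) {
    return(list(bundle = total_loss(0, 0, 0, 0, opts$lambda1, opts$lambda2),
                grads = grads))
  }
  Fq <- do.call(rbind, E_all)
  y <- unlist(y_all)
  positive <- unlist(pos_rows)
  targets <- do.call(rbind, pos_tgt)
  N <- nrow(Fq)

  # --- FAM ------------------------------------------------------------------
  use_fam <- isTRUE(opts$use_fam) && !is.null(opts$support)
  agg <- list(L_agg = 0)
  if (use_fam) {
    fp <- fam_params_from_par(par, model$cfg$d_k)
    fc <- fam_forward(Fq, opts$support$features, fp)
    E <- fc$F_enhanced
    agg <- aggregation_loss(fc$scores, fc$weights)
  } else {
    E <- Fq
  }

  # --- Classification (focal) ----------------------------------------------
  logits <- E %*% par$W_cls + matrix(par$b_cls, N, C + 1, byrow = TRUE)
  if (!all(is.finite(logits))) {
    # diverged weights: signal the training loop to stop at the last good state
    nan_bundle <- tibble(cls = NaN, reg = NaN, agg = NaN, scl = NaN,
                         lambda1 = opts$lambda1, lambda2 = opts$lambda2,
                         total = NaN)
    return(list(bundle = nan_bundle, grads = grads))
  }
  P <- row_softmax(logits)
  L_cls_head <- focal_loss(P, y, cfg$gamma, opts$alpha_t)
  dlogits <- focal_grad_logits(P, y, cfg$gamma, opts$alpha_t)
  grads$W_cls <- grads$W_cls + crossprod(E, dlogits)
  grads$b_cls <- grads$b_cls + colSums(dlogits)
  dE <- dlogits %*% t(par$W_cls)

  # --- Regression (smooth L1 on positives) ---------------------------------
  # The regression branch reads spatially standardized pre-FAM RoI features
  # (appearance-invariant localization); classification and SCL read the
  # FAM-enhanced features.
  L_reg_head <- 0
  if (any(positive)) {
    Ep <- spatial_standardize_roi(Fq[positive, , drop = FALSE],
                                  model$cfg$roi_size^2, model$cfg$fpn_dim)
    pred <- Ep %*% par$W_reg + matrix(par$b_reg, sum(positive), 4, byrow = TRUE)
    L_reg_head <- smooth_l1_loss(pred, targets, cfg$beta)
    dT <- smooth_l1_grad(pred, targets, cfg$beta)
    grads$W_reg <- grads$W_reg + crossprod(Ep, dT)
    grads$b_reg <- grads$b_reg + colSums(dT)
  }

  # --- Supervised contrastive loss on positive RoIs ------------------------
  L_scl <- 0
  if (isTRUE(opts$use_scl) && sum(positive) >= 2) {
    rows <- which(positive)
    Ep <- E[rows, , drop = FALSE]
    lab_p <- y[rows]
    head <- structure(list(W1 = par$scl_W1, b1 = par$scl_b1,
                           W2 = par$scl_W2, b2 = par$scl_b2),
                      class = "scl_head")
    H1 <- pmax(sweep(Ep %*% head$W1, 2, head$b1, "+"), 0)
    Zr <- sweep(H1 %*% head$W2, 2, head$b2, "+")
    nrm <- sqrt(rowSums(Zr^2))
    if (all(nrm > 1e-12)) {
      z <- Zr / nrm
      counts <- opts$scl_counts
      cw <- if (is.null(counts)) NULL else {
        setNames(as.numeric(counts[as.character(model$class_ids)]),
                 seq_along(model$class_ids))
      }
      L_scl <- supcon_loss(z, lab_p, opts$tau, weighted = TRUE,
                           class_counts = cw)
      if (L_scl > 0 && opts$lambda2 > 0) {
        dz <- supcon_grad(z, lab_p, opts$tau, weighted = TRUE,
                          class_counts = cw) * opts$lambda2
        # back through row normalization: dZr = (dz - z * rowSums(dz*z))/nrm
        dZr <- (dz - z * rowSums(dz * z)) / nrm
        dH1 <- (dZr %*% t(head$W2)) * (H1 > 0)
        grads$scl_W2 <- grads$scl_W2 + crossprod(H1, dZr)
        grads$scl_b2 <- grads$scl_b2 + colSums(dZr)
        grads$scl_W1 <- grads$scl_W1 + crossprod(Ep, dH1)
        grads$scl_b1 <- grads$scl_b1 + colSums(dH1)
        dE[rows, ] <- dE[rows, ] + dH1 %*% t(head$W1)
      }
    }
  }

  # --- FAM backward (classification/regression/SCL paths + regularizer) ----
  if (use_fam) {
    ag <- aggregation_grad(fc$scores, fc$weights)
    fb <- fam_backward(fc, dE,
                       dS_extra = opts$lambda1 * ag$dS,
                       dA_extra = opts$lambda1 * ag$dA)
    grads$fam_Wq <- grads$fam_Wq + fb$W_q
    grads$fam_Wk <- grads$fam_Wk + fb$W_k
    grads$fam_Wv <- grads$fam_Wv + fb$W_v
    grads$fam_Wo <- grads$fam_Wo + fb$W_o
    grads$fam_alpha <- grads$fam_alpha + fb$alpha
  }

  rpn_scale <- 1 / max(n_rpn, 1)
  grads$rpn_w <- grads$rpn_w * rpn_scale
  grads$rpn_b <- grads$rpn_b * rpn_scale
  grads$rpn_dw <- grads$rpn_dw / max(length(batch_ids), 1)
  grads$rpn_db <- grads$rpn_db / max(length(batch_ids), 1)
  L_cls <- L_cls_head + loss_rpn_cls * rpn_scale
  L_reg <- L_reg_head + loss_rpn_reg / max(length(batch_ids), 1)
  comps <- c(L_cls, L_reg, agg$L_agg, L_scl)
  if (!all(is.finite(comps))) {
    bundle <- tibble(cls = L_cls, reg = L_reg, agg = agg$L_agg, scl = L_scl,
                     lambda1 = opts$lambda1, lambda2 = opts$lambda2,
                     total = NaN)
    return(list(bundle = bundle, grads = grads))
  }
  bundle <- total_loss(L_cls, L_reg, agg$L_agg, L_scl,
                       opts$lambda1, opts$lambda2)
  list(bundle = bundle, grads = grads)
}

cfg_proposal_source <- function(model, opts) {
  opts$proposal_source %||% model$cfg$proposal_source
}

# SGD with momentum + weight decay on matrices, with global-norm gradient
# clipping (SGD on the piecewise-linear losses can overshoot on small
# few-shot batches; clipping keeps the update bounded).
sgd_update <- function(par, grads, state, lr, momentum, weight_decay,
                       clip_norm = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  scale <- if (is.finite(gn) && gn > clip_norm) clip_norm / gn else 1
  decay_on <- c("rpn_w", "rpn_dw", "W_cls", "W_reg", "fam_Wq", "fam_Wk",
                "fam_Wv", "fam_Wo", "scl_W1", "scl_W2")
  for (nm in names(par)) {
    g <- grads[[nm]] * scale
    if (nm %in% decay_on) g <- g + weight_decay * par[[nm]]
    v <- momentum * state[[nm]] - lr * g
    state[[nm]] <- v
    par[[nm]] <- par[[nm]] + v
  }
  list(par = par, state = state)
}

schedule_lr <- function(cfg, iter) {
  if (cfg$lr_schedule == "step") {
    if (iter > floor(2 * cfg$iters / 3)) cfg$lr * 0.1 else cfg$lr
  } else {
    cfg$lr * 0.5 * (1 + cos(pi * (iter - 1) / cfg$iters))
  }
}

focal_alpha_weights <- function(manifest, class_ids, mode) {
  if (mode == "none") return(1)
  cnt <- manifest$per_class_counts
  n <- setNames(cnt$n_boxes, cnt$category_id)[as.character(class_ids)]
  n[is.na(n) | n == 0] <- 1
  w <- (1 / n) / mean(1 / n)        # normalized inverse frequency, mean 1
  c(w, 1)                          # background weight 1
}

# Core training loop shared by the base stage and fine-tuning.
train_detector <- function(model, manifest, cfg, val_manifest = NULL,
                           opts = list(), cache = NULL, images = NULL) {
  stopifnot(inherits(model, "fs_detector"), inherits(cfg, "train_config"))
  assert_that(nrow(manifest$annotations) > 0, "training data is empty")
  if (is.null(cache)) cache <- prepare_image_cache(model, manifest, images)
  opts$iou_pos <- opts$iou_pos %||% 0.5
  opts$tau <- opts$tau %||% 0.2
  opts$lambda1 <- opts$lambda1 %||% cfg$lambda1
  opts$lambda2 <- opts$lambda2 %||% cfg$lambda2
  opts$use_fam <- opts$use_fam %||% cfg$use_fam
  opts$use_scl <- opts$use_scl %||% cfg$use_scl
  opts$alpha_t <- focal_alpha_weights(manifest, model$class_ids, cfg$alpha_mode)
  state <- zero_grads(model$par)
  history <- vector("list", cfg$iters)
  last_good <- model$par
  best <- list(map = -Inf, par = model$par, lr = cfg$lr)
  img_ids <- manifest$images$image_id
  img_ids <- img_ids[vapply(as.character(img_ids),
                            function(i) !is.null(cache[[i]]$gt_boxes), TRUE)]
  assert_that(length(img_ids) > 0, "no annotated images to train on")
  # optional sampler weights (e.g. oversampling of novel-class images)
  wts <- opts$img_weights
  wts <- if (is.null(wts)) rep(1, length(img_ids)) else wts[as.character(img_ids)]
  with_seed(derive_seed(cfg$seed, "train"), {
    for (it in seq_len(cfg$iters)) {
      ids <- if (length(img_ids) <= cfg$batch_size) img_ids else
        sample(img_ids, cfg$batch_size, prob = wts)
      step <- batch_step(model, cache, ids, cfg, opts)
      if (!is.finite(step$bundle$total)) {
        warn(sprintf("non-finite loss at iteration %d; stopping at last good state", it))
        model$par <- last_good
        break
      }
      last_good <- model$par
      lr <- schedule_lr(cfg, it)
      upd <- sgd_update(model$par, step$grads, state, lr, cfg$momentum,
                        cfg$weight_decay)
      model$par <- upd$par; state <- upd$state
      history[[it]] <- dplyr::mutate(step$bundle, iter = it, lr = lr)
      if (!is.null(val_manifest) && it %% cfg$eval_interval == 0) {
        ev <- suppressWarnings(
          evaluate_detections(detect(model, val_manifest), val_manifest))
        if (is.finite(ev$map) && ev$map >= best$map) {
          best <- list(map = ev$map, par = model$par, lr = lr)
        }
      }
    }
  })
  if (is.finite(best$map) && best$map > -Inf) model$par <- best$par
  model$optimizer_state <- state
  model$lr <- if (best$map > -Inf) best$lr else schedule_lr(cfg, cfg$iters)
  model$history <- dplyr::bind_rows(history[!vapply(history, is.null, TRUE)])
  model
}

#' Base-stage training
#'
#' Trains the detector on base-class images only (images carrying any
#' novel-class annotation are excluded so novel classes stay unseen), with
#' the plain `L_cls + L_reg` objective by default; FAM/SCL can be switched on
#' via `cfg$use_fam`/`cfg$use_scl` for ablations. When a validation manifest
#' is given, the checkpoint with the highest validation mAP50 (evaluated
#' every `cfg$eval_interval` iterations) is returned.
#'
#' @param model An [init_detector()] whose `class_ids` are the base classes.
#' @param manifest Training manifest (all classes; filtered internally).
#' @param cfg A [train_config()].
#' @param val_manifest Optional validation manifest for checkpoint selection.
#' @param images Optional named list of in-memory image arrays keyed by
#'   image id (bypasses PNG reading).
#' @return The trained `fs_detector` (with `$history` of per-iteration
#'   losses, `$optimizer_state` and `$lr`).
#' @export
train_base <- function(model, manifest, cfg, val_manifest = NULL,
                       images = NULL) {
  base_ids <- model$class_ids
  keep_ann <- manifest$annotations$category_id %in% base_ids
  bad_imgs <- unique(manifest$annotations$image_id[!keep_ann])
  keep_imgs <- setdiff(manifest$images$image_id, bad_imgs)
  m <- subset_manifest(manifest, keep_imgs)
  assert_that(nrow(m$annotations) > 0, "no base-class training data")
  train_detector(model, m, cfg, val_manifest = val_manifest, images = images)
}

#' K-shot fine-tuning
#'
#' Extends the base-stage classifier to base + novel classes, builds the
#' support bank from the K-shot set's ground-truth RoI features (the bank
#' conditions the FAM at both training and inference time), and optimizes
#' the full multi-task objective
#' `L_cls + L_reg + lambda1 * L_agg + lambda2 * L_SCL` with the
#' shot-specific positive-IoU threshold, temperature and loss weights.
#' Contrastive class counts come from the support set, tying the
#' inverse-frequency weights to dataset-level scarcity.
#'
#' @param model A base-trained `fs_detector`.
#' @param kshot_manifest The balanced K-shot manifest (see [sample_kshot()]).
#' @param split The `class_split`; every novel class must appear in the
#'   K-shot set.
#' @param shot_cfg A [shot_config()].
#' @param cfg A [train_config()] (typically with the fine-tuning learning
#'   rate); `use_fam`/`use_scl` default to `TRUE` here.
#' @param val_manifest Optional validation manifest for checkpoint selection.
#' @param use_fam,use_scl Ablation switches.
#' @param images Optional in-memory images (as in [train_base()]).
#' @return The fine-tuned `fs_detector` covering base + novel classes.
#' @export
finetune <- function(model, kshot_manifest, split, shot_cfg, cfg,
                     val_manifest = NULL, use_fam = TRUE, use_scl = TRUE,
                     images = NULL) {
  stopifnot(inherits(shot_cfg, "shot_config"))
  present <- unique(kshot_manifest$annotations$category_id)
  missing <- setdiff(split$novel, present)
  if (length(missing) > 0) {
    abort(sprintf("novel class %s absent from the K-shot set",
                  paste(missing, collapse = ", ")))
  }
  old_ids <- model$class_ids
  new_ids <- c(old_ids, setdiff(c(split$base, split$novel), old_ids))
  D <- model$cfg$feature_dim
  C_new <- length(new_ids)
  W <- matrix(0, D, C_new + 1); b <- numeric(C_new + 1)
  W[, seq_along(old_ids)] <- model$par$W_cls[, seq_along(old_ids)]
  W[, C_new + 1] <- model$par$W_cls[, length(old_ids) + 1]
  b[seq_along(old_ids)] <- model$par$b_cls[seq_along(old_ids)]
  b[C_new + 1] <- model$par$b_cls[length(old_ids) + 1]
  model$par$W_cls <- W; model$par$b_cls <- b
  model$class_ids <- new_ids
  cache <- prepare_image_cache(model, kshot_manifest, images)
  bank <- build_support_bank(model, kshot_manifest, cache)
  model$support_bank <- bank
  # prototype (weight-imprinting) initialization of the new classifier
  # columns: the mean support feature of each novel class, scaled so the
  # novel classes' own-support logits sit just below the base classes'
  # own-support logits. Prototype directions align with raw features far
  # better than discriminatively trained columns do, so matching column
  # NORMS overshoots (a novel prototype can hijack a visually similar base
  # class), while matching the LOGIT scale — with a small headroom factor —
  # starts novel classes visible without flipping base supports;
  # fine-tuning refines from there.
  base_norms <- sqrt(colSums(model$par$W_cls[, seq_along(old_ids), drop = FALSE]^2))
  target_norm <- max(mean(base_norms), 1)
  base_rows <- which(bank$labels %in% old_ids)
  own_logit <- vapply(base_rows, function(r) {
    sum(bank$features[r, ] * model$par$W_cls[, match(bank$labels[r], new_ids)])
  }, 0)
  for (cls in setdiff(new_ids, old_ids)) {
    rows <- which(bank$labels == cls)
    if (length(rows) == 0) next
    proto <- colMeans(bank$features[rows, , drop = FALSE])
    col <- proto / sqrt(sum(proto^2)) * target_norm
    # per-column backoff: a prototype column at full norm can out-score the
    # trained column of a visually similar base class on that class's own
    # support rows (prototype directions align with raw features far better
    # than discriminative ones). Shrink this column just enough that no base
    # support row prefers it, with a small safety margin and a visibility
    # floor; fine-tuning refines from there.
    if (length(base_rows) > 0) {
      raw <- as.vector(bank$features[base_rows, , drop = FALSE] %*% col)
      ok <- raw > 0 & own_logit > 0
      # moderate flips of base supports are recoverable by fine-tuning; what
      # is not recoverable is a large out-scoring margin, so cap the 90th
      # percentile of (novel logit / own logit) on base supports at 1.35
      if (any(ok)) {
        q <- stats::quantile(raw[ok] / own_logit[ok], 0.9, names = FALSE)
        if (q > 1.35) col <- col * max(1.35 / q, 0.2)
      }
    }
    model$par$W_cls[, match(cls, new_ids)] <- col
  }
  model$use_fam <- use_fam
  # oversample images carrying novel-class instances: their classifier
  # columns start nearly fresh and need more gradient exposure than the
  # already-trained base columns
  ann <- kshot_manifest$annotations
  novel_imgs <- unique(ann$image_id[ann$category_id %in% split$novel])
  wts <- setNames(ifelse(kshot_manifest$images$image_id %in% novel_imgs, 2, 1),
                  kshot_manifest$images$image_id)
  opts <- list(iou_pos = shot_cfg$iou_pos, tau = shot_cfg$tau,
               lambda1 = shot_cfg$lambda1, lambda2 = shot_cfg$lambda2,
               use_fam = use_fam, use_scl = use_scl,
               support = if (use_fam) bank else NULL,
               scl_counts = bank$class_counts,
               img_weights = wts)
  train_detector(model, kshot_manifest, cfg, val_manifest = val_manifest,
                 opts = opts, cache = cache)
}

#' Run inference
#'
#' Scores all anchors with the RPN-lite, decodes and NMS-filters proposals,
#' pools RoI features, optionally enhances them through the FAM with the
#' stored support bank, applies the classification and regression heads,
#' then score-thresholds and class-wise NMS-filters the detections.
#' Deterministic given weights and inputs.
#'
#' @param model A trained `fs_detector`.
#' @param manifest Manifest of images to run on.
#' @param images Optional named list of in-memory image arrays.
#' @param proposal_source Override of `model$cfg$proposal_source`
#'   (`"groundtruth"` uses the manifest's boxes as proposals; useful as a
#'   plumbing oracle).
#' @param cache Optional prepared image cache.
#' @return Tibble of detections: `image_id`, `category_id`, `score`, `x`,
#'   `y`, `w`, `h` (COCO-style boxes).
#' @export
detect <- function(model, manifest, images = NULL, proposal_source = NULL,
                   cache = NULL) {
  cfg <- model$cfg
  src <- proposal_source %||% cfg$proposal_source
  if (is.null(cache)) cache <- prepare_image_cache(model, manifest, images)
  C <- length(model$class_ids)
  out <- list()
  for (id_chr in names(cache)) {
    e <- cache[[id_chr]]
    id <- as.integer(id_chr)
    obj_score <- NULL
    props <- if (src == "groundtruth") {
      e$gt_boxes
    } else if (src == "jittered_groundtruth") {
      if (is.null(e$gt_boxes)) NULL else {
        gtb <- e$gt_boxes
        w <- gtb[, 3] - gtb[, 1]; h <- gtb[, 4] - gtb[, 2]
        gtb + cbind(-0.05 * w, -0.05 * h, 0.05 * w, 0.05 * h)
      }
    } else {
      rp <- rpn_propose(model, e, with_scores = TRUE)
      if (is.null(rp)) NULL else { obj_score <- rp$scores; rp$boxes }
    }
    if (is.null(props) || nrow(props) == 0) next
    boxes <- props
    rounds <- max(cfg$refine_rounds, 1L)
    for (round in seq_len(rounds)) {
      Fq <- roi_align(e$pyramid, boxes, cfg$strides, cfg$roi_size)
      E <- if (isTRUE(model$use_fam) && !is.null(model$support_bank)) {
        fp <- fam_params_from_par(model$par, cfg$d_k)
        fam_forward(Fq, model$support_bank$features, fp)$F_enhanced
      } else Fq
      logits <- E %*% model$par$W_cls +
        matrix(model$par$b_cls, nrow(E), C + 1, byrow = TRUE)
      P <- row_softmax(logits)
      Er <- spatial_standardize_roi(Fq, cfg$roi_size^2, cfg$fpn_dim)
      deltas <- Er %*% model$par$W_reg +
        matrix(model$par$b_reg, nrow(Er), 4, byrow = TRUE)
      boxes <- decode_deltas(boxes, deltas, cfg$image_size)
    }
    # each proposal contributes one detection, labeled by its argmax
    # foreground class (emitting every above-threshold class instead floods
    # scarcely-trained novel classes with cross-class false positives)
    cls <- max.col(P[, seq_len(C), drop = FALSE], ties.method = "first")
    score <- P[cbind(seq_len(nrow(P)), cls)]
    # temper by RPN objectness: suppresses confidently-classified clutter
    # in regions the RPN considers background
    if (!is.null(obj_score)) score <- score * sqrt(obj_score)
    keep <- is.finite(score) & score >= cfg$score_thr &
      (boxes[, 3] - boxes[, 1]) > 1 & (boxes[, 4] - boxes[, 2]) > 1
    if (!any(keep)) next
    boxes <- boxes[keep, , drop = FALSE]
    cls <- cls[keep]; score <- score[keep]
    final <- list()
    for (cc in unique(cls)) {
      sel <- which(cls == cc)
      k <- nms(boxes[sel, , drop = FALSE], score[sel], cfg$nms_iou)
      final[[length(final) + 1L]] <- tibble(
        image_id = id, category_id = model$class_ids[cc],
        score = score[sel][k],
        x = boxes[sel[k], 1], y = boxes[sel[k], 2],
        w = boxes[sel[k], 3] - boxes[sel[k], 1],
        h = boxes[sel[k], 4] - boxes[sel[k], 2])
    }
    out[[length(out) + 1L]] <- dplyr::bind_rows(final)
  }
  if (length(out) == 0) {
    return(tibble(image_id = integer(), category_id = integer(),
                  score = numeric(), x = numeric(), y = numeric(),
                  w = numeric(), h = numeric()))
  }
  dplyr::bind_rows(out)
}

rpn_propose <- function(model, entry, pre_nms = 200, post_nms = 50,
                        with_scores = FALSE) {
  af <- anchor_features(model, entry)
  af_std <- spatial_standardize_cells(af, model$cfg$fpn_dim)
  fw <- rpn_forward(model$par, af, model$anchors$type, af_reg = af_std)
  p <- 1 / (1 + exp(-fw$logit))
  topk <- order(p, decreasing = TRUE)[seq_len(min(pre_nms, length(p)))]
  # keep both the regressed boxes (deltas clamped: anchors are dense, only
  # modest corrections are trustworthy) and the raw anchors — regression
  # trained on base classes can mislocalize unseen novel-class appearances,
  # while the raw anchor often already clears IoU 0.5
  ab <- model$anchors$boxes[topk, , drop = FALSE]
  reg <- decode_deltas(ab, fw$deltas[topk, , drop = FALSE],
                       model$cfg$image_size, clamp = 0.5)
  boxes <- rbind(reg, ab)
  pp <- c(p[topk], p[topk] * 0.999)   # prefer the regressed twin under NMS
  ok <- (boxes[, 3] - boxes[, 1]) > 2 & (boxes[, 4] - boxes[, 2]) > 2
  boxes <- boxes[ok, , drop = FALSE]; pp <- pp[ok]
  if (nrow(boxes) == 0) return(NULL)
  k <- nms(boxes, pp, 0.7)
  k <- k[seq_len(min(post_nms, length(k)))]
  out_boxes <- boxes[k, , drop = FALSE]
  out_scores <- pp[k]
  # support-guided proposals: pyramid cells whose 3x3 feature matches a
  # support-class prototype emit their anchors, rescuing objects whose
  # appearance the class-agnostic objectness has never seen as a positive
  if (!is.null(model$support_bank) && !is.null(model$support_bank$cell_prototypes)) {
    sp <- prototype_propose(model, entry, top_cells = 10)
    if (!is.null(sp)) {
      bb2 <- rbind(out_boxes, sp$boxes)
      ss2 <- c(out_scores, sp$scores)
      k2 <- nms(bb2, ss2, 0.7)
      k2 <- k2[seq_len(min(post_nms + 30, length(k2)))]
      out_boxes <- bb2[k2, , drop = FALSE]
      out_scores <- ss2[k2]
    }
  }
  if (with_scores) list(boxes = out_boxes, scores = out_scores)
  else out_boxes
}

prototype_propose <- function(model, entry, top_cells = 10, sim_min = 0.6) {
  protos <- model$support_bank$cell_prototypes
  an <- model$anchors
  boxes <- list(); scores <- list()
  for (l in seq_along(entry$rpn_feat)) {
    Fm <- entry$rpn_feat[[l]]
    Fm <- Fm / pmax(sqrt(rowSums(Fm^2)), 1e-8)
    sim <- Fm %*% t(protos)
    cs <- apply(sim, 1, max)
    ord <- order(cs, decreasing = TRUE)
    ord <- ord[cs[ord] > sim_min]
    ord <- head(ord, top_cells)
    if (length(ord) == 0) next
    sel <- which(an$level == l & an$cell %in% ord)
    if (length(sel) == 0) next
    boxes[[length(boxes) + 1L]] <- an$boxes[sel, , drop = FALSE]
    scores[[length(scores) + 1L]] <- cs[an$cell[sel]]
  }
  if (length(boxes) == 0) return(NULL)
  list(boxes = do.call(rbind, boxes), scores = unlist(scores))
}

#' Save / load a detector checkpoint
#'
#' The checkpoint is a single file holding the model weights, optimizer
#' state and current learning rate (plus config and support bank), so an
#' interrupted pipeline can resume from it.
#'
#' @param model A trained `fs_detector`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `fs_detector` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "fs_detector"))
  m
}
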