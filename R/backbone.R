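# Frozen convolutional feature pyramid.
#
# The detector's trainable parts are the RPN-lite, the RoI heads, the FAM and
# the contrastive head; image features come from a small fixed convolutional
# network with seeded He-initialized random filters (random-features regime),
# followed by an FPN-style top-down pathway projected to a common low channel
# count. Random convolutional features are a standard desk-scale stand-in for
# a pretrained backbone: they preserve colour and local texture linearly and
# are deterministic given the seed.

# 3x3 "same" convolution of an H x W x Cin array with weights
# kh x kw x Cin x Cout, implemented as one matrix product per kernel offset.
conv2d <- function(x, w) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  xm <- matrix(x, H * W, Cin)
  out <- matrix(0, H * W, Cout)
  pr <- (kh - 1) %/% 2; pc <- (kw - 1) %/% 2
  idx_r <- rep(seq_len(H), times = W)
  idx_c <- rep(seq_len(W), each = H)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      dr <- i - 1 - pr; dc <- j - 1 - pc
      rr <- idx_r + dr; cc <- idx_c + dc
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      src <- (cc[ok] - 1) * H + rr[ok]
      Wij <- matrix(w[i, j, , ], Cin, Cout)
      out[ok, ] <- out[ok, ] + xm[src, , drop = FALSE] %*% Wij
    }
  }
  array(out, dim = c(H, W, Cout))
}

relu <- function(x) pmax(x, 0)

# 2x2 max pooling with stride 2 (even input dims assumed; odd rows/cols drop).
maxpool2 <- function(x) {
  H <- dim(x)[1] %/% 2 * 2; W <- dim(x)[2] %/% 2 * 2
  a <- x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
  b <- x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
  d <- x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
  e <- x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
  pmax(pmax(a, b), pmax(d, e))
}

# Nearest-neighbour 2x upsampling.
upsample2 <- function(x, H_out, W_out) {
  r <- rep(seq_len(dim(x)[1]), each = 2)[seq_len(H_out)]
  c <- rep(seq_len(dim(x)[2]), each = 2)[seq_len(W_out)]
  x[r, c, , drop = FALSE]
}

# Initialize the frozen backbone + FPN weights.
backbone_init <- function(channels = c(16, 32, 64, 128), fpn_dim = 12,
                          seed = 0) {
  with_seed(derive_seed(seed, "backbone"), {
    cin <- c(3, channels[-length(channels)])
    stages <- lapply(seq_along(channels), function(s) {
      array(rnorm(9 * cin[s] * channels[s], 0, sqrt(2 / (9 * cin[s]))),
            dim = c(3, 3, cin[s], channels[s]))
    })
    lateral <- lapply(channels[-1], function(ch) {
      matrix(rnorm(ch * fpn_dim, 0, sqrt(1 / ch)), ch, fpn_dim)
    })
    list(stages = stages, lateral = lateral, fpn_dim = fpn_dim,
         strides = c(4, 8, 16))
  })
}

# Forward pass: image (H x W x 3 in [0,1]) -> list of pyramid levels
# P2 (stride 4), P3 (stride 8), P4 (stride 16), each H_l x W_l x fpn_dim.
backbone_forward <- function(image, bb) {
  x <- image - mean(image)
  feats <- list()
  for (s in seq_along(bb$stages)) {
    x <- maxpool2(relu(conv2d(x, bb$stages[[s]])))
    feats[[s]] <- x
  }
  # lateral 1x1 projections of stages 2..4 (strides 4, 8, 16)
  lat <- lapply(2:4, function(s) {
    f <- feats[[s]]
    array(matrix(f, prod(dim(f)[1:2]), dim(f)[3]) %*% bb$lateral[[s - 1]],
          dim = c(dim(f)[1], dim(f)[2], bb$fpn_dim))
  })
  P4 <- lat[[3]]
  P3 <- lat[[2]] + upsample2(P4, dim(lat[[2]])[1], dim(lat[[2]])[2])
  P2 <- lat[[1]] + upsample2(P3, dim(lat[[1]])[1], dim(lat[[1]])[2])
  list(P2 = P2, P3 = P3, P4 = P4)
}

# FPN level (1..3) for a box, by the usual area heuristic at desk scale.
roi_level <- function(boxes_xyxy) {
  s <- sqrt(pmax((boxes_xyxy[, 3] - boxes_xyxy[, 1]) *
                   (boxes_xyxy[, 4] - boxes_xyxy[, 2]), 1))
  ifelse(s < 32, 1L, ifelse(s < 64, 2L, 3L))
}

# RoI Align: bilinear sampling of a roi_size x roi_size grid per box on the
# level chosen by roi_level(). Returns an N x (roi_size^2 * fpn_dim) matrix,
# each row scaled to unit L2 norm (stabilizes head optimization; amplitude
# is not informative for frozen random features).
roi_align <- function(pyramid, boxes_xyxy, strides = c(4, 8, 16),
                      roi_size = 7, normalize = TRUE) {
  boxes_xyxy <- if (is.null(dim(boxes_xyxy))) matrix(boxes_xyxy, nrow = 1) else as.matrix(boxes_xyxy)
  n <- nrow(boxes_xyxy)
  fpn_dim <- dim(pyramid[[1]])[3]
  D <- roi_size^2 * fpn_dim
  out <- matrix(0, n, D)
  lev <- roi_level(boxes_xyxy)
  g <- (seq_len(roi_size) - 0.5) / roi_size
  for (l in unique(lev)) {
    P <- pyramid[[l]]
    Hf <- dim(P)[1]; Wf <- dim(P)[2]
    Pm <- matrix(P, Hf * Wf, fpn_dim)
    rows <- which(lev == l)
    b <- boxes_xyxy[rows, , drop = FALSE]
    # sample centres in image coords, then continuous feature coords
    sx <- b[, 1] + outer(b[, 3] - b[, 1], g)        # n_l x roi_size
    sy <- b[, 2] + outer(b[, 4] - b[, 2], g)
    u <- sx / strides[l] + 0.5                      # 1-based feature coords
    v <- sy / strides[l] + 0.5
    nl <- length(rows)
    # full grid: for each box, roi_size x roi_size points (y-major)
    U <- u[, rep(seq_len(roi_size), each = roi_size), drop = FALSE]
    V <- v[, rep(seq_len(roi_size), times = roi_size), drop = FALSE]
    U <- pmin(pmax(U, 1), Wf); V <- pmin(pmax(V, 1), Hf)
    u0 <- pmin(floor(U), Wf - 1); v0 <- pmin(floor(V), Hf - 1)
    du <- U - u0; dv <- V - v0
    # flatten point dimension: nl * roi_size^2 points
    flat <- function(M) as.vector(t(M))
    i00 <- (flat(u0) - 1) * Hf + flat(v0)
    i01 <- (flat(u0 + 1) - 1) * Hf + flat(v0)
    i10 <- (flat(u0) - 1) * Hf + flat(v0 + 1)
    i11 <- (flat(u0 + 1) - 1) * Hf + flat(v0 + 1)
    wdu <- flat(du); wdv <- flat(dv)
    val <- Pm[i00, , drop = FALSE] * ((1 - wdu) * (1 - wdv)) +
      Pm[i01, , drop = FALSE] * (wdu * (1 - wdv)) +
      Pm[i10, , drop = FALSE] * ((1 - wdu) * wdv) +
      Pm[i11, , drop = FALSE] * (wdu * wdv)
    # val: (nl * roi_size^2) x fpn_dim, point-major per box
    for (k in seq_len(nl)) {
      block <- val[((k - 1) * roi_size^2 + 1):(k * roi_size^2), , drop = FALSE]
      out[rows[k], ] <- as.vector(block)
    }
  }
  if (normalize) {
    nrm <- sqrt(rowSums(out^2))
    out <- out / pmax(nrm, 1e-8)
  }
  out
}

# Per-channel spatial standardization of flattened RoI features (layout:
# channel-major blocks of roi_size^2 positions). Removes each channel's
# per-RoI mean and scale, leaving only the spatial pattern: box regression
# trained on these features is invariant to the class's colour signature and
# so transfers from base to novel appearances.
spatial_standardize_roi <- function(X, n_pos, n_ch) {
  for (ch in seq_len(n_ch)) {
    idx <- ((ch - 1) * n_pos + 1):(ch * n_pos)
    block <- X[, idx, drop = FALSE]
    m <- rowMeans(block)
    s <- sqrt(pmax(rowMeans(block^2) - m^2, 0))
    X[, idx] <- (block - m) / (s + 1e-6)
  }
  X / pmax(sqrt(rowSums(X^2)), 1e-8)
}

# Same for 3x3-neighbourhood cell features (layout: offset-major blocks of
# n_ch channels): channel ch occupies columns ch, ch + n_ch, ..., ch + 8*n_ch.
spatial_standardize_cells <- function(X, n_ch) {
  for (ch in seq_len(n_ch)) {
    idx <- seq(ch, by = n_ch, length.out = ncol(X) %/% n_ch)
    block <- X[, idx, drop = FALSE]
    m <- rowMeans(block)
    s <- sqrt(pmax(rowMeans(block^2) - m^2, 0))
    X[, idx] <- (block - m) / (s + 1e-6)
  }
  X / pmax(sqrt(rowSums(X^2)), 1e-8)
}
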