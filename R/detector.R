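# Cascade detector: region proposals on the fused pyramid, three cascaded
# heads at increasing IoU thresholds with OHEM sampling, weighted total
# loss. Desk-scale training updates the linear parts (RPN objectness scorer
# and the heads' classifiers/regressors) analytically over the
# backbone/ASPP/FPN features, which act as a fixed multi-scale feature
# extractor.

#' Assemble the improved cascade detector
#'
#' Wires the four components together: the parallel-resolution backbone
#' with attention, one sawtooth atrous-pyramid module per branch, the
#' feature-pyramid fusion, and three cascaded detection heads with an
#' online hard-example-mining ROI sampler. Component contracts are checked
#' at build time (channel widths must chain, one pyramid module per
#' branch).
#'
#' @param backbone a [build_improved_backbone()] module.
#' @param aspp list of 4 [build_sawtooth_aspp()] modules, one per branch.
#' @param fpn a [build_fpn()] module.
#' @param cascade a [cascade_config()].
#' @param n_classes number of foreground classes (2: psyllid, fruit fly).
#' @param anchor_base anchor edge length on the finest level in pixels;
#'   doubles per level. Small targets need a small base (default 8 px).
#' @param use_ohem apply hard-example mining when sampling training ROIs;
#'   when `FALSE`, ROIs are sampled uniformly at random instead.
#' @param seed optional RNG seed for head initialisation.
#' @return A list of type `"detector"`.
#' @export
assemble_detector <- function(backbone, aspp, fpn, cascade = cascade_config(),
                              n_classes = 2L, anchor_base = 8L,
                              use_ohem = TRUE, seed = NULL) {
  stopifnot(identical(backbone$type, "backbone"), identical(fpn$type, "fpn"),
            inherits(cascade, "cascade_config"))
  if (length(aspp) != 4L)
    stopf("need one atrous-pyramid module per backbone branch (4), got %d",
          length(aspp))
  widths <- backbone$config$widths
  for (i in 1:4) {
    stopifnot(identical(aspp[[i]]$type, "aspp"))
    if (aspp[[i]]$in_channels != widths[[i]])
      stopf("aspp branch %d expects %d channels but the backbone emits %d",
            i, aspp[[i]]$in_channels, widths[[i]])
    if (fpn$in_channels[[i]] != aspp[[i]]$out_channels)
      stopf("fpn branch %d expects %d channels but aspp emits %d",
            i, fpn$in_channels[[i]], aspp[[i]]$out_channels)
  }
  cf <- fpn$out_channels
  with_seed_or_current(seed, {
    heads <- lapply(seq_len(cascade$n_stages), function(t) list(
      w_cls = matrix(rnorm((n_classes + 1L) * (cf + 1L), sd = 0.01),
                     n_classes + 1L, cf + 1L),
      w_reg = matrix(rnorm(4L * (cf + 1L), sd = 0.01), 4L, cf + 1L)))
    list(type = "detector", backbone = backbone, aspp = aspp, fpn = fpn,
         cascade = cascade, n_classes = as.integer(n_classes),
         anchor_base = anchor_base, use_ohem = isTRUE(use_ohem),
         strides = c(4L, 8L, 16L, 32L),
         rpn_w = rnorm(cf + 1L, sd = 0.01),
         heads = heads)
  })
}

#' Convenience constructor for the test-scale detector
#'
#' Builds a complete detector from the tiny backbone profile; all weights
#' are initialised from `seed`.
#'
#' @param seed RNG seed.
#' @param fpn_channels fused-pyramid channel width.
#' @param use_ohem see [assemble_detector()].
#' @return A detector.
#' @export
build_tiny_detector <- function(seed = 1L, fpn_channels = 16L, use_ohem = TRUE) {
  with_seed_or_current(seed, {
    cfg <- backbone_config(tiny = TRUE)
    backbone <- build_improved_backbone(cfg)
    aspp <- lapply(cfg$widths, function(wi)
      build_sawtooth_aspp(wi, out_channels = fpn_channels))
    fpn <- build_fpn(rep(fpn_channels, 4L), out_channels = fpn_channels)
    assemble_detector(backbone, aspp, fpn, use_ohem = use_ohem)
  })
}

#' Multi-scale features for one image
#'
#' Runs backbone, per-branch atrous pyramid and feature-pyramid fusion.
#'
#' @param detector a detector.
#' @param image pixel array `[H, W, 3]`, dimensions divisible by 32.
#' @return List of 4 feature tensors (finest first).
#' @export
detector_features <- function(detector, image) {
  branches <- backbone_forward(detector$backbone, image)
  processed <- lapply(1:4, function(i) aspp_apply(detector$aspp[[i]], branches[[i]]))
  fpn_apply(detector$fpn, processed)
}

# anchors for one pyramid level: one square anchor per cell, centred
level_anchors <- function(h_cells, w_cells, stride, size) {
  ij <- expand.grid(i = seq_len(h_cells), j = seq_len(w_cells))
  cx <- (ij$j - 0.5) * stride
  cy <- (ij$i - 0.5) * stride
  data.frame(x0 = cx - size / 2, y0 = cy - size / 2,
             x1 = cx + size / 2, y1 = cy + size / 2,
             level = NA_integer_, i = ij$i, j = ij$j)
}

detector_anchors <- function(detector, feats) {
  out <- lapply(1:4, function(l) {
    a <- level_anchors(dim(feats[[l]])[[2]], dim(feats[[l]])[[3]],
                       detector$strides[[l]],
                       detector$anchor_base * 2L^(l - 1L))
    a$level <- l
    a
  })
  do.call(rbind, out)
}

# feature matrix [Cf+1, n] (bias row of ones appended) for all cells of a level
level_feature_matrix <- function(feat) {
  cf <- dim(feat)[[1]]
  rbind(matrix(feat, cf, dim(feat)[[2]] * dim(feat)[[3]]), 1)
}

rpn_scores <- function(detector, feats, anchors) {
  scores <- numeric(nrow(anchors))
  for (l in 1:4) {
    sel <- anchors$level == l
    if (!any(sel)) next
    fm <- level_feature_matrix(feats[[l]])
    # column index of cell (i, j) in the [C, H, W] flattening is i + (j-1) H
    idx <- anchors$i[sel] + (anchors$j[sel] - 1L) * dim(feats[[l]])[[2]]
    scores[sel] <- nn_sigmoid(as.numeric(detector$rpn_w %*% fm[, idx, drop = FALSE]))
  }
  scores
}

# average-pooled ROI feature from the pyramid level matched to the box size
roi_pool <- function(detector, feats, b) {
  size <- max(b[[3]] - b[[1]], b[[4]] - b[[2]])
  l <- min(max(1L, as.integer(round(log2(max(size, 1) / detector$anchor_base))) + 1L), 4L)
  s <- detector$strides[[l]]
  f <- feats[[l]]
  i0 <- max(1L, floor(b[[2]] / s) + 1L); i1 <- min(dim(f)[[2]], ceiling(b[[4]] / s))
  j0 <- max(1L, floor(b[[1]] / s) + 1L); j1 <- min(dim(f)[[3]], ceiling(b[[3]] / s))
  if (i1 < i0) { i0 <- min(i0, dim(f)[[2]]); i1 <- i0 }
  if (j1 < j0) { j0 <- min(j0, dim(f)[[3]]); j1 <- j0 }
  sub <- f[, i0:i1, j0:j1, drop = FALSE]
  c(apply(sub, 1, mean), 1)
}

roi_feature_matrix <- function(detector, feats, boxes) {
  vapply(seq_len(nrow(boxes)), function(r)
    roi_pool(detector, feats, as.numeric(boxes[r, c("x0", "y0", "x1", "y1")])),
    numeric(detector$fpn$out_channels + 1L))
}

encode_deltas <- function(roi, gt) {
  rw <- roi[, 3] - roi[, 1]; rh <- roi[, 4] - roi[, 2]
  gw <- gt[, 3] - gt[, 1]; gh <- gt[, 4] - gt[, 2]
  cbind((gt[, 1] + gt[, 3] - roi[, 1] - roi[, 3]) / (2 * rw),
        (gt[, 2] + gt[, 4] - roi[, 2] - roi[, 4]) / (2 * rh),
        log(gw / rw), log(gh / rh))
}

decode_deltas <- function(roi, d, width, height) {
  rw <- roi[, 3] - roi[, 1]; rh <- roi[, 4] - roi[, 2]
  cx <- (roi[, 1] + roi[, 3]) / 2 + d[, 1] * rw
  cy <- (roi[, 2] + roi[, 4]) / 2 + d[, 2] * rh
  w <- rw * exp(pmin(d[, 3], 4)); h <- rh * exp(pmin(d[, 4], 4))
  out <- cbind(x0 = cx - w / 2, y0 = cy - h / 2, x1 = cx + w / 2, y1 = cy + h / 2)
  out[, 1] <- pmin(pmax(out[, 1], 0), width - 1)
  out[, 2] <- pmin(pmax(out[, 2], 0), height - 1)
  out[, 3] <- pmin(pmax(out[, 3], out[, 1] + 1), width)
  out[, 4] <- pmin(pmax(out[, 4], out[, 2] + 1), height)
  out
}

# max-IoU label assignment at one cascade stage's threshold
assign_rois <- function(boxes, gt, iou_thr) {
  n <- nrow(boxes)
  label <- rep(0L, n)           # 0 = background, else class_id + 1
  target <- matrix(0, n, 4L)
  if (nrow(gt) > 0L) {
    for (r in seq_len(n)) {
      ious <- box_iou_many(as.numeric(boxes[r, 1:4]), ann_boxes(gt))
      best <- which.max(ious)
      if (ious[[best]] >= iou_thr) {
        label[[r]] <- gt$class_id[[best]] + 1L
        target[r, ] <- encode_deltas(matrix(as.numeric(boxes[r, 1:4]), 1),
                                     matrix(as.numeric(ann_box(gt, best)), 1))
      }
    }
  }
  list(label = label, target = target)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

smooth_l1 <- function(e) ifelse(abs(e) < 1, 0.5 * e^2, abs(e) - 0.5)
smooth_l1_grad <- function(e) ifelse(abs(e) < 1, e, sign(e))

# per-stage forward, per-ROI losses, OHEM selection and analytic gradients
stage_pass <- function(head, fm, labels, targets, n_classes,
                       use_ohem, n_pos = 64L, n_neg = 192L) {
  n <- ncol(fm)
  logits <- head$w_cls %*% fm                       # [K+1, n]
  p <- softmax_cols(logits)
  y <- labels + 1L                                  # row index (1 = background)
  ce <- -log(pmax(p[cbind(y, seq_len(n))], 1e-12))
  reg <- head$w_reg %*% fm                          # [4, n]
  err <- t(reg) - targets
  reg_loss <- rowSums(smooth_l1(err))
  roi_loss <- ce + ifelse(labels > 0L, reg_loss, 0)

  batch <- roi_batch(roi_loss, labels > 0L)
  sel <- if (use_ohem) {
    ohem_sample(batch, n_pos, n_neg)
  } else {
    cap <- min(n, n_pos + n_neg)
    sample(batch$index, cap)
  }
  ns <- length(sel)
  loss <- mean(roi_loss[sel])

  dlogits <- matrix(0, nrow(p), n)
  dlogits[, sel] <- p[, sel, drop = FALSE]
  dlogits[cbind(y[sel], sel)] <- dlogits[cbind(y[sel], sel)] - 1
  dlogits <- dlogits / ns
  g_cls <- dlogits %*% t(fm)

  derr <- matrix(0, n, 4L)
  pos_sel <- sel[labels[sel] > 0L]
  if (length(pos_sel))
    derr[pos_sel, ] <- smooth_l1_grad(err[pos_sel, , drop = FALSE]) / ns
  g_reg <- t(derr) %*% t(fm)

  list(loss = loss, selected = sel, p = p, reg = reg,
       g_cls = g_cls, g_reg = g_reg)
}

#' Smoke-train a detector on fixture scenes
#'
#' Runs the cascade training loop at desk scale: per iteration one image's
#' cached pyramid features are used to (1) update the RPN objectness scorer
#' on sampled anchors, (2) run the three cascade stages on RPN proposals
#' plus the ground-truth boxes, selecting ROIs with the hard-example-mining
#' sampler, computing each stage's classification + box-regression loss at
#' its IoU threshold, and applying gradient steps to the head parameters.
#' The recorded total loss is the 1 : 0.5 : 0.25 weighted stage sum.
#'
#' @param detector a detector.
#' @param dataset a [detection_dataset()] whose records carry in-memory
#'   images (e.g. from [generate_scene()]), dimensions divisible by 32.
#' @param iterations gradient iterations (images are cycled).
#' @param lr learning rate for the head/RPN updates.
#' @param top_n proposals kept per image.
#' @param seed RNG seed for sampling.
#' @return A list with `detector` (updated parameters) and `history`, a
#'   data frame of per-iteration stage losses and weighted totals.
#' @export
train_smoke <- function(detector, dataset, iterations = 200L, lr = 0.5,
                        top_n = 64L, seed = 1L) {
  stopifnot(identical(detector$type, "detector"))
  recs <- dataset$records
  if (!length(recs)) stopf("training dataset is empty")
  feats_cache <- lapply(recs, function(r) {
    if (is.null(r$image)) stopf("record %d has no in-memory image", r$id)
    detector_features(detector, r$image)
  })
  anchors_cache <- lapply(feats_cache, function(f) detector_anchors(detector, f))
  n_cls <- detector$n_classes
  cfg <- detector$cascade
  history <- data.frame(iteration = seq_len(iterations), rpn_loss = NA_real_,
                        stage1 = NA_real_, stage2 = NA_real_,
                        stage3 = NA_real_, total = NA_real_)

  with_seed_or_current(seed, {
    for (it in seq_len(iterations)) {
      k <- (it - 1L) %% length(recs) + 1L
      rec <- recs[[k]]
      feats <- feats_cache[[k]]
      anchors <- anchors_cache[[k]]
      gt <- rec$annotations

      # --- RPN objectness update on a sampled anchor set
      scores <- rpn_scores(detector, feats, anchors)
      amax <- vapply(seq_len(nrow(anchors)), function(r) {
        if (nrow(gt) == 0L) return(0)
        max(box_iou_many(as.numeric(anchors[r, 1:4]), ann_boxes(gt)))
      }, numeric(1))
      pos_idx <- which(amax >= 0.5)
      neg_idx <- which(amax < 0.3)
      if (length(neg_idx) > 32L) neg_idx <- sample(neg_idx, 32L)
      idx <- c(pos_idx, neg_idx)
      ylab <- c(rep(1, length(pos_idx)), rep(0, length(neg_idx)))
      if (length(idx)) {
        fm_all <- lapply(1:4, function(l) level_feature_matrix(feats[[l]]))
        fvec <- vapply(idx, function(r) {
          l <- anchors$level[[r]]
          fm_all[[l]][, anchors$i[[r]] + (anchors$j[[r]] - 1L) *
                        dim(feats[[l]])[[2]]]
        }, numeric(detector$fpn$out_channels + 1L))
        s <- nn_sigmoid(as.numeric(detector$rpn_w %*% fvec))
        rpn_loss <- -mean(ylab * log(pmax(s, 1e-12)) +
                          (1 - ylab) * log(pmax(1 - s, 1e-12)))
        detector$rpn_w <- detector$rpn_w -
          lr * as.numeric(fvec %*% (s - ylab)) / length(idx)
      } else rpn_loss <- 0

      # --- proposals: top-scoring anchors plus ground truth
      keep <- order(-scores)[seq_len(min(top_n, length(scores)))]
      boxes <- as.matrix(anchors[keep, 1:4])
      boxes[, 1] <- pmax(boxes[, 1], 0); boxes[, 2] <- pmax(boxes[, 2], 0)
      boxes[, 3] <- pmin(boxes[, 3], rec$width)
      boxes[, 4] <- pmin(boxes[, 4], rec$height)
      if (nrow(gt) > 0L) boxes <- rbind(boxes, ann_boxes(gt))
      colnames(boxes) <- c("x0", "y0", "x1", "y1")

      stage_losses <- numeric(cfg$n_stages)
      for (t in seq_len(cfg$n_stages)) {
        fm <- roi_feature_matrix(detector, feats, as.data.frame(boxes))
        asg <- assign_rois(boxes, gt, cfg$iou_thresholds[[t]])
        sp <- stage_pass(detector$heads[[t]], fm, asg$label, asg$target,
                         n_cls, detector$use_ohem)
        stage_losses[[t]] <- sp$loss
        detector$heads[[t]]$w_cls <- detector$heads[[t]]$w_cls -
          lr * cfg$loss_weights[[t]] * sp$g_cls
        detector$heads[[t]]$w_reg <- detector$heads[[t]]$w_reg -
          lr * cfg$loss_weights[[t]] * sp$g_reg
        boxes <- decode_deltas(boxes, t(sp$reg), rec$width, rec$height)
        colnames(boxes) <- c("x0", "y0", "x1", "y1")
      }
      history$rpn_loss[[it]] <- rpn_loss
      history$stage1[[it]] <- stage_losses[[1]]
      history$stage2[[it]] <- stage_losses[[2]]
      history$stage3[[it]] <- stage_losses[[3]]
      history$total[[it]] <- cascade_total_loss(stage_losses, cfg$loss_weights)
    }
  })
  list(detector = detector, history = history)
}

#' Run inference on one image
#'
#' Region proposals from the RPN objectness scores are refined through the
#' three cascade stages; the final stage's class posteriors score each box.
#' Per-class greedy non-maximum suppression removes duplicates.
#'
#' @param detector a detector.
#' @param image pixel array `[H, W, 3]`, dimensions divisible by 32.
#' @param score_threshold minimum class score to report.
#' @param nms_iou IoU above which a lower-scored overlapping box is
#'   suppressed.
#' @param top_n proposals examined.
#' @return A data frame with columns `x0, y0, x1, y1, class_id, score`
#'   (possibly empty); boxes lie within image bounds.
#' @export
detect <- function(detector, image, score_threshold = 0.5, nms_iou = 0.5,
                   top_n = 64L) {
  stopifnot(identical(detector$type, "detector"))
  h <- dim(image)[[1]]; w <- dim(image)[[2]]
  feats <- detector_features(detector, image)
  anchors <- detector_anchors(detector, feats)
  scores <- rpn_scores(detector, feats, anchors)
  keep <- order(-scores)[seq_len(min(top_n, length(scores)))]
  boxes <- as.matrix(anchors[keep, 1:4])
  boxes[, 1] <- pmax(boxes[, 1], 0); boxes[, 2] <- pmax(boxes[, 2], 0)
  boxes[, 3] <- pmin(boxes[, 3], w); boxes[, 4] <- pmin(boxes[, 4], h)
  colnames(boxes) <- c("x0", "y0", "x1", "y1")
  p <- NULL
  for (t in seq_len(detector$cascade$n_stages)) {
    fm <- roi_feature_matrix(detector, feats, as.data.frame(boxes))
    p <- softmax_cols(detector$heads[[t]]$w_cls %*% fm)
    reg <- detector$heads[[t]]$w_reg %*% fm
    boxes <- decode_deltas(boxes, t(reg), w, h)
    colnames(boxes) <- c("x0", "y0", "x1", "y1")
  }
  cls <- apply(p[-1L, , drop = FALSE], 2, which.max) - 1L  # drop background row
  score <- p[cbind(cls + 2L, seq_len(ncol(p)))]
  out <- data.frame(boxes, class_id = as.integer(cls), score = score)
  out <- out[out$score >= score_threshold, , drop = FALSE]
  nms_filter(out, nms_iou)
}

# greedy per-class non-maximum suppression
nms_filter <- function(dets, iou_thr) {
  if (nrow(dets) == 0L) { rownames(dets) <- NULL; return(dets) }
  keep <- logical(nrow(dets))
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    idx <- idx[order(-dets$score[idx])]
    while (length(idx)) {
      top <- idx[[1]]
      keep[[top]] <- TRUE
      idx <- idx[-1]
      if (length(idx)) {
        ious <- box_iou_many(as.numeric(dets[top, c("x0", "y0", "x1", "y1")]),
                             as.matrix(dets[idx, c("x0", "y0", "x1", "y1")]))
        idx <- idx[ious < iou_thr]
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
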