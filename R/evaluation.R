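#' Match detections to ground truth for one class
#'
#' Greedy matching in descending score order (ties broken by stable input
#' order): a detection is a true positive iff its best-IoU unmatched ground
#' truth reaches `iou_threshold`; each ground truth can be matched at most
#' once, so duplicate detections of the same target are false positives.
#'
#' @param dets data frame of detections with box columns and `score`.
#' @param gts matrix or data frame of ground-truth boxes (may be empty).
#' @param iou_threshold matching threshold (default 0.5).
#' @return `dets` with a logical `tp` column, rows re-ordered by descending
#'   score.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  if (is.data.frame(gts)) gts <- ann_boxes(gts)
  if (is.null(dim(gts))) gts <- matrix(gts, ncol = 4L)
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  rownames(dets) <- NULL
  matched <- logical(nrow(gts))
  tp <- logical(nrow(dets))
  for (r in seq_len(nrow(dets))) {
    if (nrow(gts) == 0L) break
    ious <- box_iou_many(as.numeric(dets[r, c("x0", "y0", "x1", "y1")]), gts)
    ious[matched] <- -1
    best <- which.max(ious)
    if (length(best) && ious[[best]] >= iou_threshold) {
      tp[[r]] <- TRUE
      matched[[best]] <- TRUE
    }
  }
  dets$tp <- tp
  dets
}

#' Precision-recall curve from ranked detections
#'
#' @param tp logical true-positive labels in descending-score order.
#' @param n_gt total ground-truth count for the class.
#' @return A list of class `pr_curve` with cumulative `precision` and
#'   `recall` at each rank and the ground-truth count.
#' @export
pr_curve <- function(tp, n_gt) {
  tp_cum <- cumsum(as.numeric(tp))
  fp_cum <- cumsum(as.numeric(!tp))
  structure(list(
    precision = if (length(tp)) tp_cum / (tp_cum + fp_cum) else numeric(),
    recall = if (n_gt > 0 && length(tp)) tp_cum / n_gt else
      rep(0, length(tp)),
    n_gt = n_gt), class = "pr_curve")
}

#' Average precision by precision-envelope integration
#'
#' Computes the area under the precision-recall curve over recall in
#' `[0, 1]` using all-point (continuous) interpolation: precision is first
#' replaced by its running maximum from the right (the envelope), then
#' integrated across the recall increments. A class with zero ground truths
#' has undefined AP; `NA` is returned with attribute `undefined = TRUE`
#' and a warning — never a silent 0.
#'
#' @param curve a [pr_curve()].
#' @return AP in `[0, 1]`, or flagged `NA` when undefined.
#' @export
average_precision <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  if (curve$n_gt == 0) {
    warnf("AP is undefined for a class with zero ground truths")
    return(structure(NA_real_, undefined = TRUE))
  }
  if (length(curve$precision) == 0L) return(0)
  env <- rev(cummax(rev(curve$precision)))
  r <- c(0, curve$recall)
  sum(diff(r) * env)
}

#' Mean average precision
#'
#' Arithmetic mean of the per-class APs; order-invariant. Undefined (`NA`)
#' APs must be removed by the caller — see [evaluate()], which excludes
#' zero-ground-truth classes with a warning.
#'
#' @param per_class_ap numeric vector of per-class APs (fractions or
#'   percentages; the mean is on the same scale).
#' @return The mean.
#' @examples
#' mean_average_precision(c(88.78, 91.64))  # 90.21
#' @export
mean_average_precision <- function(per_class_ap) {
  if (length(per_class_ap) == 0L || all(is.na(per_class_ap)))
    stopf("mean average precision needs at least one class with a defined AP")
  if (any(is.na(per_class_ap)))
    stopf("undefined APs must be excluded before averaging")
  mean(per_class_ap)
}

#' Evaluate detections against a dataset
#'
#' Builds one globally score-ranked precision-recall curve per class from
#' per-image greedy matching, integrates each to AP, and averages defined
#' APs to mAP. Classes with no ground truths are excluded from the mean
#' with a warning rather than counted as zero.
#'
#' @param dataset a [detection_dataset()] providing ground truth.
#' @param detections data frame with `image_id`, `class_id`, box columns
#'   and `score`.
#' @param iou_threshold matching IoU threshold.
#' @return A list of class `eval_summary` with `per_class_ap` (named by
#'   category), `map` and `curves`.
#' @export
evaluate <- function(dataset, detections, iou_threshold = 0.5) {
  validate_dataset(dataset)
  class_ids <- as.integer(names(dataset$categories))
  unknown <- setdiff(unique(detections$class_id), class_ids)
  if (length(unknown))
    stopf("detections use unknown category id %d", unknown[[1]])

  per_class_ap <- setNames(rep(NA_real_, length(class_ids)),
                           dataset$categories[as.character(class_ids)])
  curves <- list()
  for (ci in seq_along(class_ids)) {
    cl <- class_ids[[ci]]
    tp_all <- logical(); score_all <- numeric()
    n_gt <- 0L
    for (rec in dataset$records) {
      gt <- rec$annotations[rec$annotations$class_id == cl, , drop = FALSE]
      n_gt <- n_gt + nrow(gt)
      d <- detections[detections$image_id == rec$id &
                      detections$class_id == cl, , drop = FALSE]
      if (nrow(d) == 0L) next
      m <- match_detections(d, gt, iou_threshold)
      tp_all <- c(tp_all, m$tp)
      score_all <- c(score_all, m$score)
    }
    ord <- order(-score_all)
    curve <- pr_curve(tp_all[ord], n_gt)
    curves[[names(per_class_ap)[[ci]]]] <- curve
    if (n_gt > 0L) per_class_ap[[ci]] <- average_precision(curve)
  }
  defined <- !is.na(per_class_ap)
  if (!all(defined))
    warnf("class(es) without ground truth excluded from the mean: %s",
          paste(names(per_class_ap)[!defined], collapse = ", "))
  structure(list(per_class_ap = per_class_ap,
                 map = mean_average_precision(per_class_ap[defined]),
                 curves = curves), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("<eval_summary>\n")
  for (nm in names(x$per_class_ap))
    cat(sprintf("  AP[%s] = %s\n", nm,
                ifelse(is.na(x$per_class_ap[[nm]]), "undefined",
                       sprintf("%.4f", x$per_class_ap[[nm]]))))
  cat(sprintf("  mAP = %.4f\n", x$map))
  invisible(x)
}
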