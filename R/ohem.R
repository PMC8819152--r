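#' ROI batches for hard-example mining
#'
#' @param loss non-negative finite per-ROI loss values.
#' @param positive logical vector: `TRUE` for positive (foreground) ROIs.
#' @param index optional stable integer ids; defaults to position.
#' @return A data frame with columns `loss`, `positive`, `index`.
#' @export
roi_batch <- function(loss, positive, index = seq_along(loss)) {
  if (any(!is.finite(loss))) stopf("ROI losses must be finite")
  if (length(positive) != length(loss) || length(index) != length(loss))
    stopf("loss, positive and index must have equal length")
  if (anyDuplicated(index)) stopf("ROI indices must be unique")
  data.frame(loss = as.numeric(loss), positive = as.logical(positive),
             index = as.integer(index))
}

#' Online hard-example mining sampler
#'
#' Replaces random ROI sampling with loss-ranked selection: within each
#' polarity the ROIs are sorted by loss in descending order and the prefix
#' is taken — the top `n_pos` positives and the top `n_neg` negatives (64
#' and 192 by default, per stage). When fewer candidates exist than a cap,
#' all of that polarity are selected. Ties are broken by stable index
#' order.
#'
#' @param batch a [roi_batch()] (or data frame with `loss`, `positive` and
#'   optionally `index` columns).
#' @param n_pos,n_neg selection caps for positive and negative ROIs.
#' @return Integer vector of selected `index` values, positives first, each
#'   polarity in descending-loss order.
#' @export
ohem_sample <- function(batch, n_pos = 64L, n_neg = 192L) {
  if (is.null(batch$index)) batch$index <- seq_len(nrow(batch))
  batch <- roi_batch(batch$loss, batch$positive, batch$index)
  pick <- function(sub, cap) {
    if (nrow(sub) == 0L || cap == 0L) return(integer())
    ord <- order(-sub$loss, sub$index)
    sub$index[ord[seq_len(min(cap, nrow(sub)))]]
  }
  c(pick(batch[batch$positive, , drop = FALSE], n_pos),
    pick(batch[!batch$positive, , drop = FALSE], n_neg))
}

#' Cascade stage configuration
#'
#' Three detection heads refine proposals sequentially; stage `t` is
#' trained at an increasing IoU threshold and receives stage `t - 1`'s
#' regressed boxes. Stage losses combine with weights 1 : 0.5 : 0.25.
#'
#' @param n_stages number of cascaded heads (3).
#' @param loss_weights positive per-stage loss weights.
#' @param iou_thresholds strictly increasing per-stage foreground IoU
#'   thresholds in (0, 1); the canonical cascade settings are 0.5, 0.6,
#'   0.7.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(n_stages = 3L, loss_weights = c(1, 0.5, 0.25),
                           iou_thresholds = c(0.5, 0.6, 0.7)) {
  if (length(loss_weights) != n_stages || length(iou_thresholds) != n_stages)
    stopf("need one loss weight and one IoU threshold per stage")
  if (any(loss_weights <= 0)) stopf("stage loss weights must be positive")
  if (any(diff(iou_thresholds) <= 0) || any(iou_thresholds <= 0) ||
      any(iou_thresholds >= 1))
    stopf("stage IoU thresholds must be strictly increasing in (0, 1)")
  structure(list(n_stages = as.integer(n_stages), loss_weights = loss_weights,
                 iou_thresholds = iou_thresholds), class = "cascade_config")
}

#' Weighted cascade total loss
#'
#' Combines the per-stage detection losses into the scalar optimised during
#' training, `sum(w[t] * L[t])` with default weights `(1, 0.5, 0.25)` for
#' stages 1-3.
#'
#' @param stage_losses numeric vector of non-negative per-stage losses.
#' @param weights per-stage weights, same length.
#' @return The weighted sum.
#' @examples
#' cascade_total_loss(c(1, 1, 1))  # 1.75
#' @export
cascade_total_loss <- function(stage_losses, weights = c(1, 0.5, 0.25)) {
  if (length(stage_losses) != length(weights))
    stopf("need one weight per stage loss")
  if (any(!is.finite(stage_losses)) || any(stage_losses < 0))
    stopf("stage losses must be finite and non-negative")
  sum(weights * stage_losses)
}
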