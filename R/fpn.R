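#' Feature pyramid fusion module
#'
#' Fuses the four multi-resolution branch outputs top-down: each branch is
#' first projected to a common channel width with a 1x1 lateral convolution;
#' starting from the coarsest level, each level is upsampled 2x (nearest
#' neighbour) and added elementwise to the next finer lateral; a 3x3 output
#' convolution smooths each fused level. All convolutions are bias-free, so
#' zero inputs map to zero outputs. The module emits four levels aligned to
#' the input resolutions.
#'
#' @param in_channels integer vector of the four branch channel counts,
#'   finest first.
#' @param out_channels uniform output channel count.
#' @return A module list of type `"fpn"`; apply with [fpn_apply()].
#' @export
build_fpn <- function(in_channels, out_channels = 32L) {
  if (length(in_channels) != 4L)
    stopf("feature pyramid fusion expects exactly 4 input branches, got %d",
          length(in_channels))
  list(type = "fpn", in_channels = in_channels, out_channels = out_channels,
       laterals = lapply(in_channels, function(ci)
         conv_module(out_channels, ci, 1L, bias = FALSE)),
       outputs = lapply(seq_len(4L), function(i)
         conv_module(out_channels, out_channels, 3L, bias = FALSE)))
}

#' @rdname build_fpn
#' @param module a module built by [build_fpn()].
#' @param branches list of 4 feature tensors, finest first, each level half
#'   the resolution of the previous.
#' @return A list of 4 tensors with `out_channels` channels at the input
#'   resolutions.
#' @export
fpn_apply <- function(module, branches) {
  stopifnot(identical(module$type, "fpn"))
  if (length(branches) != 4L)
    stopf("feature pyramid fusion expects 4 branches, got %d", length(branches))
  lat <- lapply(seq_len(4L), function(i)
    conv_forward(module$laterals[[i]], branches[[i]]))
  fused <- vector("list", 4L)
  fused[[4L]] <- lat[[4L]]
  for (i in 3L:1L)
    fused[[i]] <- lat[[i]] + nn_upsample(fused[[i + 1L]], 2L)
  lapply(seq_len(4L), function(i)
    conv_forward(module$outputs[[i]], fused[[i]]))
}
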