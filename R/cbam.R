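#' Channel + spatial attention block
#'
#' A lightweight convolutional attention block that sequentially applies
#' channel attention (shared two-layer MLP over global average- and
#' max-pooled channel descriptors, sigmoid-gated) and spatial attention
#' (7x7 convolution over channel-wise mean and max maps, sigmoid-gated).
#' Both gate maps lie strictly in (0, 1); the block output is the input
#' rescaled by the two gates, so it preserves tensor shape and maps a zero
#' tensor to zero.
#'
#' @param channels number of input channels; must be divisible by
#'   `reduction`.
#' @param reduction channel-MLP bottleneck ratio (default 16, the original
#'   attention-module setting).
#' @param spatial_kernel odd spatial-attention kernel size (default 7).
#' @return A module list of type `"cbam"`; apply with [cbam_apply()].
#' @export
build_cbam <- function(channels, reduction = 16L, spatial_kernel = 7L) {
  if (channels %% reduction != 0L)
    stopf("channels (%d) must be divisible by the reduction ratio (%d)",
          channels, reduction)
  if (spatial_kernel %% 2L != 1L) stopf("spatial_kernel must be odd")
  hidden <- channels %/% reduction
  list(type = "cbam", channels = channels, reduction = reduction,
       w1 = matrix(rnorm(hidden * channels, sd = sqrt(2 / channels)),
                   hidden, channels),
       b1 = numeric(hidden),
       w2 = matrix(rnorm(channels * hidden, sd = sqrt(2 / hidden)),
                   channels, hidden),
       b2 = numeric(channels),
       spatial = conv_module(1L, 2L, spatial_kernel, gain = 1))
}

#' @rdname build_cbam
#' @param block a module built by [build_cbam()].
#' @param x feature tensor `[C, H, W]` with `C == channels`.
#' @param return_gates also return the channel and spatial gate values.
#' @return The gated tensor, or (with `return_gates`) a list with `out`,
#'   `channel_gate` (length `C`) and `spatial_gate` (`[H, W]`).
#' @export
cbam_apply <- function(block, x, return_gates = FALSE) {
  stopifnot(identical(block$type, "cbam"), dim(x)[[1]] == block$channels)
  mlp <- function(v) block$w2 %*% pmax(block$w1 %*% v + block$b1, 0) + block$b2
  cg <- nn_sigmoid(as.numeric(mlp(nn_global_avg(x)) + mlp(nn_global_max(x))))
  x1 <- x * cg  # [C,H,W] recycles over the channel (first) dimension
  sp_in <- array(0, c(2L, dim(x)[[2]], dim(x)[[3]]))
  sp_in[1L, , ] <- apply(x1, c(2, 3), mean)
  sp_in[2L, , ] <- apply(x1, c(2, 3), max)
  sg <- nn_sigmoid(conv_forward(block$spatial, sp_in)[1L, , ])
  out <- x1 * rep(as.numeric(sg), each = dim(x)[[1]])
  if (return_gates) list(out = out, channel_gate = cg, spatial_gate = sg)
  else out
}
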