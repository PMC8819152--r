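#' Sawtooth dilation-rate validation
#'
#' Atrous pyramid rates chosen for small targets follow a "sawtooth"
#' (zigzag) pattern such as (1, 2, 5): rates are strictly increasing and no
#' consecutive pair shares a common divisor greater than 1. This keeps the
#' stacked dilated kernels' effective receptive field free of the gridding
#' artifact, where uniform large rates sample the input on a sparse lattice
#' and skip the few pixels a tiny insect occupies.
#'
#' @param rates integer vector of dilation rates.
#' @return `TRUE` invisibly; errors describe the violated rule.
#' @export
validate_sawtooth_rates <- function(rates) {
  if (length(rates) < 1L || any(rates < 1L) || any(rates != trunc(rates)))
    stopf("dilation rates must be integers >= 1")
  if (length(rates) > 1L) {
    if (any(diff(rates) <= 0)) stopf("dilation rates must be strictly increasing")
    for (i in seq_len(length(rates) - 1L)) {
      g <- gcd2(rates[[i]], rates[[i + 1L]])
      if (g > 1L)
        stopf("rates (%d, %d) share a common divisor %d; sawtooth structure requires coprime consecutive rates",
              rates[[i]], rates[[i + 1L]], g)
    }
  }
  invisible(TRUE)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Sawtooth atrous spatial pyramid pooling module
#'
#' Collects context at multiple scales by running one 3x3 dilated
#' convolution per rate in parallel, alongside a pointwise 1x1 path, then
#' concatenating all paths and projecting back to `out_channels` with a 1x1
#' convolution. Padding equals the dilation, so spatial dimensions are
#' preserved. One such module is applied independently to each of the four
#' backbone branches.
#'
#' @param in_channels input channel count.
#' @param out_channels per-path and output channel count.
#' @param rates dilation rates, default `c(1, 2, 5)`; validated with
#'   [validate_sawtooth_rates()].
#' @return A module list of type `"aspp"`; apply with [aspp_apply()].
#' @export
build_sawtooth_aspp <- function(in_channels, out_channels = in_channels,
                                rates = c(1L, 2L, 5L)) {
  validate_sawtooth_rates(rates)
  paths <- c(list(conv_module(out_channels, in_channels, 1L)),
             lapply(rates, function(r)
               conv_module(out_channels, in_channels, 3L, dilation = r)))
  list(type = "aspp", rates = rates, in_channels = in_channels,
       out_channels = out_channels, paths = paths,
       project = conv_module(out_channels,
                             out_channels * (length(rates) + 1L), 1L))
}

#' @rdname build_sawtooth_aspp
#' @param module a module built by [build_sawtooth_aspp()].
#' @param x feature tensor `[C, H, W]`.
#' @export
aspp_apply <- function(module, x) {
  stopifnot(identical(module$type, "aspp"), dim(x)[[1]] == module$in_channels)
  feats <- lapply(module$paths, function(p) nn_relu(conv_forward(p, x)))
  stacked <- array(0, c(module$out_channels * length(feats),
                        dim(x)[[2]], dim(x)[[3]]))
  for (i in seq_along(feats))
    stacked[(i - 1L) * module$out_channels + seq_len(module$out_channels), , ] <-
      feats[[i]]
  nn_relu(conv_forward(module$project, stacked))
}
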