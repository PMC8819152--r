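#' Backbone configuration
#'
#' Configuration of the improved parallel-resolution backbone: four
#' branches held at 1/4, 1/8, 1/16 and 1/32 of the input resolution, with
#' attention blocks at five insertion sites — one after each of the two
#' stage-1 extraction (stem) convolutions, and one on the fused
#' full-resolution output of each of the stage-2, stage-3 and stage-4
#' multi-branch fusions.
#'
#' @param tiny use narrow widths `(8, 16, 32, 64)` with attention reduction
#'   4, sized so tests and smoke training run on one CPU in minutes; the
#'   default widths are `(32, 64, 128, 256)` with reduction 16.
#' @param widths optional explicit 4-vector of branch channel widths.
#' @param use_cbam include the attention blocks (disable to obtain the
#'   plain backbone with identical output shapes).
#' @param cbam_reduction channel-attention bottleneck ratio; must divide
#'   every width.
#' @param cbam_spatial_kernel odd spatial-attention kernel size.
#' @return A list of class `backbone_config`.
#' @export
backbone_config <- function(tiny = FALSE, widths = NULL, use_cbam = TRUE,
                            cbam_reduction = NULL, cbam_spatial_kernel = 7L) {
  widths <- widths %||% if (tiny) c(8L, 16L, 32L, 64L) else c(32L, 64L, 128L, 256L)
  if (length(widths) != 4L || any(widths < 1L))
    stopf("backbone needs 4 positive branch widths")
  cbam_reduction <- cbam_reduction %||% if (tiny) 4L else 16L
  if (use_cbam && any(widths %% cbam_reduction != 0L))
    stopf("attention reduction %d must divide every branch width", cbam_reduction)
  structure(list(widths = as.integer(widths), tiny = tiny,
                 use_cbam = isTRUE(use_cbam),
                 cbam_reduction = as.integer(cbam_reduction),
                 cbam_spatial_kernel = as.integer(cbam_spatial_kernel)),
            class = "backbone_config")
}

#' Build the improved parallel-resolution backbone
#'
#' Constructs a four-branch feature extractor that keeps a high-resolution
#' representation alive throughout: a two-convolution stem brings the input
#' to 1/4 resolution, then stages 2-4 successively add a new branch at half
#' the previous resolution and exchange information across all live
#' branches (1x1 channel projection plus average-pool downsampling or
#' nearest upsampling, summed). Attention blocks sit at the five sites
#' described in [backbone_config()]. Forward passes require input height
#' and width divisible by 32 and yield four maps at 1/4, 1/8, 1/16, 1/32
#' resolution with the configured widths.
#'
#' @param config a [backbone_config()].
#' @param seed optional RNG seed for weight initialisation.
#' @return A module list of type `"backbone"`; run with
#'   [backbone_forward()].
#' @export
build_improved_backbone <- function(config = backbone_config(), seed = NULL) {
  stopifnot(inherits(config, "backbone_config"))
  w <- config$widths
  with_seed_or_current(seed, {
    mk_cbam <- function(channels) {
      if (!config$use_cbam) return(NULL)
      build_cbam(channels, config$cbam_reduction, config$cbam_spatial_kernel)
    }
    # fusion unit for a stage with `n` live branches: f[[i]][[j]] projects
    # branch i's channels to branch j's before resolution alignment
    mk_fusion <- function(n) {
      lapply(seq_len(n), function(i)
        lapply(seq_len(n), function(j)
          if (i == j) NULL else conv_module(w[[j]], w[[i]], 1L)))
    }
    list(
      type = "backbone", config = config,
      stem1 = conv_module(w[[1]], 3L, 3L, stride = 2L),
      cbam_stem1 = mk_cbam(w[[1]]),
      stem2 = conv_module(w[[1]], w[[1]], 3L, stride = 2L),
      cbam_stem2 = mk_cbam(w[[1]]),
      stage1_block = conv_module(w[[1]], w[[1]], 3L),
      transitions = list(conv_module(w[[2]], w[[1]], 3L, stride = 2L),
                         conv_module(w[[3]], w[[2]], 3L, stride = 2L),
                         conv_module(w[[4]], w[[3]], 3L, stride = 2L)),
      stage_blocks = list(
        lapply(1:2, function(j) conv_module(w[[j]], w[[j]], 3L)),
        lapply(1:3, function(j) conv_module(w[[j]], w[[j]], 3L)),
        lapply(1:4, function(j) conv_module(w[[j]], w[[j]], 3L))),
      stage_fusions = list(mk_fusion(2L), mk_fusion(3L), mk_fusion(4L)),
      cbam_fusions = list(mk_cbam(w[[1]]), mk_cbam(w[[1]]), mk_cbam(w[[1]]))
    )
  })
}

#' @rdname build_improved_backbone
#' @param backbone a module built by [build_improved_backbone()].
#' @param image pixel array `[H, W, 3]` with both dimensions divisible
#'   by 32.
#' @return A list of 4 feature tensors at 1/4, 1/8, 1/16, 1/32 resolution.
#' @export
backbone_forward <- function(backbone, image) {
  stopifnot(identical(backbone$type, "backbone"))
  h <- dim(image)[[1]]; wdt <- dim(image)[[2]]
  if (h %% 32L != 0L || wdt %% 32L != 0L)
    stopf("backbone input dimensions (%dx%d) must be divisible by 32", wdt, h)
  use_cbam <- backbone$config$use_cbam
  gate <- function(block, x) if (use_cbam && !is.null(block)) cbam_apply(block, x) else x

  x <- aperm(image, c(3, 1, 2))  # [3, H, W]
  x <- gate(backbone$cbam_stem1, nn_relu(conv_forward(backbone$stem1, x)))
  x <- gate(backbone$cbam_stem2, nn_relu(conv_forward(backbone$stem2, x)))
  branches <- list(nn_relu(conv_forward(backbone$stage1_block, x)))

  for (stage in 1:3) {
    n <- stage + 1L
    branches[[n]] <- nn_relu(conv_forward(backbone$transitions[[stage]],
                                          branches[[n - 1L]]))
    branches <- lapply(seq_len(n), function(j)
      nn_relu(conv_forward(backbone$stage_blocks[[stage]][[j]], branches[[j]])))
    fusion <- backbone$stage_fusions[[stage]]
    fused <- lapply(seq_len(n), function(j) {
      acc <- branches[[j]]
      for (i in seq_len(n)) {
        if (i == j) next
        y <- conv_forward(fusion[[i]][[j]], branches[[i]])
        if (i < j) y <- nn_downsample(y, 2L^(j - i))
        else y <- nn_upsample(y, 2L^(i - j))
        acc <- acc + y
      }
      nn_relu(acc)
    })
    fused[[1L]] <- gate(backbone$cbam_fusions[[stage]], fused[[1L]])
    branches <- fused
  }
  branches
}

#' Count attention blocks in a module graph
#'
#' Walks a backbone (or any nested module structure) and counts attention
#' blocks; the improved backbone has exactly five.
#'
#' @param module a module list.
#' @return Integer count.
#' @export
count_attention_blocks <- function(module) {
  length(collect_modules(module, "cbam"))
}
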