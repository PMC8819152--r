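# Minimal tensor operations for the detector. Feature tensors are numeric
# arrays [C, H, W]. Convolution uses im2col so the inner loop is a single
# matrix multiply; at the desk-scale widths used here this is fast enough
# on one CPU.

nn_relu <- function(x) { x[x < 0] <- 0; x }

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# He-normal initialised convolution weights [Cout, Cin, k, k]
conv_weights <- function(cout, cin, k, gain = sqrt(2)) {
  sd <- gain / sqrt(cin * k * k)
  array(rnorm(cout * cin * k * k, sd = sd), c(cout, cin, k, k))
}

conv_module <- function(cout, cin, k, stride = 1L, dilation = 1L,
                        bias = TRUE, gain = sqrt(2)) {
  list(type = "conv",
       w = conv_weights(cout, cin, k, gain),
       b = if (bias) numeric(cout) else NULL,
       k = k, stride = stride, dilation = dilation)
}

conv_forward <- function(mod, x) {
  nn_conv2d(x, mod$w, mod$b, stride = mod$stride, dilation = mod$dilation)
}

# "same"-padded (for stride 1) 2D convolution; pad = dilation * (k - 1) / 2
nn_conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L, pad = NULL) {
  cin <- dim(x)[[1]]; h <- dim(x)[[2]]; wd <- dim(x)[[3]]
  cout <- dim(w)[[1]]; k <- dim(w)[[3]]
  stopifnot(dim(w)[[2]] == cin, dim(w)[[4]] == k)
  if (is.null(pad)) pad <- dilation * (k - 1L) %/% 2L
  hp <- h + 2L * pad; wp <- wd + 2L * pad
  xp <- array(0, c(cin, hp, wp))
  xp[, (pad + 1L):(pad + h), (pad + 1L):(pad + wd)] <- x
  keff <- (k - 1L) * dilation + 1L
  ho <- (hp - keff) %/% stride + 1L
  wo <- (wp - keff) %/% stride + 1L
  if (ho < 1L || wo < 1L) stopf("convolution input too small for kernel")
  X <- matrix(0, cin * k * k, ho * wo)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      rows <- seq((ki - 1L) * dilation + 1L, by = stride, length.out = ho)
      cols <- seq((kj - 1L) * dilation + 1L, by = stride, length.out = wo)
      blk <- xp[, rows, cols, drop = FALSE]
      X[((kj - 1L) * k + ki - 1L) * cin + seq_len(cin), ] <-
        matrix(blk, cin, ho * wo)
    }
  }
  y <- matrix(w, cout, cin * k * k) %*% X
  if (!is.null(b)) y <- y + b
  array(y, c(cout, ho, wo))
}

# nearest-neighbour upsampling by an integer factor
nn_upsample <- function(x, factor = 2L) {
  x[, rep(seq_len(dim(x)[[2]]), each = factor),
    rep(seq_len(dim(x)[[3]]), each = factor), drop = FALSE]
}

# average-pool downsampling by an integer factor (dims must divide)
nn_downsample <- function(x, factor = 2L) {
  d <- dim(x)
  stopifnot(d[[2]] %% factor == 0L, d[[3]] %% factor == 0L)
  ho <- d[[2]] %/% factor; wo <- d[[3]] %/% factor
  out <- array(0, c(d[[1]], ho, wo))
  for (i in seq_len(factor)) for (j in seq_len(factor))
    out <- out + x[, seq(i, by = factor, length.out = ho),
                   seq(j, by = factor, length.out = wo), drop = FALSE]
  out / (factor * factor)
}

nn_global_avg <- function(x) apply(x, 1, mean)
nn_global_max <- function(x) apply(x, 1, max)

# walk a nested module structure counting entries whose $type matches
collect_modules <- function(m, type) {
  found <- list()
  walk <- function(node) {
    if (is.list(node)) {
      if (!is.null(node$type) && identical(node$type, type))
        found[[length(found) + 1L]] <<- node
      for (child in node) if (is.list(child)) walk(child)
    }
  }
  walk(m)
  found
}
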