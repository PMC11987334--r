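# Seeded convolutional feature backend ("cnn4096").
#
# Reproduces the *shape* of the classical AlexNet feature extractor --
# five convolution blocks followed by two 4096-unit fully connected
# layers -- with seeded He-initialized random weights, so that the
# 100 x 4096 QIF-matrix contract and all pipeline plumbing can be
# exercised without downloading any pretrained weights.  Random
# convolutional features are a recognized, information-preserving (if
# weaker) feature map; all statistical acceptance work uses the
# deterministic texture32 backend instead.
#
# Architecture (ungrouped AlexNet, 227 x 227 x 3 input):
#   conv1 11x11x3x96  /4  -> relu -> maxpool 3/2       (55 -> 27)
#   conv2  5x5x96x256 pad2 -> relu -> maxpool 3/2      (27 -> 13)
#   conv3  3x3x256x384 pad1 -> relu
#   conv4  3x3x384x384 pad1 -> relu
#   conv5  3x3x384x256 pad1 -> relu -> maxpool 3/2     (13 -> 6)
#   fc6    9216 -> 4096 -> relu
#   fc7    4096 -> 4096
# The reported 4096-vector is the penultimate fully connected activation;
# `layer = "fc6"` or `"fc7"` selects which (default fc7).
# Channel normalization uses the fixed constants
# mean = (0.485, 0.456, 0.406), sd = (0.229, 0.224, 0.225).

.CNN_INPUT <- 227L
.CNN_MEAN <- c(0.485, 0.456, 0.406)
.CNN_SD <- c(0.229, 0.224, 0.225)

#' @keywords internal
cnn_random_weights <- function(init_seed) {
  spec <- list(
    conv1 = list(k = 11L, cin = 3L,   f = 96L,  stride = 4L, pad = 0L, pool = TRUE),
    conv2 = list(k = 5L,  cin = 96L,  f = 256L, stride = 1L, pad = 2L, pool = TRUE),
    conv3 = list(k = 3L,  cin = 256L, f = 384L, stride = 1L, pad = 1L, pool = FALSE),
    conv4 = list(k = 3L,  cin = 384L, f = 384L, stride = 1L, pad = 1L, pool = FALSE),
    conv5 = list(k = 3L,  cin = 384L, f = 256L, stride = 1L, pad = 1L, pool = TRUE)
  )
  with_seed(init_seed, {
    w <- list(spec = spec)
    for (nm in names(spec)) {
      s <- spec[[nm]]
      fan_in <- s$k * s$k * s$cin
      # one C x F weight slice per kernel offset (k^2 slices)
      w[[nm]] <- lapply(seq_len(s$k^2), function(i)
        matrix(stats::rnorm(s$cin * s$f, 0, sqrt(2 / fan_in)), s$cin, s$f))
    }
    w$fc6 <- matrix(stats::rnorm(9216 * 4096, 0, sqrt(2 / 9216)), 9216, 4096)
    w$fc7 <- matrix(stats::rnorm(4096 * 4096, 0, sqrt(2 / 4096)), 4096, 4096)
    w
  })
}

# convolution as a sum of k*k shifted GEMMs: for each kernel offset the
# (oh*ow) x C window matrix multiplies the C x F weight slice.  Keeps the
# number of R-level indexing operations at k^2 per layer instead of
# k^2 * C, so the BLAS calls dominate.
#' @keywords internal
conv_layer <- function(x, wslices, k, stride = 1L, pad = 0L) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  if (pad > 0L) {
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, C))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
    x <- xp; H <- H + 2L * pad; W <- W + 2L * pad
  }
  oh <- (H - k) %/% stride + 1L; ow <- (W - k) %/% stride + 1L
  rows <- seq.int(1L, by = stride, length.out = oh)
  cols <- seq.int(1L, by = stride, length.out = ow)
  xm <- matrix(x, H * W, C)
  acc <- matrix(0, oh * ow, ncol(wslices[[1]]))
  s <- 0L
  for (dx in 0:(k - 1L)) {
    colbase <- (cols + dx - 1L) * H
    for (dy in 0:(k - 1L)) {
      s <- s + 1L
      idx <- as.vector(outer(rows + dy, colbase, `+`))
      acc <- acc + xm[idx, , drop = FALSE] %*% wslices[[s]]
    }
  }
  array(acc, c(oh, ow, ncol(acc)))
}

#' @keywords internal
maxpool3s2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  oh <- (H - 3L) %/% 2L + 1L; ow <- (W - 3L) %/% 2L + 1L
  rows <- seq.int(1L, by = 2L, length.out = oh)
  cols <- seq.int(1L, by = 2L, length.out = ow)
  out <- array(-Inf, c(oh, ow, dim(x)[3]))
  for (dy in 0:2) for (dx in 0:2)
    out <- pmax(out, x[rows + dy, cols + dx, , drop = FALSE])
  out
}

#' @keywords internal
cnn_forward <- function(patch, weights, layer = "fc7") {
  x <- EBImage::resize(patch, w = .CNN_INPUT, h = .CNN_INPUT,
                       filter = "bilinear")
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - .CNN_MEAN[ch]) / .CNN_SD[ch]
  for (nm in names(weights$spec)) {
    s <- weights$spec[[nm]]
    x <- pmax(conv_layer(x, weights[[nm]], s$k, s$stride, s$pad), 0)
    if (s$pool) x <- maxpool3s2(x)
  }
  v <- pmax(as.vector(x) %*% weights$fc6, 0)     # relu(fc6)
  if (layer == "fc6") return(as.vector(v))
  as.vector(v %*% weights$fc7)
}
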