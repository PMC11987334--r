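# Deterministic 32-dimensional stain/texture feature backend.
#
# Feature order (fixed):
#   1-15  per stain channel (collagen blue, red counterstain, hematoxylin)
#         after optical-density color deconvolution: mean, sd, q10, q50, q90
#   16    collagen-channel area fraction above a fixed OD threshold
#   17-22 per stain channel: gradient-magnitude mean and sd
#   23-30 GLCM contrast, homogeneity, energy (ASM), correlation at offsets
#         (0,1) and (1,0) on a 16-level gray quantization over [0,1]
#   31    bright-object (lumen/fat) pixel fraction (luminance > 0.88)
#   32    bright-object connected components per 1000 pixels
#
# The trichrome stain matrix is a fixed configuration constant (rows are
# unit optical-density vectors for aniline blue, the red counterstain and
# hematoxylin); per-slide recalibration is out of scope.

.STAIN_MATRIX <- local({
  m <- rbind(collagen     = c(0.80, 0.59, 0.11),
             counterstain = c(0.10, 0.74, 0.67),
             hematoxylin  = c(0.65, 0.70, 0.29))
  m / sqrt(rowSums(m^2))
})
.COLLAGEN_OD_THRESHOLD <- 0.10
.BRIGHT_THRESHOLD <- 0.88
.GLCM_LEVELS <- 16L

#' Optical-density stain separation with the fixed trichrome matrix
#'
#' @param patch H x W x 3 RGB array in \[0,1\].
#' @return H x W x 3 array of stain concentrations (collagen,
#'   counterstain, hematoxylin).
#' @keywords internal
stain_concentrations <- function(patch) {
  od <- -log10(pmax(patch, 1e-4))
  dm <- dim(patch)
  odm <- matrix(od, dm[1] * dm[2], 3)
  conc <- odm %*% solve(.STAIN_MATRIX)
  array(conc, c(dm[1], dm[2], 3))
}

#' Gray-level co-occurrence matrix statistics
#'
#' Counts ordered level pairs (i, j) for one pixel offset on a fixed
#' `levels`-bin quantization of \[0,1\], normalizes to probabilities, and
#' returns Haralick contrast, homogeneity, energy (angular second moment)
#' and correlation.  Correlation is defined as 0 when either marginal
#' standard deviation vanishes (single-level image).
#'
#' @param gray Numeric matrix in \[0,1\].
#' @param dr,dc Row/column offset of the second pixel.
#' @param levels Number of quantization levels.
#' @return Named numeric vector `contrast`, `homogeneity`, `energy`,
#'   `correlation`.
#' @keywords internal
glcm_stats <- function(gray, dr, dc, levels = .GLCM_LEVELS) {
  q <- pmin(pmax(floor(gray * levels), 0), levels - 1L) + 1L
  H <- nrow(q); W <- ncol(q)
  r1 <- seq_len(H - abs(dr)); c1 <- seq_len(W - abs(dc))
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * levels + b, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE) / sum(counts)
  i <- row(P); j <- col(P)
  contrast <- sum(P * (i - j)^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  energy <- sum(P^2)
  mi <- sum(i * P); mj <- sum(j * P)
  si <- sqrt(sum((i - mi)^2 * P)); sj <- sqrt(sum((j - mj)^2 * P))
  correlation <- if (si < 1e-12 || sj < 1e-12) 0 else
    sum((i - mi) * (j - mj) * P) / (si * sj)
  c(contrast = contrast, homogeneity = homogeneity, energy = energy,
    correlation = correlation)
}

#' @keywords internal
gradient_magnitude <- function(ch) {
  H <- nrow(ch); W <- ncol(ch)
  gx <- cbind(ch[, 2:W, drop = FALSE], ch[, W]) - ch
  gy <- rbind(ch[2:H, , drop = FALSE], ch[H, ]) - ch
  sqrt(gx^2 + gy^2)
}

#' Deterministic 32-feature stain/texture descriptor of a square patch
#'
#' See the feature list in the package vignette; the order is fixed so
#' feature indices are stable across runs and machines.
#'
#' @param patch Square H x H x 3 RGB array in \[0,1\].
#' @return Named numeric vector of length 32.
#' @examples
#' p <- array(0.5, c(16, 16, 3))
#' f <- texture32_features(p)
#' f[["glcm_contrast_01"]]  # 0 for a constant patch
#' @export
texture32_features <- function(patch) {
  dm <- dim(patch)
  if (length(dm) != 3L || dm[3] != 3L || dm[1] != dm[2])
    fs_stop("patch must be a square H x H x 3 RGB array", "geometry_error")
  conc <- stain_concentrations(patch)
  stains <- c("collagen", "counterstain", "hematoxylin")
  out <- numeric(0)
  for (s in 1:3) {
    v <- conc[, , s]
    qs <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE)
    f <- c(mean(v), stats::sd(as.vector(v)), qs)
    names(f) <- paste0(stains[s], c("_mean", "_sd", "_q10", "_q50", "_q90"))
    out <- c(out, f)
  }
  out <- c(out, collagen_area_fraction =
             mean(conc[, , 1] > .COLLAGEN_OD_THRESHOLD))
  for (s in 1:3) {
    g <- gradient_magnitude(conc[, , s])
    f <- c(mean(g), stats::sd(as.vector(g)))
    names(f) <- paste0(stains[s], c("_gradmag_mean", "_gradmag_sd"))
    out <- c(out, f)
  }
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  for (off in list(c(0L, 1L), c(1L, 0L))) {
    f <- glcm_stats(gray, off[1], off[2])
    names(f) <- paste0("glcm_", names(f), "_", off[1], off[2])
    out <- c(out, f)
  }
  bright <- gray > .BRIGHT_THRESHOLD
  n_comp <- if (any(bright)) max(EBImage::bwlabel(bright)) else 0
  out <- c(out, bright_fraction = mean(bright),
           bright_components_per_kpx = 1000 * n_comp / length(gray))
  stopifnot(length(out) == 32L)
  out
}
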