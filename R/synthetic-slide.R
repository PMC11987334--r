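# Stylized trichrome-like biopsy slide renderer.
#
# The rendering is deliberately schematic -- a three-compartment band
# geometry (epidermis strip / dermis band / subcutis band inside a white
# background border) with an oriented fiber texture in the dermis.  What
# matters for the pipeline is the monotone link between the planted
# severity and the blue-collagen pixel fraction, not photorealism: the
# collagen fraction is set to 0.2 + 0.5 * severity (+ a small seeded
# jitter) by quantile-thresholding a fixed anisotropic noise field, so at a
# fixed seed the realized fraction is strictly increasing in severity.

# fixed color anchors (RGB in [0,1])
.COL_COLLAGEN  <- c(0.25, 0.35, 0.75)  # aniline blue
.COL_DERMIS    <- c(0.80, 0.45, 0.55)  # red counterstain
.COL_NUCLEUS   <- c(0.22, 0.13, 0.32)  # hematoxylin
.COL_EPIDERMIS <- c(0.55, 0.40, 0.62)
.COL_SUBCUTIS  <- c(0.93, 0.82, 0.85)
.COL_VESSEL    <- c(0.70, 0.30, 0.42)
.COL_FAT       <- c(0.985, 0.97, 0.97)

#' Render a synthetic trichrome-stained biopsy slide
#'
#' Builds an RGB raster plus a compartment label mask
#' (0 = background, 1 = epidermis, 2 = dermis, 3 = subcutis) with planted
#' ground truth.  The dermis is filled with an oriented fiber texture whose
#' blue-collagen pixel fraction equals \eqn{0.2 + 0.5 \cdot severity} plus a
#' small seeded jitter; sparse dark nuclei, ring-shaped vessel profiles and
#' an inflammatory-infiltrate dot pattern are overlaid.  The subcutis
#' carries white fat vacuoles whose density decreases with severity, and
#' the epidermal strip thins as severity rises.
#'
#' @param severity Planted disease severity in \eqn{[0, 1]}.
#' @param mpp Microns per pixel (> 0); default 2.0.
#' @param height_px,width_px Raster dimensions.  The defaults
#'   (2048 x 3072) hold one hundred 200 px patches comfortably at
#'   `mpp = 2`.
#' @param seed Integer seed; the same call twice gives identical bytes.
#' @param min_patch_px Minimum square patch side the dermis band must be
#'   able to contain; generation fails with a geometry error otherwise.
#'
#' @return An object of class `biopsy_slide` (also `slide_ref`): a list
#'   with `image` (H x W x 3 array in \[0,1\]), `mask` (H x W integer
#'   matrix), `mpp`, `source_format = "memory"` and `truth`, a list of the
#'   planted parameters (`severity`, `collagen_fraction`,
#'   `fat_vacuole_density`, `vessel_ectasia_count`, `infiltrate_density`,
#'   `epidermal_thickness_um`).
#' @examples
#' sl <- render_biopsy_slide(0.5, mpp = 2, height_px = 256,
#'                           width_px = 320, seed = 3, min_patch_px = 50)
#' table(sl$mask)
#' sl$truth$collagen_fraction
#' @export
render_biopsy_slide <- function(severity, mpp = 2.0, height_px = 2048L,
                                width_px = 3072L, seed,
                                min_patch_px = 200L) {
  if (!is.numeric(severity) || length(severity) != 1L ||
      severity < 0 || severity > 1)
    fs_stop("`severity` must be a single number in [0, 1]",
            "invalid_argument")
  if (!is.numeric(mpp) || mpp <= 0)
    fs_stop("`mpp` must be > 0", "invalid_argument")
  H <- as.integer(height_px); W <- as.integer(width_px)

  border <- max(6L, round(0.02 * min(H, W)))
  epi_um <- 60 - 25 * severity            # epidermal thinning with severity
  epi_px <- max(2L, as.integer(round(epi_um / mpp)))
  sub_px <- max(16L, as.integer(round(0.22 * H)))
  d0 <- border + epi_px + 1L              # dermis row range [d0, d1]
  d1 <- H - border - sub_px
  c0 <- border + 1L; c1 <- W - border
  if (d1 - d0 + 1L < min_patch_px || c1 - c0 + 1L < min_patch_px)
    fs_stop(sprintf(
      "slide %dx%d cannot hold a %d px dermal patch between epidermis and subcutis",
      H, W, min_patch_px), "geometry_error")

  img <- array(1.0, c(H, W, 3))           # white background
  mask <- matrix(0L, H, W)
  mask[(border + 1L):(border + epi_px), c0:c1] <- 1L
  mask[d0:d1, c0:c1] <- 2L
  mask[(d1 + 1L):(H - border), c0:c1] <- 3L

  dh <- d1 - d0 + 1L; dw <- c1 - c0 + 1L
  px_mm2 <- (mpp / 1000)^2                # mm^2 per pixel
  dermis_mm2 <- dh * dw * px_mm2

  with_seed(seed, {
    # -- draws whose RNG position must not depend on severity come first --
    jitter <- stats::runif(1, -0.02, 0.02)
    field <- matrix(stats::rnorm(dh * dw), dh, dw)
    pixnoise <- array(stats::rnorm(dh * dw * 3, 0, 0.03), c(dh, dw, 3))

    # oriented fiber texture: anisotropic gaussian band-pass of white noise
    kx <- stats::dnorm(seq(-12, 12), 0, 5)
    ky <- stats::dnorm(seq(-3, 3), 0, 1.2)
    kern <- outer(ky, kx); kern <- kern / sum(kern)
    field <- EBImage::filter2(field, kern)

    f_target <- min(max(0.2 + 0.5 * severity + jitter, 0.01), 0.99)
    thr <- stats::quantile(field, 1 - f_target, names = FALSE)
    collagen <- field > thr
    collagen_fraction <- mean(collagen)

    derm <- array(rep(.COL_DERMIS, each = dh * dw), c(dh, dw, 3))
    for (ch in 1:3) {
      d <- derm[, , ch]
      d[collagen] <- .COL_COLLAGEN[ch]
      derm[, , ch] <- d + pixnoise[, , ch] + 0.04 * field
    }

    # sparse fibroblast nuclei
    n_nuc <- round(dermis_mm2 * 120)
    if (n_nuc > 0) {
      ri <- sample.int(dh, n_nuc, replace = TRUE)
      ci <- sample.int(dw, n_nuc, replace = TRUE)
      derm <- draw_discs(derm, ri, ci, radius = 2, color = .COL_NUCLEUS)
    }

    # inflammatory infiltrate: clustered dark dots, density grows with severity
    infiltrate_density <- 20 + 180 * severity      # cells per mm^2
    n_inf <- round(dermis_mm2 * infiltrate_density)
    if (n_inf > 0) {
      n_clust <- max(1L, round(n_inf / 25))
      cr <- sample.int(dh, n_clust, replace = TRUE)
      cc <- sample.int(dw, n_clust, replace = TRUE)
      idx <- sample.int(n_clust, n_inf, replace = TRUE)
      ri <- pmin(pmax(cr[idx] + round(stats::rnorm(n_inf, 0, 12)), 1L), dh)
      ci <- pmin(pmax(cc[idx] + round(stats::rnorm(n_inf, 0, 12)), 1L), dw)
      derm <- draw_discs(derm, ri, ci, radius = 1, color = .COL_NUCLEUS)
    }

    # ectatic vessels: ring profiles with a pale lumen
    vessel_ectasia_count <- stats::rpois(1, 1 + 6 * severity)
    if (vessel_ectasia_count > 0) {
      for (v in seq_len(vessel_ectasia_count)) {
        r_out <- stats::runif(1, 7, 15)
        vr <- sample.int(dh, 1); vc <- sample.int(dw, 1)
        derm <- draw_ring(derm, vr, vc, r_in = 0.55 * r_out, r_out = r_out,
                          wall = .COL_VESSEL, lumen = c(0.97, 0.95, 0.96))
      }
    }
    img[d0:d1, c0:c1, ] <- pmin(pmax(derm, 0), 1)

    # epidermis strip
    eh <- epi_px; ew <- dw
    epi <- array(rep(.COL_EPIDERMIS, each = eh * ew), c(eh, ew, 3)) +
      array(stats::rnorm(eh * ew * 3, 0, 0.03), c(eh, ew, 3))
    img[(border + 1L):(border + eh), c0:c1, ] <- pmin(pmax(epi, 0), 1)

    # subcutis with fat vacuoles; density falls with severity (fat loss)
    sh <- (H - border) - d1; sw <- dw
    sub_mm2 <- sh * sw * px_mm2
    fat_density <- 30 * (1 - 0.6 * severity)       # vacuoles per mm^2
    n_fat <- round(sub_mm2 * fat_density)
    sub <- array(rep(.COL_SUBCUTIS, each = sh * sw), c(sh, sw, 3)) +
      array(stats::rnorm(sh * sw * 3, 0, 0.02), c(sh, sw, 3))
    if (n_fat > 0) {
      ri <- sample.int(sh, n_fat, replace = TRUE)
      ci <- sample.int(sw, n_fat, replace = TRUE)
      rad <- stats::runif(n_fat, 4, 10)
      for (v in seq_len(n_fat))
        sub <- draw_discs(sub, ri[v], ci[v], radius = rad[v], color = .COL_FAT)
    }
    img[(d1 + 1L):(H - border), c0:c1, ] <- pmin(pmax(sub, 0), 1)

    structure(list(
      image = img, mask = mask, mpp = mpp, source_format = "memory",
      truth = list(
        severity = severity,
        collagen_fraction = collagen_fraction,
        fat_vacuole_density = if (sub_mm2 > 0) n_fat / sub_mm2 else 0,
        vessel_ectasia_count = as.integer(vessel_ectasia_count),
        infiltrate_density = infiltrate_density,
        epidermal_thickness_um = epi_um
      )
    ), class = c("biopsy_slide", "slide_ref"))
  })
}

# paint filled discs at (rows, cols) into an h x w x 3 array
#' @keywords internal
draw_discs <- function(arr, rows, cols, radius, color) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, , drop = FALSE]
  for (k in seq_along(rows)) {
    rr <- rows[k] + off$dy; cc <- cols[k] + off$dx
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    idx <- cbind(rr[keep], cc[keep])
    for (ch in 1:3) arr[cbind(idx, ch)] <- color[ch]
  }
  arr
}

#' @keywords internal
draw_ring <- function(arr, row, col, r_in, r_out, wall, lumen) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  r <- ceiling(r_out)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- off$dy^2 + off$dx^2
  for (part in list(list(sel = d2 <= r_in^2, col = lumen),
                    list(sel = d2 > r_in^2 & d2 <= r_out^2, col = wall))) {
    o <- off[part$sel, , drop = FALSE]
    rr <- row + o$dy; cc <- col + o$dx
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    idx <- cbind(rr[keep], cc[keep])
    for (ch in 1:3) arr[cbind(idx, ch)] <- part$col[ch]
  }
  arr
}
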