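# Random dermal patch sampling.
#
# Patches are axis-aligned squares of side sqrt(area) (default
# sqrt(0.16 mm^2) = 400 um), drawn uniformly at random -- with replacement,
# overlap allowed -- from positions whose *entire* footprint carries the
# dermis label.  Coordinates are 0-based (row, col) half-open squares
# [r0, r0 + side) x [c0, c0 + side).  Feasibility is checked with a
# dermis-only summed-area table so validity of a candidate is O(1), and a
# draw cap of 1000 * n rejections guards against fragmented dermis.

#' Sample random dermal patches from a slide
#'
#' @param slide A `slide_ref` (its `mpp` converts the patch area to
#'   pixels).
#' @param mask Integer compartment mask (same dimensions as the slide);
#'   typically from [read_mask()] or the `mask` field of a synthetic
#'   slide.
#' @param n Number of patches (default 100).
#' @param area_mm2 Patch area in mm^2 (default 0.16, i.e. a 400 um
#'   square).
#' @param seed Integer seed; fixed seed reproduces the coordinate list.
#' @param biopsy_id Identifier carried into downstream tables.
#' @return An object of class `patch_set`: list with `biopsy_id`,
#'   `patches` (data.frame `row0`, `col0`, `side_px`; 0-based), `n`,
#'   `side_px`, `area_mm2`, `seed`.
#' @examples
#' sl <- render_biopsy_slide(0.4, mpp = 2, height_px = 512, width_px = 640,
#'                           seed = 1, min_patch_px = 100)
#' ps <- sample_patches(sl, sl$mask, n = 10, area_mm2 = 0.04, seed = 17)
#' ps$side_px  # 100 px: sqrt(0.04) mm = 200 um at 2 um/px
#' @export
sample_patches <- function(slide, mask, n = 100L, area_mm2 = 0.16, seed,
                           biopsy_id = "biopsy") {
  stopifnot(inherits(slide, "slide_ref"))
  if (!is_count(n)) fs_stop("`n` must be an integer >= 1", "invalid_argument")
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    fs_stop("`area_mm2` must be > 0", "invalid_argument")
  side <- as.integer(round(1000 * sqrt(area_mm2) / slide$mpp))
  H <- nrow(mask); W <- ncol(mask)
  if (side > H || side > W)
    fs_stop(sprintf("patch side %d px exceeds slide %dx%d", side, H, W),
            "no_dermis_error")

  # summed-area table of the dermis indicator: footprint is all-dermis iff
  # its window sum equals side^2
  dermis <- matrix(as.numeric(mask == 2L), H, W)
  sat <- apply(apply(dermis, 2, cumsum), 1, cumsum)  # W x H (transposed)
  win_sum <- function(r0, c0) {            # 0-based top-left corners
    r1 <- r0 + side; c1 <- c0 + side       # exclusive ends, 0-based
    s <- sat[cbind(c1, r1)]
    s <- s - ifelse(r0 > 0, sat[cbind(c1, pmax(r0, 1))], 0)
    s <- s - ifelse(c0 > 0, sat[cbind(pmax(c0, 1), r1)], 0)
    s + ifelse(r0 > 0 & c0 > 0, sat[cbind(pmax(c0, 1), pmax(r0, 1))], 0)
  }

  max_r0 <- H - side; max_c0 <- W - side   # valid 0-based corner range [0, max]
  target <- as.numeric(side)^2
  if (sum(dermis) < target)
    fs_stop("mask contains no all-dermis patch position", "no_dermis_error")
  with_seed(seed, {
    placed_r <- integer(0); placed_c <- integer(0)
    rejected <- 0L; cap <- 1000L * n
    while (length(placed_r) < n) {
      need <- n - length(placed_r)
      m <- max(2L * need, 64L)
      r0 <- sample.int(max_r0 + 1L, m, replace = TRUE) - 1L
      c0 <- sample.int(max_c0 + 1L, m, replace = TRUE) - 1L
      ok <- abs(win_sum(r0, c0) - target) < 0.5
      rejected <- rejected + sum(!ok)
      keep <- which(ok)
      if (length(keep) > need) keep <- keep[seq_len(need)]
      placed_r <- c(placed_r, r0[keep]); placed_c <- c(placed_c, c0[keep])
      if (rejected >= cap) {
        # distinguish "no valid position at all" from exhaustion
        if (!any_valid_position(win_sum, max_r0, max_c0, target))
          fs_stop("mask contains no all-dermis patch position",
                  "no_dermis_error")
        fs_stop(sprintf(
          "draw cap reached after %d rejections; %d of %d patches placed (dermis too fragmented)",
          rejected, length(placed_r), n), "sampling_exhausted_error")
      }
    }
    structure(list(
      biopsy_id = biopsy_id,
      patches = data.frame(row0 = placed_r, col0 = placed_c,
                           side_px = side),
      n = n, side_px = side, area_mm2 = area_mm2, seed = as.integer(seed)
    ), class = "patch_set")
  })
}

# exhaustive scan on a coarse-to-fine grid: is any corner fully dermis?
#' @keywords internal
any_valid_position <- function(win_sum, max_r0, max_c0, target) {
  r <- rep(0:max_r0, times = max_c0 + 1L)
  c <- rep(0:max_c0, each = max_r0 + 1L)
  # chunked to bound memory on big slides
  idx <- seq_along(r)
  for (ch in split(idx, ceiling(idx / 5e5)))
    if (any(abs(win_sum(r[ch], c[ch]) - target) < 0.5)) return(TRUE)
  FALSE
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %s: %d patches of %d px (%.3g mm^2), seed %d\n",
              x$biopsy_id, x$n, x$side_px, x$area_mm2, x$seed))
  invisible(x)
}

# extract pixel data for one patch (1-based R indexing from 0-based coords)
#' @keywords internal
patch_pixels <- function(slide, row0, col0, side) {
  H <- dim(slide$image)[1]; W <- dim(slide$image)[2]
  if (row0 < 0 || col0 < 0 || row0 + side > H || col0 + side > W)
    fs_stop(sprintf("patch (%d,%d,+%d) outside %dx%d slide",
                    row0, col0, side, H, W), "geometry_error")
  slide$image[(row0 + 1L):(row0 + side), (col0 + 1L):(col0 + side), ,
              drop = FALSE]
}
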