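# Reading and writing section images and compartment masks.
#
# Slides are stored as TIFF or PNG rasters.  Neither writer used here
# embeds spatial calibration, so the micron-per-pixel value travels in a
# JSON sidecar `<image>.mpp.json` written next to the raster (and the
# planted truth, when present, in `<image>.truth.json`).  `read_slide`
# falls back to an explicit `mpp` argument and raises a calibration error
# when neither source is available.

.MASK_LABELS <- 0:3  # 0 background, 1 epidermis, 2 dermis, 3 subcutis

#' Write a slide (image + mask + sidecars) to disk
#'
#' Writes the RGB raster as TIFF or PNG, the compartment mask as a
#' single-channel PNG using the 0-3 label convention (scaled by 1/255),
#' the calibration as `<path>.mpp.json` and, for synthetic slides, the
#' planted truth as `<path>.truth.json`.
#'
#' @param slide A `biopsy_slide` or `slide_ref` with an in-memory image.
#' @param path Output image path; the extension selects the format
#'   (`.tif`/`.tiff` or `.png`).
#' @return Invisibly, a named list of the files written.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide_ref"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(slide$image, path, bits.per.sample = 8L,
                    compression = "deflate")
  } else if (ext == "png") {
    png::writePNG(slide$image, path)
  } else {
    fs_stop(sprintf("unsupported slide format '.%s'", ext), "io_error")
  }
  files <- list(image = path)
  mpp_path <- paste0(path, ".mpp.json")
  jsonlite::write_json(list(mpp = slide$mpp), mpp_path,
                       auto_unbox = TRUE, digits = NA)
  files$mpp <- mpp_path
  if (!is.null(slide$mask)) {
    mask_path <- paste0(tools::file_path_sans_ext(path), "_mask.png")
    png::writePNG(slide$mask / 255, mask_path)
    files$mask <- mask_path
  }
  if (!is.null(slide$truth)) {
    truth_path <- paste0(path, ".truth.json")
    jsonlite::write_json(slide$truth, truth_path,
                         auto_unbox = TRUE, digits = NA)
    files$truth <- truth_path
  }
  invisible(files)
}

#' Read a section image into a slide reference
#'
#' @param path TIFF or PNG file.
#' @param mpp Optional explicit microns-per-pixel override.  When absent,
#'   the `<path>.mpp.json` sidecar is consulted; if that is also missing a
#'   calibration error is raised.
#' @return A `slide_ref`: list with `image` (H x W x 3 in \[0,1\]), `mpp`,
#'   `source_format`.
#' @export
read_slide <- function(path, mpp = NULL) {
  if (!file.exists(path))
    fs_stop(sprintf("file not found: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    fs_stop(sprintf("unsupported slide format '.%s'", ext), "io_error"))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L)
    img <- img[, , 1:3, drop = FALSE]           # drop alpha
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    fs_stop("slide must be a three-channel RGB raster", "io_error")
  if (is.null(mpp)) {
    sidecar <- paste0(path, ".mpp.json")
    if (file.exists(sidecar)) {
      mpp <- jsonlite::read_json(sidecar)$mpp
    } else {
      fs_stop(paste0("no micron-per-pixel calibration: supply `mpp` or a ",
                     basename(sidecar), " sidecar"), "calibration_error")
    }
  }
  if (!is.numeric(mpp) || mpp <= 0)
    fs_stop("`mpp` must be a positive number", "calibration_error")
  structure(list(image = img, mpp = as.numeric(mpp), source_format = ext),
            class = "slide_ref")
}

#' Read and validate a compartment label mask
#'
#' @param path Single-channel PNG written with labels/255, or an integer
#'   matrix passed through directly.
#' @param slide The `slide_ref` the mask belongs to; dimensions must match.
#' @return An integer matrix of labels in \{0,1,2,3\} with a
#'   `label_counts` attribute giving per-label pixel counts.
#' @export
read_mask <- function(path, slide) {
  m <- if (is.matrix(path)) path else {
    if (!file.exists(path))
      fs_stop(sprintf("file not found: %s", path), "io_error")
    round(png::readPNG(path) * 255)
  }
  if (length(dim(m)) != 2L)
    fs_stop("mask must be a single-channel raster", "schema_error")
  if (!all(dim(m) == dim(slide$image)[1:2]))
    fs_stop(sprintf("mask is %dx%d but slide is %dx%d",
                    nrow(m), ncol(m), dim(slide$image)[1],
                    dim(slide$image)[2]), "geometry_error")
  lab <- sort(unique(as.integer(m)))
  bad <- setdiff(lab, .MASK_LABELS)
  if (length(bad))
    fs_stop(paste("mask contains unknown label(s):",
                  paste(bad, collapse = ", ")), "schema_error")
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  counts <- vapply(.MASK_LABELS, function(l) sum(m == l), integer(1))
  names(counts) <- c("background", "epidermis", "dermis", "subcutis")
  message(sprintf("mask labels: %s",
                  paste(names(counts), counts, sep = "=", collapse = ", ")))
  attr(m, "label_counts") <- counts
  m
}
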