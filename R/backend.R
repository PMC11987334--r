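# Feature backend registry and QIF extraction.

#' Create a quantitative-image-feature backend
#'
#' Two backends are available:
#' \describe{
#'   \item{`texture32`}{deterministic 32-feature stain/texture descriptor
#'     ([texture32_features()]); needs no parameters.}
#'   \item{`cnn4096`}{an AlexNet-shaped convolutional network with seeded
#'     He-initialized random weights producing the classical 4096-unit
#'     penultimate fully connected activation.  `params$init_seed`
#'     (default 1) seeds the weights; `params$layer` selects `"fc6"` or
#'     `"fc7"` (default).}
#' }
#'
#' @param name `"texture32"` or `"cnn4096"`.
#' @param params Backend configuration list.
#' @return An object of class `qif_backend` with fields `name`, `D` and a
#'   `featfun(patch)` closure.  Identical patch bytes and backend state
#'   yield identical feature vectors.
#' @export
make_backend <- function(name, params = list()) {
  if (identical(name, "texture32")) {
    backend <- list(name = "texture32", D = 32L, params = params,
                    featfun = texture32_features)
  } else if (identical(name, "cnn4096")) {
    init_seed <- params$init_seed %||% 1L
    layer <- params$layer %||% "fc7"
    if (!layer %in% c("fc6", "fc7"))
      fs_stop("`params$layer` must be 'fc6' or 'fc7'", "invalid_argument")
    weights <- cnn_random_weights(init_seed)
    backend <- list(
      name = "cnn4096", D = 4096L,
      params = list(init_seed = init_seed, layer = layer),
      featfun = function(patch) cnn_forward(patch, weights, layer))
  } else {
    fs_stop(sprintf("unknown backend '%s' (use 'texture32' or 'cnn4096')",
                    name), "invalid_argument")
  }
  class(backend) <- "qif_backend"
  backend
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the patch-by-feature QIF matrix for one biopsy
#'
#' Applies the backend to every patch in the set; with the defaults
#' (100 patches, cnn4096) the result is the classical 100 x 4096 matrix,
#' 409,600 feature values per biopsy.
#'
#' @param slide A `slide_ref`.
#' @param patchset A `patch_set` from [sample_patches()].
#' @param backend A `qif_backend` from [make_backend()].
#' @return An object of class `qif_matrix`: list with `biopsy_id`,
#'   `values` (n_patches x D matrix), `backend`, `D` and `patch_coords`.
#' @export
extract_qif <- function(slide, patchset, backend) {
  stopifnot(inherits(slide, "slide_ref"), inherits(patchset, "patch_set"),
            inherits(backend, "qif_backend"))
  p <- patchset$patches
  vals <- matrix(NA_real_, nrow(p), backend$D)
  feat_names <- NULL
  for (i in seq_len(nrow(p))) {
    px <- patch_pixels(slide, p$row0[i], p$col0[i], p$side_px[i])
    v <- backend$featfun(px)
    if (any(!is.finite(v)))
      fs_stop(sprintf("non-finite feature for patch %d (row0=%d, col0=%d)",
                      i, p$row0[i], p$col0[i]), "numeric_error")
    if (i == 1L) feat_names <- names(v)
    vals[i, ] <- v
  }
  if (!is.null(feat_names)) colnames(vals) <- feat_names
  structure(list(biopsy_id = patchset$biopsy_id, values = vals,
                 backend = backend$name, D = backend$D,
                 patch_coords = p),
            class = "qif_matrix")
}

#' @export
print.qif_matrix <- function(x, ...) {
  cat(sprintf("<qif_matrix> %s: %d patches x %d features (%s backend)\n",
              x$biopsy_id, nrow(x$values), x$D, x$backend))
  invisible(x)
}
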