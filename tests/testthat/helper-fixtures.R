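# shared in-code fixtures; everything is generated at test time

# wrap a plain matrix as a qif_matrix (synthetic feature backend)
mk_qif <- function(id, X) {
  structure(list(biopsy_id = id, values = X, backend = "synthetic",
                 D = ncol(X), patch_coords = NULL),
            class = "qif_matrix")
}

# a slide_ref with a uniform image and an all-dermis mask (plus the mask)
mk_flat_slide <- function(h, w, mpp = 2) {
  structure(list(image = array(0.5, c(h, w, 3)), mpp = mpp,
                 source_format = "memory"),
            class = "slide_ref")
}

# planted-truth table in the renderer's truth schema
mk_truth <- function(n, seed = 1) {
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(s); force(code)
  }
  withr_seed(seed, {
    s <- runif(n)
    data.frame(biopsy_id = sprintf("b%04d", seq_len(n)), severity = s,
               collagen_fraction = 0.2 + 0.5 * s,
               fat_vacuole_density = 30 * (1 - 0.6 * s),
               vessel_ectasia_count = rpois(n, 1 + 6 * s),
               infiltrate_density = 20 + 180 * s,
               epidermal_thickness_um = 60 - 25 * s)
  })
}

noiseless_profiles <- function() {
  list(rater_profile("R1", 0, c(0, 1, 0), 0, 0),
       rater_profile("R2", 0, c(0, 1, 0), 0, 0))
}

# synthetic patch-feature cohort with a planted linear biopsy-level signal
mk_linear_cohort <- function(n_biopsy = 12, patches = 25, D = 10,
                             noise = 2, seed = 1) {
  set.seed(seed)
  qifs <- list(); labels <- c(); groups <- c()
  v <- rnorm(D); v <- v / sqrt(sum(v^2))
  for (b in seq_len(n_biopsy)) {
    z <- rnorm(1)
    X <- matrix(rnorm(patches * D, sd = 0.5), patches, D) +
      tcrossprod(rep(z, patches), v)
    id <- sprintf("b%02d", b)
    qifs[[b]] <- mk_qif(id, X)
    labels[id] <- 25 + 10 * z + rnorm(1, 0, noise)
    groups[id] <- sprintf("p%02d", b)
  }
  list(qifs = qifs, labels = labels, groups = groups)
}
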