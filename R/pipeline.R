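# End-to-end run: simulate -> sample -> extract -> fit -> score -> stats.
#
# A single run seed is fanned out to per-stage child seeds by a fixed
# derivation, so each stage is independently reproducible and two runs
# with the same config produce byte-identical outputs.

.CONFIG_DEFAULTS <- list(
  seed = 17L,
  n_patients = 20L,
  visits = c(0, 24, 52),
  slope_sd = 0.1,
  noise_sd = 1,
  patch = list(count = 100L, area_mm2 = 0.16),
  slide = list(mpp = 2.0, height_px = 2048L, width_px = 3072L),
  backend = list(name = "texture32", params = list()),
  lambda_grid = list(count = 16L, log10_min = -5, log10_max = 3),
  cv = "group",
  raters = list(flip_prob = 0.1, ordinal_noise = c(0.1, 0.8, 0.1),
                continuous_cv = 0.1, session_drift = 0.05),
  log_level = "info"
)

#' Read, default and validate a pipeline run configuration
#'
#' Unknown keys (at top level or inside nested sections) are rejected so
#' a typo cannot silently fall back to a default.  An empty file yields
#' the full default configuration: 100 patches of 0.16 mm^2, a 16-value
#' penalty grid from 1e-5 to 1e3, 20 patients with visits at weeks 0, 24
#' and 52.
#'
#' @param path YAML file.
#' @return A validated config list of class `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path))
    fs_stop(sprintf("config file not found: %s", path), "io_error")
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .CONFIG_DEFAULTS
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      fs_stop(sprintf("unknown config key%s in %s: %s",
                      if (length(bad) > 1) "s" else "", where,
                      paste(bad, collapse = ", ")), "config_error")
  }
  check_keys(user, names(cfg), "top level")
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && !is.null(names(cfg[[key]]))) {
      check_keys(user[[key]], names(cfg[[key]]), key)
      cfg[[key]] <- utils::modifyList(cfg[[key]], user[[key]])
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  range_check <- function(ok, what) {
    if (!ok) fs_stop(paste("config value out of range:", what),
                     "range_error")
  }
  range_check(is_count(cfg$n_patients), "n_patients must be an integer >= 1")
  range_check(is_count(cfg$patch$count), "patch$count must be an integer >= 1")
  range_check(is.numeric(cfg$patch$area_mm2) && cfg$patch$area_mm2 > 0,
              "patch$area_mm2 must be > 0")
  range_check(is.numeric(cfg$slide$mpp) && cfg$slide$mpp > 0,
              "slide$mpp must be > 0")
  range_check(is_count(cfg$lambda_grid$count, 2), "lambda_grid$count must be >= 2")
  range_check(all(cfg$visits >= 0), "visits must be nonnegative weeks")
  range_check(cfg$cv %in% "group", "cv must be 'group'")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Generates a cohort, renders one slide per (patient, visit) biopsy,
#' samples dermal patches, extracts QIFs, fits the Fibrosis Score model
#' with grouped-CV penalty selection, simulates two-rater score sheets
#' from the planted truth, and computes the statistics layer.  Writes
#' `scores.csv`, `or_table.csv`, `kappa_table.csv`, `slopes.csv`,
#' `correlation.json`, `model.json` and `manifest.json` into `outdir`.
#'
#' @param config A `run_config` from [validate_config()], or a path to a
#'   YAML config file.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the fitted model, score table, stats
#'   tables and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  msg <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                              sprintf(...)))

  msg("cohort", "generating %d patients", config$n_patients)
  cohort <- generate_cohort(config$n_patients, seed = child_seed(seed, 1L),
                            slope_sd = config$slope_sd,
                            noise_sd = config$noise_sd)
  cohort <- cohort[cohort$week %in% config$visits, ]
  cohort$biopsy_id <- sprintf("%s_W%02d", cohort$patient_id, cohort$week)

  side_px <- round(1000 * sqrt(config$patch$area_mm2) / config$slide$mpp)
  msg("slides", "rendering %d biopsies (%dx%d px)", nrow(cohort),
      config$slide$height_px, config$slide$width_px)
  backend <- make_backend(config$backend$name, config$backend$params)
  qifs <- vector("list", nrow(cohort))
  truths <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sl <- render_biopsy_slide(cohort$severity[i], mpp = config$slide$mpp,
                              height_px = config$slide$height_px,
                              width_px = config$slide$width_px,
                              seed = child_seed(seed, 100L + i),
                              min_patch_px = side_px)
    ps <- sample_patches(sl, sl$mask, n = config$patch$count,
                         area_mm2 = config$patch$area_mm2,
                         seed = child_seed(seed, 10000L + i),
                         biopsy_id = cohort$biopsy_id[i])
    qifs[[i]] <- extract_qif(sl, ps, backend)
    truths[[i]] <- c(list(biopsy_id = cohort$biopsy_id[i]), sl$truth)
  }
  truth <- do.call(rbind, lapply(truths, as.data.frame))

  msg("fit", "grouped-CV lasso over %d penalties", config$lambda_grid$count)
  labels <- stats::setNames(cohort$mrss, cohort$biopsy_id)
  groups <- stats::setNames(cohort$patient_id, cohort$biopsy_id)
  grid <- make_lambda_grid(config$lambda_grid$count,
                           config$lambda_grid$log10_min,
                           config$lambda_grid$log10_max)
  model <- fit_fibrosis(qifs, labels, groups, grid,
                        seed = child_seed(seed, 2L))

  scores <- lapply(qifs, predict_fibrosis_score, model = model)
  score_tab <- data.frame(
    biopsy_id = cohort$biopsy_id, patient_id = cohort$patient_id,
    week = cohort$week, mrss = cohort$mrss,
    fibrosis_score = vapply(scores, function(s) s$score, numeric(1)),
    n_patches = config$patch$count)
  # held-out scores at the selected penalty (from the CV table)
  cvt <- model$cv$cv_table
  held <- cvt[abs(cvt$lambda - model$lambda) < 1e-12, ]
  score_tab$fibrosis_score_heldout <-
    held$pred[match(score_tab$biopsy_id, held$biopsy_id)]

  msg("stats", "rater simulation and statistics layer")
  profiles <- list(
    rater_profile("R1", config$raters$flip_prob, config$raters$ordinal_noise,
                  config$raters$continuous_cv, config$raters$session_drift),
    rater_profile("R2", config$raters$flip_prob, config$raters$ordinal_noise,
                  config$raters$continuous_cv, config$raters$session_drift))
  sheets <- simulate_rater_scores(truth, profiles, sessions = 2L,
                                  seed = child_seed(seed, 3L))
  kappa_tab <- rater_agreement(sheets)
  or_mrss <- odds_ratio_table(sheets, stats::setNames(cohort$mrss,
                                                      cohort$biopsy_id))
  or_score <- odds_ratio_table(sheets, stats::setNames(
    score_tab$fibrosis_score, score_tab$biopsy_id))
  or_tab <- rbind(cbind(predictor = "mrss", or_mrss),
                  cbind(predictor = "fibrosis_score", or_score))
  slope_tab <- slope_table(sheets, cohort[, c("biopsy_id", "patient_id",
                                              "week")])
  corr <- evaluate_scores(score_tab$fibrosis_score_heldout, cohort$mrss)

  write_csv <- function(d, name) {
    f <- file.path(outdir, name)
    utils::write.csv(d, f, row.names = FALSE)
    f
  }
  files <- c(
    write_csv(score_tab, "scores.csv"),
    write_csv(or_tab, "or_table.csv"),
    write_csv(kappa_tab, "kappa_table.csv"),
    write_csv(slope_tab, "slopes.csv"))
  jsonlite::write_json(list(rho = corr$rho, p = corr$p, n = corr$n),
                       file.path(outdir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    coefficients = as.list(model$coefficients), intercept = model$intercept,
    lambda = model$lambda, center = as.list(model$center),
    scale = as.list(model$scale), backend = config$backend$name,
    seed = seed), file.path(outdir, "model.json"),
    auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(outdir, c("correlation.json", "model.json")))

  cfg_file <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = seed,
    package_version = as.character(utils::packageVersion("fibroscore")),
    lambda_selected = model$lambda,
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, scores = score_tab, or_table = or_tab,
                 kappa_table = kappa_tab, slope_table = slope_tab,
                 correlation = corr, manifest = manifest, truth = truth))
}
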