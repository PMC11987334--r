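# Simulated dermatopathologist score sheets.
#
# The 16-parameter schema mirrors standard scleroderma dermatopathology
# scoring: eight present/absent parameters, four continuous measurements
# and four 0-5 staining intensities scored against a reference standard.
# True values derive from the planted slide truth through fixed monotone
# thresholds (documented in `histo_truth_scores`); each simulated rater
# then perturbs them according to a `rater_profile`, with optional extra
# drift at the second scoring session (the wash-out re-read).

#' The 16-parameter histological score schema
#'
#' @return A list with character vectors `binary`, `continuous`, `ordinal`
#'   naming the 16 parameters by type.
#' @export
histo_params <- function() {
  list(
    binary = c("epidermal_papilla_loss", "eccrine_entrapment",
               "eccrine_coil_loss", "telangiectasia", "hair_follicle_loss",
               "calcification", "sc_fat_loss_widened_septa",
               "thickened_intima"),
    continuous = c("mean_epidermal_thickness_um", "perivascular_cd3_density",
                   "perivascular_cd8_density", "pct_cd8_among_cd3"),
    ordinal = c("hyalinized_collagen", "cd34", "trichrome", "asma")
  )
}

.TRUTH_FIELDS <- c("severity", "collagen_fraction", "fat_vacuole_density",
                   "vessel_ectasia_count", "infiltrate_density",
                   "epidermal_thickness_um")

#' Noise profile for a simulated rater
#'
#' @param rater_id Character label.
#' @param flip_prob Probability of flipping a binary call; must be in
#'   \eqn{[0, 0.5)} (at 0.5 a rater carries no information).
#' @param ordinal_noise Length-3 probabilities of a \eqn{\{-1, 0, +1\}}
#'   jitter on the 0-5 scales; must sum to 1.
#' @param continuous_cv Coefficient of variation applied multiplicatively
#'   to continuous measurements.
#' @param session_drift Extra noise added at the second scoring session:
#'   an additional flip probability for binary calls, an additional
#'   \eqn{\pm 1} jitter probability for ordinal scales, and an additional
#'   coefficient of variation for continuous measurements.
#' @return A list of class `rater_profile`.
#' @export
rater_profile <- function(rater_id, flip_prob = 0.1,
                          ordinal_noise = c(0.1, 0.8, 0.1),
                          continuous_cv = 0.1, session_drift = 0.05) {
  if (!is.numeric(flip_prob) || flip_prob < 0 || flip_prob >= 0.5)
    fs_stop("`flip_prob` must be in [0, 0.5)", "invalid_argument")
  if (length(ordinal_noise) != 3L || any(ordinal_noise < 0) ||
      abs(sum(ordinal_noise) - 1) > 1e-8)
    fs_stop("`ordinal_noise` must be 3 nonnegative probabilities summing to 1",
            "invalid_argument")
  if (!is.numeric(continuous_cv) || continuous_cv < 0)
    fs_stop("`continuous_cv` must be >= 0", "invalid_argument")
  if (!is.numeric(session_drift) || session_drift < 0)
    fs_stop("`session_drift` must be >= 0", "invalid_argument")
  structure(list(rater_id = as.character(rater_id), flip_prob = flip_prob,
                 ordinal_noise = as.numeric(ordinal_noise),
                 continuous_cv = continuous_cv,
                 session_drift = session_drift),
            class = "rater_profile")
}

#' True 16-parameter scores implied by planted slide truth
#'
#' Fixed monotone thresholds translate the planted parameters into the
#' score schema: e.g. subcutaneous fat loss / widened septa is true iff
#' severity > 0.5, telangiectasia iff at least 3 ectatic vessel profiles
#' were rendered, hyalinized collagen is `floor(6 * severity)` capped at 5.
#'
#' @param truth A data.frame with columns `biopsy_id` and the planted
#'   fields `severity`, `collagen_fraction`, `fat_vacuole_density`,
#'   `vessel_ectasia_count`, `infiltrate_density`,
#'   `epidermal_thickness_um`.
#' @return A data.frame with `biopsy_id` and the 16 parameter columns.
#' @export
histo_truth_scores <- function(truth) {
  missing <- setdiff(c("biopsy_id", .TRUTH_FIELDS), names(truth))
  if (length(missing))
    fs_stop(paste("truth table lacks field(s):",
                  paste(missing, collapse = ", ")), "schema_error")
  s <- truth$severity
  cd3 <- pmax(round(truth$infiltrate_density / 4), 0)
  cd8 <- pmax(round(cd3 * (0.3 + 0.4 * s)), 0)
  ord5 <- function(x) as.integer(pmin(pmax(floor(x), 0), 5))
  data.frame(
    biopsy_id = truth$biopsy_id,
    epidermal_papilla_loss = as.integer(s > 0.30),
    eccrine_entrapment = as.integer(s > 0.40),
    eccrine_coil_loss = as.integer(s > 0.70),
    telangiectasia = as.integer(truth$vessel_ectasia_count >= 3),
    hair_follicle_loss = as.integer(s > 0.55),
    calcification = as.integer(s > 0.85),
    sc_fat_loss_widened_septa = as.integer(s > 0.50),
    thickened_intima = as.integer(s > 0.60),
    mean_epidermal_thickness_um = truth$epidermal_thickness_um,
    perivascular_cd3_density = cd3,
    perivascular_cd8_density = cd8,
    pct_cd8_among_cd3 = 100 * cd8 / pmax(cd3, 1),
    hyalinized_collagen = ord5(6 * s),
    cd34 = ord5(5 * s + 0.5),
    trichrome = ord5(6 * (truth$collagen_fraction - 0.2) / 0.5),
    asma = ord5(5.5 * s),
    stringsAsFactors = FALSE
  )
}

#' Simulate two-rater, two-session histological score sheets
#'
#' @param truth Planted-parameter table as for [histo_truth_scores()].
#' @param profiles List of exactly two [rater_profile()] objects.
#' @param sessions Number of scoring sessions per rater (default 2,
#'   emulating a re-read after a wash-out period).
#' @param seed Integer seed; fixed seed gives identical sheets.
#' @return A data.frame of class `histo_score_sheet` with one row per
#'   (biopsy, rater, session) and the 16 parameter columns.
#' @examples
#' tr <- data.frame(biopsy_id = c("b1", "b2"), severity = c(0.2, 0.8),
#'                  collagen_fraction = c(0.3, 0.6),
#'                  fat_vacuole_density = c(25, 12),
#'                  vessel_ectasia_count = c(1L, 5L),
#'                  infiltrate_density = c(50, 180),
#'                  epidermal_thickness_um = c(55, 40))
#' pr <- list(rater_profile("R1"), rater_profile("R2"))
#' sheets <- simulate_rater_scores(tr, pr, seed = 1)
#' nrow(sheets)  # 2 biopsies x 2 raters x 2 sessions
#' @export
simulate_rater_scores <- function(truth, profiles, sessions = 2L, seed) {
  if (length(profiles) != 2L ||
      !all(vapply(profiles, inherits, logical(1), "rater_profile")))
    fs_stop("`profiles` must be a list of exactly 2 rater_profile objects",
            "invalid_argument")
  if (!is_count(sessions))
    fs_stop("`sessions` must be an integer >= 1", "invalid_argument")
  true_scores <- histo_truth_scores(truth)
  p <- histo_params()
  n <- nrow(true_scores)
  with_seed(seed, {
    out <- list()
    for (pr in profiles) for (s in seq_len(sessions)) {
      drift <- if (s > 1L) pr$session_drift else 0
      sheet <- true_scores
      # binary: independent flips
      fp <- min(pr$flip_prob + drift, 0.499)
      for (col in p$binary) {
        flip <- stats::rbinom(n, 1L, fp)
        sheet[[col]] <- as.integer(xor(sheet[[col]], flip))
      }
      # ordinal 0-5: +/-1 jitter, clamped
      for (col in p$ordinal) {
        j <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                    prob = pr$ordinal_noise)
        if (drift > 0) {
          j2 <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                       prob = c(drift / 2, 1 - drift, drift / 2))
          j <- j + j2
        }
        sheet[[col]] <- as.integer(pmin(pmax(sheet[[col]] + j, 0L), 5L))
      }
      # continuous: multiplicative noise at the rater's CV (+ drift)
      cv <- sqrt(pr$continuous_cv^2 + drift^2)
      for (col in p$continuous) {
        x <- sheet[[col]] * (1 + stats::rnorm(n, 0, cv))
        x <- pmax(x, 0)
        if (col %in% c("perivascular_cd3_density",
                       "perivascular_cd8_density")) x <- round(x)
        if (col == "pct_cd8_among_cd3") x <- pmin(x, 100)
        sheet[[col]] <- x
      }
      sheet <- cbind(data.frame(biopsy_id = true_scores$biopsy_id,
                                rater_id = pr$rater_id,
                                session = s, stringsAsFactors = FALSE),
                     sheet[, setdiff(names(sheet), "biopsy_id")])
      out[[length(out) + 1L]] <- sheet
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("histo_score_sheet", "data.frame")
    res
  })
}

#' Simulate data under a proportional-odds (cumulative logit) model
#'
#' Draws \eqn{x_i \sim N(0, x_{sd})} and samples the ordinal response from
#' \eqn{P(Y \le k \mid x) = \mathrm{logistic}(\theta_k - \beta x)}, the
#' parameterization under which \eqn{e^\beta > 1} means larger \eqn{x}
#' favors higher categories.
#'
#' @param beta True regression coefficient (log odds ratio).
#' @param n Number of observations.
#' @param k_categories Number of ordinal categories (\eqn{\ge 2}).
#' @param thresholds Strictly increasing cutpoints, length
#'   `k_categories - 1`.
#' @param x_sd Standard deviation of the predictor.
#' @param seed Integer seed.
#' @return A list with numeric `x` and integer `y` in
#'   `0:(k_categories - 1)`.
#' @examples
#' d <- simulate_proportional_odds_data(log(2), 500, 2, 0, x_sd = 2, seed = 1)
#' table(d$y)
#' @export
simulate_proportional_odds_data <- function(beta, n, k_categories,
                                            thresholds, x_sd = 1, seed) {
  if (!is_count(k_categories, 2L))
    fs_stop("`k_categories` must be an integer >= 2", "invalid_argument")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != k_categories - 1L)
    fs_stop("`thresholds` must have length k_categories - 1",
            "invalid_argument")
  if (k_categories > 2L && any(diff(thresholds) <= 0))
    fs_stop("`thresholds` must be strictly increasing", "invalid_argument")
  if (!is_count(n)) fs_stop("`n` must be an integer >= 1", "invalid_argument")
  with_seed(seed, {
    x <- stats::rnorm(n, 0, x_sd)
    # cumulative P(Y <= k | x), k = 0..K-2; y = #cutpoints below u
    cum <- stats::plogis(outer(thresholds, x, function(t, x) t - beta * x))
    u <- stats::runif(n)
    y <- colSums(cum < rep(u, each = length(thresholds)))
    list(x = x, y = as.integer(y))
  })
}
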