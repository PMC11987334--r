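# Cohen's kappa and the standard agreement bands.

#' Cohen's kappa between two raters
#'
#' Unweighted kappa from the cross-tabulation over the union of observed
#' categories: \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with expected
#' agreement \eqn{p_e} from the product of the marginals.
#'
#' @param r1,r2 Equal-length categorical vectors (factor, character or
#'   numeric codes) of length \eqn{\ge 2}.
#' @return An object of class `kappa_result`: list with `kappa`,
#'   `p_observed`, `p_expected`, `band` (see [agreement_band()]), `n`.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))$kappa  # 0
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2))
    fs_stop("`r1` and `r2` must have equal length", "shape_error")
  if (length(r1) < 2L)
    fs_stop("need at least 2 paired ratings", "invalid_argument")
  levs <- sort(unique(c(as.character(r1), as.character(r2))))
  tab <- table(factor(as.character(r1), levels = levs),
               factor(as.character(r2), levels = levs))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12)
    fs_stop("both raters are constant on the same category; kappa undefined",
            "degenerate_agreement_error")
  k <- (p_o - p_e) / (1 - p_e)
  structure(list(kappa = k, p_observed = p_o, p_expected = p_e,
                 band = agreement_band(k), n = as.integer(n)),
            class = "kappa_result")
}

#' Agreement band for a kappa value
#'
#' Standard six-band interpretation: \eqn{\kappa \le 0} no agreement,
#' 0.01-0.20 none to slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-1.00 almost perfect.  Band boundaries are
#' inclusive of their upper endpoint, and the gap \eqn{(0, 0.01)} is
#' assigned to "none to slight".
#'
#' @param kappa A kappa value (\eqn{\le 1}).
#' @return Character band label.
#' @export
agreement_band <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa))
    fs_stop("`kappa` must be a single number", "invalid_argument")
  if (kappa > 1) fs_stop("kappa cannot exceed 1", "invalid_argument")
  if (kappa <= 0) "no agreement"
  else if (kappa <= 0.20) "none to slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s), p_o = %.3f, p_e = %.3f, n = %d\n",
              x$kappa, x$band, x$p_observed, x$p_expected, x$n))
  invisible(x)
}

#' Inter- and intra-rater agreement table for score sheets
#'
#' Computes, per histological parameter, the inter-rater kappa (session 1
#' scores of the two raters) and each rater's intra-rater kappa (session 1
#' vs session 2).  Continuous parameters are discretized into quintile
#' bins (computed on the pooled values) before kappa.  Parameters on which
#' a comparison is degenerate (both raters constant) are reported as NA.
#'
#' @param sheets A `histo_score_sheet` data.frame from
#'   [simulate_rater_scores()] (or real data in the same layout).
#' @return A data.frame with one row per parameter: `parameter`, `type`,
#'   `kappa_inter`, `band_inter`, `kappa_intra_r1`, `kappa_intra_r2`.
#' @export
rater_agreement <- function(sheets) {
  p <- histo_params()
  raters <- sort(unique(sheets$rater_id))
  if (length(raters) != 2L)
    fs_stop("score sheets must contain exactly 2 raters", "schema_error")
  sessions <- sort(unique(sheets$session))
  get <- function(rater, session, col) {
    s <- sheets[sheets$rater_id == rater & sheets$session == session, ]
    s[order(s$biopsy_id), col]
  }
  safe_kappa <- function(a, b) {
    tryCatch(cohens_kappa(a, b)$kappa,
             degenerate_agreement_error = function(e) NA_real_)
  }
  rows <- lapply(c(p$binary, p$continuous, p$ordinal), function(col) {
    type <- if (col %in% p$binary) "binary"
            else if (col %in% p$continuous) "continuous" else "ordinal"
    prep <- identity
    if (type == "continuous") {
      pooled <- sheets[[col]]
      br <- unique(stats::quantile(pooled, seq(0, 1, 0.2)))
      prep <- function(x) if (length(br) < 3) rep(1L, length(x)) else
        findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
    }
    k_inter <- safe_kappa(prep(get(raters[1], sessions[1], col)),
                          prep(get(raters[2], sessions[1], col)))
    k_r1 <- k_r2 <- NA_real_
    if (length(sessions) >= 2L) {
      k_r1 <- safe_kappa(prep(get(raters[1], sessions[1], col)),
                         prep(get(raters[1], sessions[2], col)))
      k_r2 <- safe_kappa(prep(get(raters[2], sessions[1], col)),
                         prep(get(raters[2], sessions[2], col)))
    }
    data.frame(parameter = col, type = type,
               kappa_inter = k_inter,
               band_inter = if (is.na(k_inter)) NA_character_ else
                 agreement_band(k_inter),
               kappa_intra_r1 = k_r1, kappa_intra_r2 = k_r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
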