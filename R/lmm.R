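# Per-week change via a random-intercept + random-slope mixed model.
#
#   y_ij = b0 + b1 * week_ij + u0_i + u1_i * week_ij + e_ij
# with independent random effects (diagonal G: no intercept-slope
# covariance) fitted by restricted maximum likelihood.  The two variance
# ratios g0 = var(u0)/var(e) and g1 = var(u1)/var(e) are optimized
# directly (box-constrained at 0, so a negative-variance iterate is
# impossible by construction); beta and the residual variance are profiled
# out in closed form per evaluation.

#' Fit the per-week slope mixed model
#'
#' @param values Numeric response vector (one histological measurement per
#'   row).
#' @param weeks Visit week of each measurement.
#' @param patient_ids Participant id of each measurement; at least two
#'   patients must contribute at least two distinct-week measurements.
#' @return An object of class `slope_result`: list with `slope_per_week`,
#'   `intercept`, `se_slope`, `p` (Wald), `var_intercept`, `var_slope`,
#'   `var_resid`, `reml_logLik`, `n`, `n_patients`.
#' @examples
#' w <- rep(c(0, 24, 52), 4)
#' id <- rep(1:4, each = 3)
#' fit_slope_lmm(2 + 0.1 * w, w, id)$slope_per_week  # 0.1
#' @export
fit_slope_lmm <- function(values, weeks, patient_ids) {
  y <- as.numeric(values); w <- as.numeric(weeks)
  id <- as.character(patient_ids)
  if (length(y) != length(w) || length(y) != length(id))
    fs_stop("`values`, `weeks`, `patient_ids` must have equal length",
            "shape_error")
  if (length(unique(w)) < 2L)
    fs_stop("all weeks identical: slope is not identifiable",
            "rank_deficiency_error")
  split_idx <- split(seq_along(y), id)
  multi <- vapply(split_idx, function(ii) length(unique(w[ii])) >= 2L,
                  logical(1))
  if (sum(multi) < 2L)
    fs_stop("need >= 2 patients with >= 2 timepoints each",
            "invalid_argument")
  N <- length(y); p <- 2L

  blocks <- lapply(split_idx, function(ii) {
    list(X = cbind(1, w[ii]), y = y[ii], w = w[ii], n = length(ii))
  })

  profile <- function(g) {                 # g = (g0, g1) >= 0
    A <- matrix(0, 2, 2); b <- numeric(2)
    ldR <- 0
    Rinv <- vector("list", length(blocks))
    for (i in seq_along(blocks)) {
      bl <- blocks[[i]]
      R <- diag(bl$n) + g[1] + g[2] * tcrossprod(bl$w)
      ch <- chol(R)
      ldR <- ldR + 2 * sum(log(diag(ch)))
      Ri <- chol2inv(ch)
      Rinv[[i]] <- Ri
      A <- A + crossprod(bl$X, Ri %*% bl$X)
      b <- b + crossprod(bl$X, Ri %*% bl$y)
    }
    beta <- solve(A, b)
    q <- 0
    for (i in seq_along(blocks)) {
      bl <- blocks[[i]]
      r <- bl$y - bl$X %*% beta
      q <- q + crossprod(r, Rinv[[i]] %*% r)
    }
    q <- as.numeric(q)
    sigma2 <- q / (N - p)
    crit <- ldR + (N - p) * log(pmax(sigma2, 1e-12)) +
      determinant(A, logarithm = TRUE)$modulus[1]
    list(crit = crit, beta = as.vector(beta), sigma2 = sigma2, A = A)
  }

  # optimize the log variance ratios (scale-free, derivative-free); a
  # ratio driven to the lower edge of the search region is reported as a
  # zero variance component
  w2 <- mean(w^2)
  obj <- function(lg) profile(exp(pmin(pmax(lg, -30), 30)))$crit
  opt <- stats::optim(log(c(1, 1 / max(w2, 1))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  g_hat <- exp(pmin(pmax(opt$par, -30), 30))
  g_hat[g_hat < 1e-10] <- 0
  pr <- profile(g_hat)
  vb <- pr$sigma2 * solve(pr$A)            # Var(beta) = sigma2 * A^{-1}
  se1 <- sqrt(vb[2, 2])
  z <- if (se1 > 0) pr$beta[2] / se1 else Inf
  # REML log-likelihood up to the usual additive constant
  reml_ll <- -0.5 * (pr$crit + (N - p) * (1 + log(2 * pi)))
  structure(list(slope_per_week = pr$beta[2], intercept = pr$beta[1],
                 se_slope = se1, p = 2 * stats::pnorm(-abs(z)),
                 var_intercept = g_hat[1] * pr$sigma2,
                 var_slope = g_hat[2] * pr$sigma2,
                 var_resid = pr$sigma2,
                 reml_logLik = reml_ll,
                 n = N, n_patients = length(blocks)),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("per-week slope = %.4f (SE %.4f, p = %.4g)\n",
              x$slope_per_week, x$se_slope, x$p))
  cat(sprintf("variances: intercept %.4g, slope %.4g, residual %.4g (%d patients, %d obs)\n",
              x$var_intercept, x$var_slope, x$var_resid, x$n_patients, x$n))
  invisible(x)
}

#' Per-week change table for every histological parameter
#'
#' Averages each parameter over raters and sessions per biopsy, then fits
#' [fit_slope_lmm()] of the averaged score on visit week with the
#' cohort's patient grouping.
#'
#' @param sheets A `histo_score_sheet` data.frame.
#' @param biopsy_meta data.frame with columns `biopsy_id`, `patient_id`,
#'   `week`.
#' @return data.frame: `parameter`, `slope_per_week`, `se`, `p`, `reason`.
#' @export
slope_table <- function(sheets, biopsy_meta) {
  p <- histo_params()
  params <- c(p$binary, p$continuous, p$ordinal)
  agg <- stats::aggregate(sheets[params],
                          by = list(biopsy_id = sheets$biopsy_id), mean)
  m <- merge(agg, biopsy_meta, by = "biopsy_id")
  rows <- lapply(params, function(col) {
    res <- tryCatch(fit_slope_lmm(m[[col]], m$week, m$patient_id),
                    fibroscore_error = function(e) e)
    if (inherits(res, "slope_result"))
      data.frame(parameter = col, slope_per_week = res$slope_per_week,
                 se = res$se_slope, p = res$p, reason = NA_character_,
                 stringsAsFactors = FALSE)
    else
      data.frame(parameter = col, slope_per_week = NA_real_, se = NA_real_,
                 p = NA_real_, reason = conditionMessage(res),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
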