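# Proportional-odds (cumulative logit) ordinal regression.
#
# Model: P(Y <= k | x) = logistic(theta_k - beta * x), so exp(beta) > 1
# means a unit increase in x multiplies the odds of *exceeding* any
# cutpoint -- i.e. of a higher category -- by exp(beta).  Maximum
# likelihood by full Newton iterations with analytic gradient and Hessian,
# step-halving, convergence at gradient norm < 1e-8; Wald inference from
# the observed information.

#' Fit a single-predictor proportional-odds model
#'
#' @param y Ordinal response: integer/numeric codes or ordered factor with
#'   at least 2 observed categories.
#' @param x Numeric predictor.
#' @return An object of class `or_result`: list with `beta`,
#'   `or = exp(beta)`, `se`, `ci_low`, `ci_high` (95% Wald), `p`,
#'   `thresholds` (increasing cutpoints), `converged`, `n`, `k`.
#' @examples
#' d <- simulate_proportional_odds_data(log(2), 2000, 2, 0, x_sd = 2,
#'                                      seed = 1)
#' fit_proportional_odds(d$y, d$x)$or  # close to 2
#' @export
fit_proportional_odds <- function(y, x) {
  if (length(y) != length(x))
    fs_stop("`y` and `x` must have equal length", "shape_error")
  yf <- factor(y)                        # sorted unique codes -> 1..K
  K <- nlevels(yf)
  if (K < 2L)
    fs_stop("response has fewer than 2 observed categories",
            "invalid_argument")
  n <- length(x)
  if (n <= K)
    fs_stop("too few observations for the number of categories",
            "invalid_argument")
  k <- as.integer(yf)
  x <- as.numeric(x)

  loglik <- function(theta, beta) {
    zu <- ifelse(k < K, theta[pmin(k, K - 1L)] - beta * x, Inf)
    zl <- ifelse(k > 1L, theta[pmax(k - 1L, 1L)] - beta * x, -Inf)
    sum(log(pmax(stats::plogis(zu) - stats::plogis(zl), 1e-300)))
  }

  score_hess <- function(theta, beta) {
    m <- K                               # K-1 thresholds + beta
    g <- numeric(m); H <- matrix(0, m, m)
    Fl <- function(z) stats::plogis(z)
    fl <- function(z) { p <- stats::plogis(z); p * (1 - p) }
    dfl <- function(z) { p <- stats::plogis(z); p * (1 - p) * (1 - 2 * p) }
    for (cat in 1:K) {
      idx <- which(k == cat)
      if (!length(idx)) next
      xi <- x[idx]
      has_u <- cat < K; has_l <- cat > 1L
      zu <- if (has_u) theta[cat] - beta * xi else rep(Inf, length(idx))
      zl <- if (has_l) theta[cat - 1L] - beta * xi else rep(-Inf, length(idx))
      P <- pmax(Fl(zu) - Fl(zl), 1e-12)
      fu <- if (has_u) fl(zu) else 0; fL <- if (has_l) fl(zl) else 0
      dfu <- if (has_u) dfl(zu) else 0; dfL <- if (has_l) dfl(zl) else 0
      huu <- dfu / P - fu^2 / P^2
      hll <- -dfL / P - fL^2 / P^2
      hul <- fu * fL / P^2
      if (has_u) {
        g[cat] <- g[cat] + sum(fu / P)
        H[cat, cat] <- H[cat, cat] + sum(huu)
        H[cat, m] <- H[cat, m] - sum(xi * (huu + hul))
      }
      if (has_l) {
        g[cat - 1L] <- g[cat - 1L] - sum(fL / P)
        H[cat - 1L, cat - 1L] <- H[cat - 1L, cat - 1L] + sum(hll)
        H[cat - 1L, m] <- H[cat - 1L, m] - sum(xi * (hll + hul))
      }
      if (has_u && has_l) {
        H[cat, cat - 1L] <- H[cat, cat - 1L] + sum(hul)
        H[cat - 1L, cat] <- H[cat - 1L, cat] + sum(hul)
      }
      g[m] <- g[m] - sum(xi * (fu - fL) / P)
      H[m, m] <- H[m, m] + sum(xi^2 * (huu + 2 * hul + hll))
    }
    H[m, 1:(m - 1L)] <- H[1:(m - 1L), m]
    list(g = g, H = H)
  }

  # start: empirical cumulative logits at beta = 0
  cum <- cumsum(tabulate(k, K))[1:(K - 1L)] / n
  theta <- stats::qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6))
  beta <- 0
  ll <- loglik(theta, beta)
  converged <- FALSE
  for (iter in 1:100) {
    sh <- score_hess(theta, beta)
    if (sqrt(sum(sh$g^2)) < 1e-8) { converged <- TRUE; break }
    step <- tryCatch(solve(-sh$H, sh$g), error = function(e)
      solve(-sh$H + diag(1e-8, K), sh$g))
    size <- 1
    repeat {
      th_new <- theta + size * step[1:(K - 1L)]
      b_new <- beta + size * step[K]
      ok <- (K == 2L || all(diff(th_new) > 0))
      if (ok) {
        ll_new <- loglik(th_new, b_new)
        if (ll_new >= ll - 1e-12) break
      }
      size <- size / 2
      if (size < 1e-10) { th_new <- theta; b_new <- beta; ll_new <- ll; break }
    }
    theta <- th_new; beta <- b_new; ll <- ll_new
    if (abs(beta) > 30)
      fs_stop(paste("fitted log odds ratio is diverging: the data are",
                    "(quasi-)separated; consider pooling categories or",
                    "penalized estimation"), "separation_error")
  }
  sh <- score_hess(theta, beta)
  if (sqrt(sum(sh$g^2)) < 1e-6) converged <- TRUE
  info <- -sh$H
  vcov <- tryCatch(solve(info), error = function(e)
    fs_stop("observed information is singular", "separation_error"))
  se <- sqrt(vcov[K, K])
  z <- beta / se
  structure(list(beta = beta, or = exp(beta), se = se,
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 thresholds = theta, converged = converged,
                 logLik = ll, n = n, k = K),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("proportional odds: OR = %.3f [%.3f, %.3f], p = %.4g (n = %d, %d categories)\n",
              x$or, x$ci_low, x$ci_high, x$p, x$n, x$k))
  invisible(x)
}

#' Odds-ratio table: each histological parameter against a predictor
#'
#' Fits one proportional-odds model per parameter with the per-biopsy
#' predictor (mRSS or Fibrosis Score) as the explanatory variable, using
#' every (rater, session) score row as an observation.  Binary parameters
#' reduce to ordinary logistic regression; continuous parameters are
#' rounded to integers and fitted as reported-scale ordinal responses.  No
#' multiplicity correction is applied.  Parameters whose fit is degenerate
#' (constant response, separation) are reported as NA with the reason.
#'
#' @param sheets A `histo_score_sheet` data.frame.
#' @param predictor Named numeric vector keyed by `biopsy_id`, or a
#'   data.frame with columns `biopsy_id` and `value`.
#' @return A data.frame with one row per parameter: `parameter`, `type`,
#'   `n`, `or`, `ci_low`, `ci_high`, `p`, `beta`, `reason`.
#' @export
odds_ratio_table <- function(sheets, predictor) {
  if (is.data.frame(predictor))
    predictor <- stats::setNames(predictor$value, predictor$biopsy_id)
  missing <- setdiff(unique(sheets$biopsy_id), names(predictor))
  if (length(missing))
    fs_stop(paste("no predictor value for biopsy:",
                  paste(missing, collapse = ", ")), "join_error")
  x <- as.numeric(predictor[sheets$biopsy_id])
  p <- histo_params()
  rows <- lapply(c(p$binary, p$continuous, p$ordinal), function(col) {
    type <- if (col %in% p$binary) "binary"
            else if (col %in% p$continuous) "continuous" else "ordinal"
    y <- sheets[[col]]
    if (type == "continuous") y <- round(y)
    res <- tryCatch(fit_proportional_odds(y, x),
                    fibroscore_error = function(e) e)
    if (inherits(res, "or_result")) {
      data.frame(parameter = col, type = type, n = res$n, or = res$or,
                 ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
                 beta = res$beta, reason = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(parameter = col, type = type, n = length(y),
                 or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, beta = NA_real_,
                 reason = conditionMessage(res), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
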