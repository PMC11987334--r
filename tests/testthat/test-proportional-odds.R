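test_that("two-category fits equal an independent logistic MLE", {
  for (s in 1:3) {
    d <- simulate_proportional_odds_data(0.4, 800, 2, 0.3, x_sd = 1.5,
                                         seed = s)
    mine <- fit_proportional_odds(d$y, d$x)
    ref <- stats::glm(d$y ~ d$x, family = stats::binomial())
    expect_lt(abs(mine$beta - unname(stats::coef(ref)[2])), 1e-6)
    expect_lt(abs(mine$thresholds + unname(stats::coef(ref)[1])), 1e-6)
  }
})

test_that("multi-category fits agree with an independent ordinal solver", {
  skip_if_not_installed("MASS")
  d <- simulate_proportional_odds_data(0.3, 2000, 5, c(-1.5, -0.5, 0.5, 1.5),
                                       x_sd = 1, seed = 4)
  mine <- fit_proportional_odds(d$y, d$x)
  ref <- MASS::polr(factor(d$y) ~ d$x, method = "logistic", Hess = TRUE)
  expect_lt(abs(mine$beta - unname(stats::coef(ref))), 1e-4)
  expect_equal(unname(mine$thresholds), unname(ref$zeta), tolerance = 1e-4)
})

test_that("a permuted predictor yields an odds ratio near 1", {
  d <- simulate_proportional_odds_data(log(2), 5000, 3, c(-0.5, 0.5),
                                       x_sd = 1, seed = 6)
  set.seed(1)
  f <- fit_proportional_odds(d$y, sample(d$x))
  expect_gt(f$or, 0.93); expect_lt(f$or, 1.07)
})

test_that("confidence interval brackets the estimate; sign convention holds", {
  d <- simulate_proportional_odds_data(log(2), 3000, 2, 0, x_sd = 2,
                                       seed = 7)
  f <- fit_proportional_odds(d$y, d$x)
  expect_lt(f$ci_low, f$or); expect_gt(f$ci_high, f$or)
  expect_gt(f$or, 1)     # larger x favors higher categories by construction
  expect_true(f$converged)
})

test_that("separated data raise a separation error with guidance", {
  x <- c(rnorm(50, -3), rnorm(50, 3))
  y <- as.integer(x > 0)
  expect_error(fit_proportional_odds(y, x), class = "separation_error")
})

test_that("degenerate responses are rejected", {
  expect_error(fit_proportional_odds(rep(1, 50), rnorm(50)),
               class = "invalid_argument")
  expect_error(fit_proportional_odds(1:3, 1:4), class = "shape_error")
})

test_that("the odds-ratio table is complete, typed and translation-invariant", {
  tr <- mk_truth(150, seed = 9)
  pr <- list(rater_profile("R1", 0.05, c(0.05, 0.9, 0.05), 0.05, 0),
             rater_profile("R2", 0.05, c(0.05, 0.9, 0.05), 0.05, 0))
  sheets <- simulate_rater_scores(tr, pr, seed = 10)
  pred <- stats::setNames(15 + 25 * tr$severity, tr$biopsy_id)
  tab <- odds_ratio_table(sheets, pred)
  expect_equal(nrow(tab), 16L)
  expect_true(all(!is.na(tab$or) | !is.na(tab$reason)))
  ok <- !is.na(tab$or)
  expect_true(all(tab$ci_low[ok] <= tab$or[ok] & tab$or[ok] <= tab$ci_high[ok]))
  # shifting the predictor by a constant leaves every beta unchanged
  tab2 <- odds_ratio_table(sheets, pred + 100)
  expect_equal(tab2$beta, tab$beta, tolerance = 1e-6)
  # unjoinable biopsies are reported
  expect_error(odds_ratio_table(sheets, pred[-1]), class = "join_error")
})

test_that("planted effect directions are recovered across parameter types", {
  # severity raises every fibrosis-linked parameter, so with a predictor
  # increasing in severity all informative ORs must land above 1
  tr <- mk_truth(500, seed = 12)
  pr <- list(rater_profile("R1", 0.05, c(0.1, 0.8, 0.1), 0.05, 0),
             rater_profile("R2", 0.05, c(0.1, 0.8, 0.1), 0.05, 0))
  sheets <- simulate_rater_scores(tr, pr, sessions = 1, seed = 13)
  pred <- stats::setNames(15 + 25 * tr$severity + stats::rnorm(500, 0, 1),
                          tr$biopsy_id)
  tab <- odds_ratio_table(sheets, pred)
  up <- c("sc_fat_loss_widened_septa", "thickened_intima",
          "eccrine_entrapment", "telangiectasia", "hyalinized_collagen",
          "trichrome", "asma")
  expect_true(all(tab$or[tab$parameter %in% up] > 1))
  expect_lt(tab$or[tab$parameter == "mean_epidermal_thickness_um"], 1)
})
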