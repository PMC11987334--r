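test_that("penalty grid follows the log-spacing law", {
  g <- make_lambda_grid()
  expect_equal(g$n, 16L)
  expect_equal(g$values[1], 1e-5)
  expect_equal(g$values[16], 1e3)
  expect_equal(unique(round(diff(log10(g$values)), 10)), 8 / 15)
  expect_equal(make_lambda_grid(2, -1, 1)$values, c(0.1, 10))
  expect_error(make_lambda_grid(1), class = "invalid_argument")
})

test_that("unpenalized fit matches the normal-equations oracle", {
  d <- mk_linear_cohort(n_biopsy = 10, patches = 50, D = 5, seed = 1)
  m <- fit_lasso_patchwise(d$qifs, d$labels, 0)
  X <- do.call(rbind, lapply(d$qifs, function(q) q$values))
  y <- rep(d$labels, each = 50)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2,
              apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))), "/")
  ols <- stats::coef(stats::lm(y ~ Xs))
  expect_equal(unname(m$coefficients), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(m$intercept, unname(ols[1]), tolerance = 1e-10)
})

test_that("strong penalty zeroes all coefficients and predicts the mean mRSS", {
  d <- mk_linear_cohort(n_biopsy = 8, patches = 30, D = 6, seed = 2)
  m <- fit_lasso_patchwise(d$qifs, d$labels, 1e3)
  expect_true(all(m$coefficients == 0))
  expect_equal(m$intercept, mean(rep(d$labels, each = 30)))
  s <- predict_fibrosis_score(m, d$qifs[[3]])
  expect_equal(s$score, m$intercept)
})

test_that("solutions agree with an independent lasso solver", {
  skip_if_not_installed("glmnet")
  d <- mk_linear_cohort(n_biopsy = 10, patches = 40, D = 8, seed = 3)
  X <- do.call(rbind, lapply(d$qifs, function(q) q$values))
  y <- rep(d$labels, each = 40)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2,
              apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))), "/")
  for (lam in c(0.05, 0.5, 2)) {
    mine <- fit_lasso_patchwise(d$qifs, d$labels, lam)
    ref <- glmnet::glmnet(Xs, y, alpha = 1, lambda = lam,
                          standardize = FALSE, thresh = 1e-12)
    expect_equal(unname(mine$coefficients),
                 as.vector(stats::coef(ref))[-1], tolerance = 1e-5)
  }
})

test_that("identical labels give a pure-intercept model", {
  d <- mk_linear_cohort(n_biopsy = 5, patches = 20, D = 4, seed = 4)
  labels <- stats::setNames(rep(30, 5), names(d$labels))
  m <- fit_lasso_patchwise(d$qifs, labels, 0.1)
  expect_equal(m$intercept, 30)
  expect_true(all(m$coefficients == 0))
})

test_that("constant features are dropped with a warning, coefficient zero", {
  d <- mk_linear_cohort(n_biopsy = 5, patches = 20, D = 4, seed = 5)
  d$qifs <- lapply(d$qifs, function(q) { q$values[, 2] <- 7; q })
  expect_warning(m <- fit_lasso_patchwise(d$qifs, d$labels, 0.01),
                 "constant feature")
  expect_equal(unname(m$coefficients[2]), 0)
})

test_that("nonzero-coefficient count is nonincreasing along the grid", {
  d <- mk_linear_cohort(n_biopsy = 10, patches = 30, D = 8, seed = 6)
  nz <- vapply(make_lambda_grid()$values, function(l)
    sum(fit_lasso_patchwise(d$qifs, d$labels, l)$coefficients != 0),
    numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("scores are patch-prediction means, invariant to row permutation", {
  d <- mk_linear_cohort(n_biopsy = 6, patches = 25, D = 5, seed = 7)
  m <- fit_lasso_patchwise(d$qifs, d$labels, 0.05)
  q <- d$qifs[[1]]
  s <- predict_fibrosis_score(m, q)
  expect_equal(s$score, mean(s$patch_predictions))
  qp <- q; qp$values <- q$values[sample(nrow(q$values)), ]
  expect_equal(predict_fibrosis_score(m, qp)$score, s$score)
  # dimension mismatch is a typed shape error
  qbad <- q; qbad$values <- q$values[, 1:3]; qbad$D <- 3L
  expect_error(predict_fibrosis_score(m, qbad), class = "shape_error")
})

test_that("missing biopsy labels raise a join error", {
  d <- mk_linear_cohort(n_biopsy = 4, patches = 10, D = 3, seed = 8)
  expect_error(fit_lasso_patchwise(d$qifs, d$labels[-2], 0.1),
               class = "join_error")
})
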