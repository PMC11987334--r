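test_that("two patients give exactly two leave-one-patient-out folds", {
  d <- mk_linear_cohort(n_biopsy = 6, patches = 15, D = 4, seed = 1)
  groups <- stats::setNames(rep(c("pA", "pB"), each = 3), names(d$labels))
  cv <- select_lambda_grouped_cv(d$qifs, d$labels, groups,
                                 make_lambda_grid(4, -3, 1), seed = 1)
  expect_length(unique(cv$folds), 2L)
  # each biopsy is held out exactly once per lambda
  tab <- table(cv$cv_table$biopsy_id, cv$cv_table$lambda)
  expect_true(all(tab == 1))
})

test_that("no CV fold ever shares a patient between train and test", {
  d <- mk_linear_cohort(n_biopsy = 24, patches = 10, D = 4, seed = 2)
  groups <- stats::setNames(rep(sprintf("p%02d", 1:12), each = 2),
                            names(d$labels))
  cv <- select_lambda_grouped_cv(d$qifs, d$labels, groups,
                                 make_lambda_grid(4, -3, 1), seed = 3)
  expect_length(unique(cv$folds), 5L)       # 12 patients -> 5 grouped folds
  # fold test sets partition the patients
  expect_setequal(names(cv$folds), sprintf("p%02d", 1:12))
  held_patients <- tapply(groups[cv$cv_table$biopsy_id], cv$cv_table$fold,
                          function(p) sort(unique(p)))
  expect_equal(sort(unlist(held_patients, use.names = FALSE)),
               sort(unique(groups)))
})

test_that("exact CV-error ties resolve to the larger penalty", {
  d <- mk_linear_cohort(n_biopsy = 4, patches = 10, D = 3, seed = 4)
  labels <- stats::setNames(rep(30, 4), names(d$labels))  # zero-signal
  groups <- stats::setNames(paste0("p", 1:4), names(d$labels))
  # with constant labels every penalty fits the same intercept-only model
  cv <- select_lambda_grouped_cv(d$qifs, labels, groups,
                                 make_lambda_grid(6, -3, 3), seed = 1)
  expect_equal(cv$lambda, 1e3)
})

test_that("a planted linear signal with excess noise features selects an interior penalty", {
  # with more features than informative directions and few patches, the
  # unpenalized end overfits and the fully penalized end underfits, so
  # cross-validation should land strictly inside the grid
  interior <- vapply(1:20, function(s) {
    d <- mk_linear_cohort(n_biopsy = 12, patches = 5, D = 40, noise = 3,
                          seed = 100 + s)
    cv <- select_lambda_grouped_cv(d$qifs, d$labels, d$groups, seed = s)
    g <- make_lambda_grid()$values
    cv$lambda > g[1] && cv$lambda < g[16]
  }, logical(1))
  expect_gte(mean(interior), 0.8)
})

test_that("single-patient cohorts are rejected", {
  d <- mk_linear_cohort(n_biopsy = 3, patches = 10, D = 3, seed = 5)
  groups <- stats::setNames(rep("p1", 3), names(d$labels))
  expect_error(select_lambda_grouped_cv(d$qifs, d$labels, groups, seed = 1),
               class = "invalid_argument")
})

test_that("the fitted model object exposes the standard methods", {
  d <- mk_linear_cohort(n_biopsy = 8, patches = 20, D = 5, seed = 6)
  m <- fit_fibrosis(d$qifs, d$labels, d$groups,
                    make_lambda_grid(6, -4, 2), seed = 1)
  expect_s3_class(m, "fibrosis_model")
  expect_named(coef(m)[1], "(Intercept)")
  expect_output(print(m), "lasso model")
  expect_output(print(summary(m)), "cross-validated MSE")
  s <- predict(m, d$qifs[[1]])
  expect_s3_class(s, "fibrosis_score")
  r <- evaluate_scores(lapply(d$qifs, predict_fibrosis_score, model = m),
                       d$labels)
  expect_s3_class(r, "correlation_result")
  expect_gt(r$rho, 0)
})
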