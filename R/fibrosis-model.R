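# The Fibrosis Score model.
#
# Training rows are image patches, each carrying its biopsy's mRSS label;
# features are standardized to mean 0, sd 1 on the training rows; the
# coefficients minimize
#     (1/2) * mean((y - b0 - X b)^2) + lambda * sum(|b|)
# with an unpenalized intercept, solved by cyclic coordinate descent
# (soft-thresholding updates; convergence when the largest coefficient
# change in a sweep is below 1e-7, at most 10,000 sweeps).  The penalty is
# chosen from a 16-point log-spaced grid by grouped (leave-patients-out)
# cross-validation of the *biopsy-level* score -- the mean of the patch
# predictions -- so folds never split a patient.  The per-biopsy Fibrosis
# Score of a fitted model is the arithmetic mean of its patch predictions.

#' Logarithmically spaced penalty grid
#'
#' @param n Number of grid points (default 16).
#' @param log10_min,log10_max Base-10 exponents of the endpoints
#'   (defaults -5 and +3, i.e. 1e-5 ... 1e3).
#' @return An object of class `lambda_grid`: list with increasing
#'   `values`, `n`, `log10_min`, `log10_max`.
#' @examples
#' g <- make_lambda_grid()
#' range(g$values)           # 1e-5, 1e3
#' @export
make_lambda_grid <- function(n = 16L, log10_min = -5, log10_max = 3) {
  if (!is_count(n, 2L)) fs_stop("`n` must be an integer >= 2",
                                "invalid_argument")
  if (log10_min >= log10_max)
    fs_stop("`log10_min` must be < `log10_max`", "invalid_argument")
  j <- seq_len(n) - 1
  structure(list(values = 10^(log10_min + (log10_max - log10_min) * j / (n - 1)),
                 n = as.integer(n), log10_min = log10_min,
                 log10_max = log10_max),
            class = "lambda_grid")
}

# pool a list of qif_matrix objects into one design: rows = patches
#' @keywords internal
pool_patches <- function(qifs, labels) {
  if (inherits(qifs, "qif_matrix")) qifs <- list(qifs)
  ids <- vapply(qifs, function(q) q$biopsy_id, character(1))
  if (is.data.frame(labels)) {
    lv <- labels$label %||% labels$mrss
    labels <- stats::setNames(lv, labels$biopsy_id)
  }
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    fs_stop(paste("no label for biopsy:", paste(missing, collapse = ", ")),
            "join_error")
  X <- do.call(rbind, lapply(qifs, function(q) q$values))
  nper <- vapply(qifs, function(q) nrow(q$values), integer(1))
  y <- rep(as.numeric(labels[ids]), times = nper)
  list(X = X, y = y, biopsy = rep(ids, times = nper), ids = ids,
       labels = as.numeric(labels[ids]))
}

# cyclic coordinate descent in the covariance formulation: with the Gram
# matrix G = X'X/n and c = X'y/n precomputed, each coefficient update is
# O(D) regardless of the number of training rows
#' @keywords internal
lasso_cd <- function(Xs, yc, lambda, beta0 = NULL,
                     tol = 1e-7, max_sweeps = 10000L,
                     gram = NULL, xty = NULL) {
  n <- nrow(Xs); D <- ncol(Xs)
  G <- if (is.null(gram)) crossprod(Xs) / n else gram
  cvec <- if (is.null(xty)) as.vector(crossprod(Xs, yc)) / n else xty
  beta <- if (is.null(beta0)) numeric(D) else beta0
  Gb <- as.vector(G %*% beta)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(D)) {
      bj <- beta[j]
      if (G[j, j] < 1e-12) next          # dropped/constant column
      rho <- cvec[j] - Gb[j] + bj        # G[j,j] == 1 on standardized cols
      bn <- sign(rho) * max(abs(rho) - lambda, 0)
      if (bn != bj) {
        Gb <- Gb + G[, j] * (bn - bj)
        beta[j] <- bn
        delta <- max(delta, abs(bn - bj))
      }
    }
    if (delta < tol) break
  }
  beta
}

#' Fit the patch-level lasso regression at a fixed penalty
#'
#' Pools all patches (each labeled with its biopsy's mRSS), standardizes
#' the features on the training rows, and solves the lasso by coordinate
#' descent.  Constant features are dropped with a warning and reported
#' with coefficient 0.
#'
#' @param qifs A `qif_matrix` or list of them (one per biopsy).
#' @param labels Per-biopsy mRSS: named numeric vector keyed by
#'   `biopsy_id`, or a data.frame with columns `biopsy_id` and
#'   `label`/`mrss`.
#' @param lambda Penalty (\eqn{\ge 0}).
#' @return An object of class `fibrosis_model`; see [fit_fibrosis()].
#' @export
fit_lasso_patchwise <- function(qifs, labels, lambda) {
  if (!is.numeric(lambda) || lambda < 0)
    fs_stop("`lambda` must be >= 0", "invalid_argument")
  d <- pool_patches(qifs, labels)
  fit_lasso_raw(d$X, d$y, lambda)
}

#' @keywords internal
fit_lasso_raw <- function(X, y, lambda) {
  lasso_path(X, y, lambda)[[1]]
}

# fit a decreasing sequence of penalties on one training set with shared
# standardization, one Gram computation and warm starts
#' @keywords internal
lasso_path <- function(X, y, lambdas) {
  D <- ncol(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))   # population sd
  dropped <- which(scl < 1e-12)
  if (length(dropped)) {
    warning(sprintf("%d constant feature(s) dropped (coefficient 0)",
                    length(dropped)))
    scl[dropped] <- 1
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (length(dropped)) Xs[, dropped] <- 0
  b0 <- mean(y)
  yc <- y - b0
  n <- nrow(Xs)
  G <- crossprod(Xs) / n
  cvec <- as.vector(crossprod(Xs, yc)) / n
  ord <- order(lambdas, decreasing = TRUE)    # strong-to-weak, warm starts
  beta <- NULL
  fits <- vector("list", length(lambdas))
  for (i in ord) {
    beta <- lasso_cd(Xs, yc, lambdas[i], beta0 = beta, gram = G, xty = cvec)
    b <- beta
    if (length(dropped)) b[dropped] <- 0
    fits[[i]] <- structure(
      list(coefficients = stats::setNames(b, colnames(X)),
           intercept = b0, lambda = lambdas[i], center = ctr, scale = scl,
           dropped = dropped, D = D),
      class = "fibrosis_model")
  }
  fits
}

#' @keywords internal
predict_patches <- function(model, values) {
  if (ncol(values) != model$D)
    fs_stop(sprintf("QIF matrix has %d features but model expects %d",
                    ncol(values), model$D), "shape_error")
  Xs <- sweep(sweep(values, 2, model$center), 2, model$scale, "/")
  if (length(model$dropped)) Xs[, model$dropped] <- 0
  as.vector(model$intercept + Xs %*% model$coefficients)
}

#' Select the lasso penalty by grouped (leave-patients-out) CV
#'
#' Folds hold out whole patients: leave-one-patient-out when there are at
#' most 10 patients, otherwise 5 patient-grouped folds from a seeded
#' shuffle.  For each penalty, the model is fitted on the training
#' patches (standardization computed on training rows only) and scored by
#' the squared error of the held-out *biopsy-level* scores against their
#' mRSS labels.  The selected penalty minimizes the mean held-out squared
#' error; ties within 1e-12 resolve to the larger (more parsimonious)
#' penalty.  Train/test patient disjointness is asserted programmatically
#' in every fold.
#'
#' @param qifs List of `qif_matrix` objects.
#' @param labels Per-biopsy labels as in [fit_lasso_patchwise()].
#' @param groups Named character vector mapping `biopsy_id` to patient id.
#' @param grid A [make_lambda_grid()] object.
#' @param seed Integer seed (fold assignment when > 10 patients).
#' @return List with `lambda` (the selected penalty), `cv_table`
#'   (data.frame fold x biopsy x lambda with held-out predictions and
#'   squared errors), `cv_mean` (mean squared error per lambda) and
#'   `folds` (patient fold assignment).
#' @export
select_lambda_grouped_cv <- function(qifs, labels, groups,
                                     grid = make_lambda_grid(), seed = 1L) {
  stopifnot(inherits(grid, "lambda_grid"))
  if (inherits(qifs, "qif_matrix")) qifs <- list(qifs)
  d <- pool_patches(qifs, labels)
  missing <- setdiff(d$ids, names(groups))
  if (length(missing))
    fs_stop(paste("no patient mapping for biopsy:",
                  paste(missing, collapse = ", ")), "join_error")
  patient <- as.character(groups[d$ids])
  patients <- unique(patient)
  if (length(patients) < 2L)
    fs_stop("grouped CV needs at least 2 patients", "invalid_argument")

  fold_of <- if (length(patients) <= 10L) {
    stats::setNames(seq_along(patients), patients)        # LOPO
  } else {
    shuffled <- with_seed(seed, sample(patients))
    stats::setNames(rep_len(1:5, length(shuffled)), shuffled)[patients]
  }
  fold_of <- stats::setNames(as.integer(fold_of), patients)

  lam <- grid$values
  rows <- list()
  for (f in sort(unique(fold_of))) {
    test_patients <- names(fold_of)[fold_of == f]
    test_idx <- which(patient %in% test_patients)
    train_idx <- setdiff(seq_along(d$ids), test_idx)
    # leakage guard: must be unreachable
    stopifnot(length(intersect(patient[train_idx], patient[test_idx])) == 0)
    train_rows <- d$biopsy %in% d$ids[train_idx]
    Xtr <- d$X[train_rows, , drop = FALSE]
    ytr <- d$y[train_rows]
    fits <- suppressWarnings(lasso_path(Xtr, ytr, lam))
    for (li in seq_along(lam)) {
      m <- fits[[li]]
      for (bi in test_idx) {
        pred <- mean(predict_patches(m, qifs[[bi]]$values))
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, biopsy_id = d$ids[bi], lambda = lam[li],
          pred = pred, label = d$labels[bi],
          sq_err = (pred - d$labels[bi])^2)
      }
    }
  }
  cv_table <- do.call(rbind, rows)
  cv_mean <- vapply(lam, function(l)
    mean(cv_table$sq_err[cv_table$lambda == l]), numeric(1))
  best <- min(cv_mean)
  lambda_star <- max(lam[cv_mean <= best + 1e-12])
  list(lambda = lambda_star,
       cv_table = cv_table,
       cv_mean = stats::setNames(cv_mean, signif(lam, 6)),
       folds = fold_of)
}

#' Fit the Fibrosis Score model with cross-validated penalty selection
#'
#' The one-stop fitting interface: selects the penalty by grouped CV
#' ([select_lambda_grouped_cv()]), then refits on all patients at the
#' selected penalty.  The returned object supports `print`, `summary`,
#' `coef` and `predict`.
#'
#' @inheritParams select_lambda_grouped_cv
#' @return A `fibrosis_model` with the refit coefficients, `lambda`, the
#'   CV table and the fold assignment.
#' @export
fit_fibrosis <- function(qifs, labels, groups, grid = make_lambda_grid(),
                         seed = 1L) {
  cv <- select_lambda_grouped_cv(qifs, labels, groups, grid, seed)
  model <- fit_lasso_patchwise(qifs, labels, cv$lambda)
  model$cv <- cv
  model$grid <- grid
  model
}

#' Per-biopsy Fibrosis Score from a fitted model
#'
#' Applies the linear model to every patch and averages: the score is the
#' arithmetic mean of the patch predictions, reported unclipped on the
#' (approximate) mRSS scale.
#'
#' @param model A `fibrosis_model`.
#' @param qif A `qif_matrix` for one biopsy.
#' @return An object of class `fibrosis_score`: list with `biopsy_id`,
#'   `score`, `n_patches`, `patch_predictions`.
#' @export
predict_fibrosis_score <- function(model, qif) {
  stopifnot(inherits(model, "fibrosis_model"), inherits(qif, "qif_matrix"))
  preds <- predict_patches(model, qif$values)
  structure(list(biopsy_id = qif$biopsy_id, score = mean(preds),
                 n_patches = length(preds), patch_predictions = preds),
            class = "fibrosis_score")
}

#' Rank correlation between Fibrosis Scores and labels
#'
#' @param scores List of `fibrosis_score` objects (or a numeric vector).
#' @param labels Numeric vector, same order.
#' @return A `correlation_result` from [spearman_corr()].
#' @export
evaluate_scores <- function(scores, labels) {
  s <- if (is.numeric(scores)) scores else
    vapply(scores, function(x) x$score, numeric(1))
  spearman_corr(s, labels)
}

#' @export
predict.fibrosis_model <- function(object, newdata, ...) {
  if (inherits(newdata, "qif_matrix"))
    return(predict_fibrosis_score(object, newdata))
  if (is.list(newdata))
    return(lapply(newdata, predict_fibrosis_score, model = object))
  fs_stop("`newdata` must be a qif_matrix or a list of them", "shape_error")
}

#' @export
coef.fibrosis_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.fibrosis_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("Fibrosis Score lasso model: %d features, %d nonzero, lambda = %.4g\n",
              x$D, nz, x$lambda))
  cat(sprintf("intercept (training-mean mRSS): %.3f\n", x$intercept))
  if (!is.null(x$cv))
    cat(sprintf("lambda selected by %d-fold grouped CV (min MSE %.3f)\n",
                length(unique(x$cv$folds)), min(x$cv$cv_mean)))
  invisible(x)
}

#' @export
summary.fibrosis_model <- function(object, ...) {
  out <- list(model = object,
              nonzero = names(object$coefficients)[object$coefficients != 0],
              cv_mean = object$cv$cv_mean)
  class(out) <- "summary.fibrosis_model"
  out
}

#' @export
print.summary.fibrosis_model <- function(x, ...) {
  print(x$model)
  if (length(x$nonzero)) {
    cat("nonzero coefficients:\n")
    print(x$model$coefficients[x$nonzero])
  }
  if (!is.null(x$cv_mean)) {
    cat("cross-validated MSE by lambda:\n")
    print(round(x$cv_mean, 3))
  }
  invisible(x)
}

#' @export
print.fibrosis_score <- function(x, ...) {
  cat(sprintf("<fibrosis_score> %s: %.3f (mean of %d patch predictions)\n",
              x$biopsy_id, x$score, x$n_patches))
  invisible(x)
}
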