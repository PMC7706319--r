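#' Default SVR hyperparameter grid
#'
#' Gaussian-kernel support vector regression with kernel
#' \eqn{K(x, x') = \exp(-\gamma \lVert x - x' \rVert^2)}.  The kernel
#' width grid is anchored at the median heuristic
#' \eqn{\gamma_0 = 1 / (2\,\mathrm{median}(\lVert x_i - x_j \rVert^2))}
#' computed on the training rows, scaled by `gamma_scale`.
#'
#' @param cost Box-constraint values.
#' @param epsilon Epsilon-insensitive tube widths.
#' @param gamma_scale Multipliers applied to the median-heuristic width.
#' @return List with class `"svr_grid"`.
#' @export
svr_grid <- function(cost = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1, 1),
                     gamma_scale = c(0.25, 1, 4)) {
  if (!length(cost) || !length(epsilon) || !length(gamma_scale))
    stop("empty hyperparameter grid")
  structure(list(cost = cost, epsilon = epsilon, gamma_scale = gamma_scale),
            class = "svr_grid")
}

#' Fit a Gaussian-kernel SVR with grid-searched hyperparameters and predict
#'
#' Hyperparameters (box constraint, epsilon, kernel width) are selected by
#' K-fold cross-validation on the training set only, minimizing CV mean
#' squared error; the winning triple is refitted on the full training set
#' and applied to the test rows, which never influence fitting.
#'
#' @param u_train,u_test Representation matrices (train/test rows).
#' @param y_train Numeric training targets.
#' @param grid An [svr_grid()].
#' @param cv_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment (determinism
#'   contract: identical inputs and seed give identical predictions).
#' @return Numeric predictions for `u_test` rows, with attribute
#'   `"chosen"` (the selected hyperparameters).
#' @export
fit_predict_svr <- function(u_train, y_train, u_test, grid = svr_grid(),
                            cv_folds = 10L, seed = 1L) {
  if (!inherits(grid, "svr_grid")) stop("'grid' must be an svr_grid")
  if (!all(is.finite(y_train))) stop("non-finite training targets")
  u_train <- as.matrix(u_train); u_test <- as.matrix(u_test)
  ntr <- nrow(u_train)
  if (ntr < cv_folds) stop("fewer training samples (", ntr,
                           ") than CV folds (", cv_folds, ")")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  g0 <- median_gamma(u_train)
  combos <- expand.grid(cost = grid$cost, epsilon = grid$epsilon,
                        gamma = g0 * grid$gamma_scale)
  fold <- sample(rep(seq_len(cv_folds), length.out = ntr))
  cv_mse <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pred <- numeric(ntr)
    for (f in seq_len(cv_folds)) {
      hold <- fold == f
      m <- e1071::svm(x = u_train[!hold, , drop = FALSE], y = y_train[!hold],
                      type = "eps-regression", kernel = "radial",
                      cost = combos$cost[i], epsilon = combos$epsilon[i],
                      gamma = combos$gamma[i], scale = FALSE)
      pred[hold] <- stats::predict(m, u_train[hold, , drop = FALSE])
    }
    cv_mse[i] <- mean((pred - y_train)^2)
  }
  best <- which.min(cv_mse)
  m <- e1071::svm(x = u_train, y = y_train, type = "eps-regression",
                  kernel = "radial", cost = combos$cost[best],
                  epsilon = combos$epsilon[best], gamma = combos$gamma[best],
                  scale = FALSE)
  out <- as.numeric(stats::predict(m, u_test))
  attr(out, "chosen") <- combos[best, , drop = FALSE]
  out
}

median_gamma <- function(u, max_rows = 200L) {
  if (nrow(u) > max_rows) u <- u[seq_len(max_rows), , drop = FALSE]
  d2 <- stats::dist(u)^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  1 / (2 * med)
}

#' Coefficient of determination against a training-mean baseline
#'
#' \deqn{R^2 = 1 - \frac{\sum_i (y_i - \hat{y}_i)^2}{\sum_i (y_i - \bar{y})^2}}
#' where \eqn{\bar{y}} is the mean of the *training* targets, so that a
#' constant predictor at the training mean scores exactly 0 on any test
#' set.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @param baseline_mean Mean of the training targets.
#' @return R-squared (can be negative for predictors worse than the
#'   baseline).
#' @export
r_squared <- function(y_true, y_pred, baseline_mean) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty vectors")
  denom <- sum((y_true - baseline_mean)^2)
  if (denom == 0)
    stop("zero denominator: all test targets equal the baseline mean, ",
         "R-squared is undefined")
  1 - sum((y_true - y_pred)^2) / denom
}

#' Proportion of predictions within a relative margin of the truth
#'
#' Fraction of samples with
#' \eqn{|\hat{y}_i - y_i| \le \mathrm{margin} \cdot |y_i|}, the
#' "confidence range" summary used for phenotype predictions.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @param margin Relative margin, e.g. 0.05, 0.10, 0.15.
#' @param relative If `FALSE`, `margin` is an absolute tolerance instead.
#' @return Proportion in `[0, 1]`.
#' @export
margin_proportion <- function(y_true, y_pred, margin, relative = TRUE) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (margin <= 0) stop("'margin' must be > 0")
  if (relative && any(y_true == 0))
    stop("relative margin undefined for zero targets; use relative = FALSE")
  tol <- if (relative) margin * abs(y_true) else margin
  mean(abs(y_pred - y_true) <= tol)
}

#' Repeated random-split evaluation of a representation
#'
#' For each repeat the samples are randomly split into training and test
#' sets, a Gaussian-kernel SVR is tuned on the training set
#' ([fit_predict_svr()]), and held-out R-squared (training-mean baseline),
#' mean squared error and the proportions of predictions inside the 5, 10
#' and 15 percent confidence ranges are recorded.  Repeat seeds are
#' derived deterministically from `seed`.
#'
#' Following the original protocol the representation is computed once on
#' all samples before splitting; see [evaluate_views()] for the strict
#' variant that refits the representation inside each repeat.
#'
#' @param u Representation matrix (n x d), e.g. a fitted model's joint
#'   representation.
#' @param y Numeric phenotype vector of length n.
#' @param n_repeats Number of random splits (default 200).
#' @param test_fraction Fraction of samples held out (default 0.2).
#' @param grid,cv_folds Passed to [fit_predict_svr()].
#' @param seed Master seed.
#' @param margins Relative margins summarized per repeat.
#' @return Object of class `"hcca_eval"`: data frame `repeats` (per-repeat
#'   R-squared, MSE, margin proportions, chosen hyperparameters), summary
#'   fields `r2_mean`, `r2_sd`, `mse_mean` and `margin_mean`.
#' @export
evaluate_joint <- function(u, y, n_repeats = 200L, test_fraction = 0.2,
                           grid = svr_grid(), cv_folds = 10L, seed = 1L,
                           margins = c(0.05, 0.10, 0.15)) {
  u <- as.matrix(u)
  n <- nrow(u)
  if (length(y) != n) stop("phenotype length does not match representation rows")
  if (n < 10L) stop("need at least 10 samples")
  if (n_repeats < 1L) stop("'n_repeats' must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must be in (0, 1)")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rep_seed <- (as.integer(seed) + r) %% .Machine$integer.max
    set.seed(rep_seed)
    test <- sample(n, max(1L, round(test_fraction * n)))
    train <- setdiff(seq_len(n), test)
    yhat <- fit_predict_svr(u[train, , drop = FALSE], y[train],
                            u[test, , drop = FALSE], grid = grid,
                            cv_folds = cv_folds, seed = rep_seed)
    chosen <- attr(yhat, "chosen")
    prop <- vapply(margins, function(m)
      margin_proportion(y[test], yhat, m), 0)
    rows[[r]] <- data.frame(
      repeat_id = r, seed = rep_seed,
      r2 = r_squared(y[test], yhat, mean(y[train])),
      mse = mean((y[test] - yhat)^2),
      t(stats::setNames(prop, paste0("within_", margins * 100))),
      cost = chosen$cost, epsilon = chosen$epsilon, gamma = chosen$gamma)
  }
  rep_df <- do.call(rbind, rows)
  sd_flag <- n_repeats < 2L
  structure(list(repeats = rep_df,
                 r2_mean = mean(rep_df$r2),
                 r2_sd = if (sd_flag) 0 else stats::sd(rep_df$r2),
                 r2_sd_undefined = sd_flag,
                 mse_mean = mean(rep_df$mse),
                 margin_mean = colMeans(rep_df[, grep("^within_", colnames(rep_df)),
                                               drop = FALSE]),
                 n = n, n_repeats = n_repeats,
                 test_fraction = test_fraction, seed = seed),
            class = "hcca_eval")
}

#' @export
print.hcca_eval <- function(x, ...) {
  cat(sprintf("Repeated SVR evaluation: %d repeats, %d samples, %.0f%% held out\n",
              x$n_repeats, x$n, 100 * x$test_fraction))
  cat(sprintf("  R-squared: mean %.4f, sd %.4f%s\n", x$r2_mean, x$r2_sd,
              if (isTRUE(x$r2_sd_undefined)) " (single repeat; sd undefined, reported as 0)" else ""))
  cat(sprintf("  MSE: mean %.4f\n", x$mse_mean))
  cat("  within-margin proportions:",
      paste(sprintf("%s=%.3f", names(x$margin_mean), x$margin_mean),
            collapse = " "), "\n")
  invisible(x)
}

#' Evaluate integration methods and single views on one phenotype
#'
#' Convenience wrapper around [evaluate_joint()]: computes the requested
#' representations (single views, stacked matrix, HCCA / PCCA / TCCA joint
#' representations) on the aligned views and evaluates each with the same
#' repeated-split protocol, so results are directly comparable.
#'
#' With `strict_split = TRUE` the integration model is refitted on every
#' repeat's training samples only and test samples are projected through
#' it ([predict.hcca()]), so no test information can leak into the
#' representation; the default reproduces the project-once-then-split
#' protocol.
#'
#' @param views Sample-aligned list of view matrices.
#' @param y Phenotype vector aligned with the views.
#' @param methods Character subset of `"hcca"`, `"pcca"`, `"tcca"`,
#'   `"stack"`, `"single"`.
#' @param strict_split Refit the representation inside each repeat
#'   (HCCA only)?
#' @param c,percent Passed to the integrators.
#' @param ... Passed to [evaluate_joint()] (`n_repeats`, `grid`, `seed`,
#'   ...).
#' @return Named list of `"hcca_eval"` objects (one per representation;
#'   single views are named by view).
#' @export
evaluate_views <- function(views, y, methods = c("hcca", "single"),
                           strict_split = FALSE, c = 4, percent = 85, ...) {
  al <- align_samples(views, y)
  views <- al$views; y <- al$phenotype
  out <- list()
  if ("single" %in% methods)
    for (v in names(views)) out[[v]] <- evaluate_joint(views[[v]], y, ...)
  if ("stack" %in% methods)
    out$stack <- evaluate_joint(stack_views(views), y, ...)
  if ("pcca" %in% methods) {
    fit <- pcca(views, c = c, percent = percent)
    out$pcca <- evaluate_joint(do.call(cbind, fit$scores), y, ...)
  }
  if ("tcca" %in% methods) {
    fit <- tcca(views, k = 2L, c = c)
    out$tcca <- evaluate_joint(do.call(cbind, fit$scores), y, ...)
  }
  if ("hcca" %in% methods) {
    if (strict_split) {
      out$hcca <- evaluate_joint_strict(views, y, c = c, percent = percent, ...)
    } else {
      fit <- hcca(views, c = c, percent = percent)
      out$hcca <- evaluate_joint(fit$U, y, ...)
    }
  }
  out
}

# strict no-leakage variant: refit HCCA per repeat on training rows only
evaluate_joint_strict <- function(views, y, c = 4, percent = 85,
                                  n_repeats = 200L, test_fraction = 0.2,
                                  grid = svr_grid(), cv_folds = 10L,
                                  seed = 1L, margins = c(0.05, 0.10, 0.15)) {
  n <- length(y)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rep_seed <- (as.integer(seed) + r) %% .Machine$integer.max
    set.seed(rep_seed)
    test <- sample(n, max(1L, round(test_fraction * n)))
    train <- setdiff(seq_len(n), test)
    tr_views <- lapply(views, function(v) v[train, , drop = FALSE])
    te_views <- lapply(views, function(v) v[test, , drop = FALSE])
    fit <- hcca(tr_views, c = c, percent = percent)
    u_test <- predict(fit, te_views)
    yhat <- fit_predict_svr(fit$U, y[train], u_test, grid = grid,
                            cv_folds = cv_folds, seed = rep_seed)
    chosen <- attr(yhat, "chosen")
    prop <- vapply(margins, function(m) margin_proportion(y[test], yhat, m), 0)
    rows[[r]] <- data.frame(
      repeat_id = r, seed = rep_seed,
      r2 = r_squared(y[test], yhat, mean(y[train])),
      mse = mean((y[test] - yhat)^2),
      t(stats::setNames(prop, paste0("within_", margins * 100))),
      cost = chosen$cost, epsilon = chosen$epsilon, gamma = chosen$gamma)
  }
  rep_df <- do.call(rbind, rows)
  sd_flag <- n_repeats < 2L
  structure(list(repeats = rep_df, r2_mean = mean(rep_df$r2),
                 r2_sd = if (sd_flag) 0 else stats::sd(rep_df$r2),
                 r2_sd_undefined = sd_flag, mse_mean = mean(rep_df$mse),
                 margin_mean = colMeans(rep_df[, grep("^within_", colnames(rep_df)),
                                               drop = FALSE]),
                 n = n, n_repeats = n_repeats,
                 test_fraction = test_fraction, seed = seed),
            class = "hcca_eval")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
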