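test_that("R-squared uses the training-mean baseline", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3), 2), 1)
  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2), 2), 0)
  expect_equal(r_squared(c(0, 2), c(1, 1), 1), 0)
  expect_lt(r_squared(c(0, 2), c(2, 0), 1), 0)  # worse than baseline
  expect_error(r_squared(c(1, 1), c(0, 0), 1), "zero denominator")
  expect_error(r_squared(1:3, 1:2, 0), "length")
})

test_that("margin proportions count predictions inside the relative band", {
  expect_equal(margin_proportion(c(100, 200), c(110, 260), 0.15), 0.5)
  expect_equal(margin_proportion(c(5, 5), c(5, 5), 0.05), 1)
  y <- c(10, 20, 30, 40); yh <- c(10.4, 21, 36, 55)
  props <- vapply(c(0.05, 0.10, 0.15), function(m)
    margin_proportion(y, yh, m), 0)
  expect_true(all(diff(props) >= 0))
  expect_error(margin_proportion(c(0, 1), c(0, 1), 0.1), "zero targets")
  expect_equal(margin_proportion(c(0, 1), c(0.05, 1), 0.1, relative = FALSE), 1)
})

test_that("SVR learns a noiseless relationship and fails on permuted targets", {
  set.seed(71)
  u <- matrix(rnorm(100), 100, 1)
  y <- 3 * u[, 1] + 2
  yhat <- fit_predict_svr(u[1:80, , drop = FALSE], y[1:80],
                          u[81:100, , drop = FALSE], grid = tiny_grid,
                          cv_folds = 5, seed = 1)
  expect_gte(r_squared(y[81:100], yhat, mean(y[1:80])), 0.99)

  null_r2 <- vapply(1:20, function(s) {
    set.seed(700 + s)
    yp <- sample(y[1:80])
    yh <- fit_predict_svr(u[1:80, , drop = FALSE], yp,
                          u[81:100, , drop = FALSE], grid = tiny_grid,
                          cv_folds = 5, seed = s)
    r_squared(y[81:100], yh, mean(yp))
  }, 0)
  expect_lte(median(null_r2), 0.1)
})

test_that("SVR predictions are deterministic given a seed", {
  set.seed(72)
  u <- matrix(rnorm(120), 60, 2)
  y <- u[, 1] + rnorm(60, sd = 0.2)
  p1 <- fit_predict_svr(u[1:50, ], y[1:50], u[51:60, ], grid = tiny_grid,
                        cv_folds = 5, seed = 9)
  p2 <- fit_predict_svr(u[1:50, ], y[1:50], u[51:60, ], grid = tiny_grid,
                        cv_folds = 5, seed = 9)
  expect_identical(p1, p2)
  expect_error(fit_predict_svr(u[1:5, ], y[1:5], u[6:10, ], cv_folds = 10),
               "fewer training samples")
})

test_that("repeated evaluation reports per-repeat metrics deterministically", {
  set.seed(73)
  u <- matrix(rnorm(200), 100, 2)
  y <- 60 + u[, 1] + rnorm(100, sd = 0.5)
  ev1 <- evaluate_joint(u, y, n_repeats = 3, grid = tiny_grid,
                        cv_folds = 5, seed = 4)
  ev2 <- evaluate_joint(u, y, n_repeats = 3, grid = tiny_grid,
                        cv_folds = 5, seed = 4)
  expect_identical(ev1$repeats, ev2$repeats)
  expect_equal(nrow(ev1$repeats), 3L)
  expect_true(all(diff(as.numeric(ev1$margin_mean)) >= 0))

  one <- evaluate_joint(u, y, n_repeats = 1, grid = tiny_grid,
                        cv_folds = 5, seed = 4)
  expect_equal(one$r2_sd, 0)
  expect_true(one$r2_sd_undefined)
  expect_error(evaluate_joint(u, y, n_repeats = 0), "n_repeats")
})

test_that("strict splitting refits the model on training rows only", {
  sc <- sim_scenario("grouped", seed = 74, n = 60)
  train <- 1:45
  tr <- lapply(sc$views, function(v) v[train, , drop = FALSE])
  fit1 <- hcca(tr)
  # perturbing held-out rows cannot change the refitted model
  views2 <- lapply(sc$views, function(v) { v[46:60, ] <- v[46:60, ] + 100; v })
  fit2 <- hcca(lapply(views2, function(v) v[train, , drop = FALSE]))
  expect_identical(fit1, fit2)
})

test_that("the comparison wrapper evaluates every requested representation", {
  sc <- sim_scenario("grouped", seed = 75, n = 60)
  y <- 5 + sc$truth$Z[, 1] + rnorm(60, sd = 0.5)
  names(y) <- rownames(sc$views[[1]])
  res <- evaluate_views(sc$views, y, methods = c("single", "stack", "pcca", "tcca"),
                        n_repeats = 2, grid = tiny_grid, cv_folds = 5, seed = 1)
  expect_setequal(names(res), c("view1", "view2", "view3", "stack", "pcca", "tcca"))
  for (r in res) expect_s3_class(r, "hcca_eval")

  strict <- evaluate_views(sc$views, y, methods = "hcca", strict_split = TRUE,
                           n_repeats = 2, grid = tiny_grid, cv_folds = 5, seed = 1)
  expect_equal(nrow(strict$hcca$repeats), 2L)
  expect_true(is.finite(strict$hcca$r2_mean))
})

test_that("integrated representations beat single views when signal is shared", {
  # scaled-down sweep of the qualitative comparison pattern, at the
  # scenario's design size where split noise does not swamp the margins
  g <- svr_grid(cost = c(1, 10, 100), epsilon = 0.1, gamma_scale = c(0.5, 1, 2))
  wins_single <- 0L; wins_stack <- 0L
  n_scen <- 5L
  for (s in seq_len(n_scen)) {
    sc <- sim_scenario("flowering", seed = 800 + s)
    fit <- hcca(sc$views)
    evj <- evaluate_joint(fit$U, sc$y, n_repeats = 4, grid = g,
                          cv_folds = 5, seed = s)
    best_single <- max(vapply(sc$views, function(v)
      evaluate_joint(v, sc$y, n_repeats = 3, grid = g,
                     cv_folds = 5, seed = s)$r2_mean, 0))
    stacked <- evaluate_joint(stack_views(sc$views), sc$y, n_repeats = 3,
                              grid = g, cv_folds = 5, seed = s)$r2_mean
    if (evj$r2_mean >= best_single) wins_single <- wins_single + 1L
    if (evj$r2_mean >= stacked) wins_stack <- wins_stack + 1L
  }
  expect_gte(wins_single, 4L)
  expect_gte(wins_stack, 4L)
})
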