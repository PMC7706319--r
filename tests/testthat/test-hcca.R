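test_that("a single view passes through unchanged", {
  set.seed(41)
  x <- rand_view(12, 4)
  fit <- hcca(list(only = x))
  expect_identical(fit$U, x)
  expect_null(fit$merge_log)
  expect_identical(predict(fit, list(only = x)), x)
})

test_that("two views reduce exactly to a single CCA coprojection", {
  set.seed(42)
  x <- rand_view(30, 4)
  y <- rand_view(30, 5, prefix = "h")
  y[, 1] <- y[, 1] + x[, 1]
  fit <- hcca(list(a = x, b = y))
  ref <- rcca(x, y, c = 4, percent = 85)
  expect_identical(fit$U,
                   coproject(ref$scores$left, ref$scores$right, node = "(a+b)"))
  expect_equal(nrow(fit$merge_log), 1L)
})

test_that("the planted strongly-shared pair is merged first", {
  hits <- 0L
  for (s in 1:5) {
    sc <- sim_scenario("grouped", seed = 500 + s)
    fit <- hcca(sc$views)
    first <- sort(c(fit$merge_log$i[1], fit$merge_log$j[1]))
    expect_equal(first, brute_best_pair(sc$views))  # oracle agreement always
    if (identical(first, sc$planted_pair)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("merge log records the minimum of each level's pair table", {
  set.seed(43)
  views <- list(a = rand_view(25, 4), b = rand_view(25, 5, prefix = "h"),
                c = rand_view(25, 3, prefix = "e"))
  fit <- hcca(views)
  expect_equal(nrow(fit$merge_log), 2L)
  for (lvl in 1:2) {
    tab <- fit$pair_tables[[lvl]]
    expect_equal(fit$merge_log$kappa[lvl], min(tab$kappa))
  }
})

test_that("fitting is deterministic and fixed pairs constrain level 1 only", {
  sc <- sim_scenario("grouped", seed = 7)
  f1 <- hcca(sc$views)
  f2 <- hcca(sc$views)
  expect_identical(f1, f2)

  forced <- hcca(sc$views, fixed_first_pair = c(3, 1))
  expect_equal(sort(c(forced$merge_log$i[1], forced$merge_log$j[1])), c(1L, 3L))
  # level 2 has a single remaining pair either way
  expect_equal(nrow(forced$merge_log), 2L)
  expect_error(hcca(sc$views, fixed_first_pair = c(1, 9)), "view indices")
  expect_error(hcca(list()), "non-empty")
})

test_that("prediction replays the tree on new samples", {
  sc <- sim_scenario("grouped", seed = 9)
  fit <- hcca(sc$views)
  expect_equal(predict(fit, sc$views), fit$U, tolerance = 1e-10)

  one <- lapply(sc$views, function(v) v[5, , drop = FALSE])
  expect_equal(predict(fit, one), fit$U[5, , drop = FALSE], tolerance = 1e-10)

  perm <- sample(nrow(fit$U))
  permed <- lapply(sc$views, function(v) v[perm, , drop = FALSE])
  expect_equal(predict(fit, permed), fit$U[perm, , drop = FALSE],
               tolerance = 1e-10)

  bad <- sc$views
  colnames(bad[[2]]) <- paste0("x", seq_len(ncol(bad[[2]])))
  expect_error(predict(fit, bad), "feature IDs")
})

test_that("models survive a serialization round trip and reject bad files", {
  sc <- sim_scenario("grouped", seed = 11, n = 40)
  fit <- hcca(sc$views)
  f <- withr::local_tempfile(fileext = ".rds")
  write_hcca(fit, f)
  back <- read_hcca(f)
  expect_equal(back, fit, tolerance = 1e-15)
  expect_identical(predict(back, sc$views), predict(fit, sc$views))

  raw <- readBin(f, "raw", file.info(f)$size)
  trunc <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[seq_len(20)], trunc)
  expect_error(read_hcca(trunc), "truncated|corrupt|not an hcca")

  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "hcca_model", version = 99L, model = NULL), other)
  expect_error(read_hcca(other), "version")
})

test_that("the joint representation concentrates a globally shared factor", {
  wins <- 0L
  for (s in 1:10) {
    sim <- sim_multiview(n = 100, dims = c(20, 20, 20),
                         shared = list(r = 1, scale = 1.5),
                         groups = list(list(views = c(1, 2), r = 2),
                                       list(views = 3, r = 2)),
                         noise_sd = 0.5, seed = 600 + s)
    z <- sim$truth$Z[, 1]
    fit <- hcca(sim$views)
    joint_cor <- max(abs(cor(fit$U, z)))
    best_feature <- max(vapply(sim$views, function(v) max(abs(cor(v, z))), 0))
    if (joint_cor > best_feature) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("hierarchical cost stays within a small factor of one flat CCA", {
  set.seed(44)
  sim <- sim_multiview(n = 80, dims = rep(100L, 4), shared = list(r = 2),
                       groups = list(), noise_sd = 0.5, seed = 45)
  t_h <- system.time(hcca(sim$views))[["elapsed"]]
  big_a <- rand_view(80, 200)
  big_b <- rand_view(80, 200, prefix = "h")
  t_c <- system.time(rcca(big_a, big_b))[["elapsed"]]
  # smoke benchmark, not a hard bound: same asymptotic order
  expect_lt(t_h, 50 * max(t_c, 0.02))
})
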