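test_that("loadings are exactly per-feature Pearson correlations", {
  set.seed(61)
  x <- rand_view(5, 4)
  u <- mk_view(matrix(rnorm(10), 5, 2), prefix = "u")
  lt <- factor_loadings(x, u)
  for (f in 1:4) for (m in 1:2)
    expect_equal(lt[f, m], cor(x[, f], u[, m]), tolerance = 1e-12)
  expect_true(all(lt >= -1 & lt <= 1))
})

test_that("self-correlated and orthogonal features load at 1 and 0", {
  set.seed(62)
  u <- mk_view(matrix(rnorm(40), 20, 2), prefix = "u")
  x <- cbind(u[, 1], rnorm(20))
  # third feature: residualize to make it exactly orthogonal to both
  r <- residuals(lm(rnorm(20) ~ u[, 1] + u[, 2]))
  x <- mk_view(cbind(u[, 1], r))
  lt <- factor_loadings(x, u)
  expect_equal(lt[1, 1], 1, tolerance = 1e-10)
  expect_equal(unname(lt[2, ]), c(0, 0), tolerance = 1e-10)
})

test_that("constant features are flagged with loading zero", {
  x <- mk_view(cbind(rep(1, 10), rnorm(10)))
  u <- mk_view(matrix(rnorm(20), 10, 2), prefix = "u")
  lt <- factor_loadings(x, u)
  expect_equal(unname(lt[1, ]), c(0, 0))
  expect_true(attr(lt, "constant")[1])
  expect_false(attr(lt, "constant")[2])
})

test_that("path loadings walk the view's merges to the root", {
  sc <- sim_scenario("grouped", seed = 63)
  fit <- hcca(sc$views, fixed_first_pair = c(1, 2))
  # view1's first merge is the level-1 node, stored as the root's right child
  l1 <- path_loadings(fit, 1, sc$views, level = 1)
  first_node <- fit$root$right
  expect_identical(first_node$name, "(view1+view2)")
  u1 <- coproject(first_node$fit$scores$left, first_node$fit$scores$right,
                  node = first_node$name)
  direct <- factor_loadings(sc$views[[1]], u1)
  expect_equal(unclass(l1), unclass(direct), ignore_attr = TRUE)

  l2 <- path_loadings(fit, 1, sc$views, level = 2)
  expect_false(isTRUE(all.equal(unclass(l1), unclass(l2), check.attributes = FALSE)))
  expect_error(path_loadings(fit, 1, sc$views, level = 5), "valid levels")
  expect_error(path_loadings(fit, "nope", sc$views), "unknown view")
})

test_that("nearest features rank by Euclidean loading distance with ID ties", {
  ta <- structure(matrix(c(0.5, 0.1), 1, 2,
                         dimnames = list("target", c("c1", "c2"))),
                  class = c("loading_table", "matrix"), node = "m")
  B <- matrix(c(0.5, 0.1,   # exact match -> distance 0
                0.6, 0.1,   # 0.1
                0.5, 0.4,   # 0.3
                0.6, 0.1),  # tie with row 2 -> ID order decides
              4, 2, byrow = TRUE,
              dimnames = list(c("g4", "g2", "g3", "g1"), c("c1", "c2")))
  tb <- structure(B, class = c("loading_table", "matrix"), node = "m")
  rk <- nearest_features(ta, tb, "target", m = 10)
  expect_equal(rk$feature_id, c("g4", "g1", "g2", "g3"))
  expect_equal(rk$distance, c(0, 0.1, 0.1, 0.3), tolerance = 1e-12)
  expect_equal(rk$rank, 1:4)

  top2 <- nearest_features(ta, tb, "target", m = 2)
  expect_equal(nrow(top2), 2L)
  expect_error(nearest_features(ta, tb, "missing"), "unknown target")
})

test_that("cross-node loading comparison is refused", {
  lt1 <- structure(matrix(0, 1, 2, dimnames = list("a", NULL)),
                   class = c("loading_table", "matrix"), node = "n1")
  lt2 <- structure(matrix(0, 1, 2, dimnames = list("b", NULL)),
                   class = c("loading_table", "matrix"), node = "n2")
  expect_error(nearest_features(lt1, lt2, "a"), "different hierarchy nodes")
})

test_that("co-loading features of two views find each other without noise", {
  # one shared factor, zero noise: a view-1 feature and a view-2 feature
  # loading on the same factor coincide in loading space
  sim <- sim_multiview(n = 50, dims = c(3, 3), shared = list(r = 2),
                       groups = list(), noise_sd = 0, seed = 64)
  fit <- hcca(sim$views)
  node <- fit$root
  u <- coproject(node$fit$scores$left, node$fit$scores$right, node = node$name)
  la <- factor_loadings(sim$views[[1]], u, view = "v1", node = node$name)
  lb <- factor_loadings(sim$views[[2]], u, view = "v2", node = node$name)
  # for each view-2 feature, its nearest view-1 feature should be the one
  # with the most similar true loading pattern; verify distance ~ 0 ordering
  target <- rownames(lb)[1]
  rk <- nearest_features(lb, la, target, m = 3)
  best_true <- which.min(colSums((t(unclass(la)) - unclass(lb)[1, ])^2))
  expect_identical(rk$feature_id[1], rownames(la)[best_true])
})

test_that("exported gene lists are deterministic TSV", {
  rk <- data.frame(rank = 1:3, feature_id = c("a", "b", "c"),
                   distance = c(0, 0.5, 1.25))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_gene_list(rk, f1)
  export_gene_list(rk, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(readLines(f1)), 4L)
  empty <- rk[0, ]
  export_gene_list(empty, f1)
  expect_equal(length(readLines(f1)), 1L)
})
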