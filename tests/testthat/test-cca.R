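test_that("a view against itself has first canonical correlation 1", {
  set.seed(31)
  x <- rand_view(30, 4)
  y <- x; colnames(y) <- paste0("h", 1:4)
  fit <- rcca(x, y, alpha = c(0, 0))
  expect_equal(fit$cor[1], 1, tolerance = 1e-8)
})

test_that("single-feature views reduce to the Pearson correlation", {
  x <- mk_view(matrix(c(1, 2, 3), 3, 1))
  y <- mk_view(matrix(c(1, 3, 2), 3, 1), prefix = "h")
  fit <- rcca(x, y, alpha = c(0, 0))
  expect_equal(fit$cor[1], 0.5, tolerance = 1e-10)
})

test_that("independent views stay below the permutation null", {
  set.seed(32)
  x <- rand_view(500, 3)
  y <- rand_view(500, 3, prefix = "h")
  rho <- rcca(x, y, alpha = c(0, 0))$cor[1]
  null <- replicate(200, {
    perm <- sample(nrow(y))
    yp <- y[perm, , drop = FALSE]
    rownames(yp) <- rownames(y)
    rcca(x, yp, alpha = c(0, 0), k = 1)$cor[1]
  })
  expect_lt(rho, quantile(null, 0.99))
})

test_that("component count follows the cumulative-spectrum rule", {
  expect_equal(choose_k(c(1, 1, 1, 1), 85), 3L)
  expect_equal(choose_k(c(0.9, 0.5, 0.3, 0.2, 0.1), 85), 3L)
  expect_equal(choose_k(0.7, 85), 1L)
  expect_equal(choose_k(c(1, 1e-15), 85), 1L)  # numerical zeros excluded
  expect_warning(k <- choose_k(c(0, 0), 85), "all-zero")
  expect_equal(k, 1L)
})

test_that("projection applies stored centers and weights", {
  set.seed(33)
  x <- rand_view(6, 3)
  e2 <- matrix(c(0, 1, 0), 3, 1)
  u <- project_view(x, e2)
  expect_equal(unname(u[, 1]), unname(x[, 2] - mean(x[, 2])))

  z <- mk_view(matrix(0, 4, 2))
  expect_true(all(project_view(z, matrix(1, 2, 1)) == 0))

  w <- matrix(rnorm(6), 3, 2)
  expect_equal(unname(project_view(x, w)),
               unname(sweep(x, 2, colMeans(x)) %*% w))
  expect_error(project_view(x, matrix(1, 5, 1)), "do not match")
})

test_that("coprojection concatenates left block first with indexable columns", {
  set.seed(34)
  ul <- mk_view(matrix(rnorm(8), 4, 2))
  ur <- mk_view(matrix(rnorm(8), 4, 2), prefix = "h")
  out <- coproject(ul, ur, node = "m1")
  expect_equal(dim(out), c(4L, 4L))
  expect_equal(unname(out[, 1:2]), unname(ul))
  for (m in 1:2) expect_equal(unname(out[, 2 + m]), unname(ur[, m]))
  expect_identical(colnames(out), c("m1:L:1", "m1:L:2", "m1:R:1", "m1:R:2"))

  k1 <- coproject(ul[, 1, drop = FALSE], ur[, 1, drop = FALSE])
  expect_equal(ncol(k1), 2L)
  expect_error(coproject(ul, ur[1:3, ]), "row counts")
})

test_that("fitted correlation matches direct maximization of the objective", {
  set.seed(35)
  for (rep in 1:6) {
    n <- sample(10:30, 1)
    di <- sample(2:4, 1); dj <- sample(2:4, 1)
    x <- rand_view(n, di)
    y <- rand_view(n, dj, prefix = "h")
    y[, 1] <- y[, 1] + 0.5 * x[, 1]  # some real signal
    fit <- rcca(x, y, alpha = c(0, 0), k = 1)
    expect_equal(fit$cor[1], cca_rho_oracle(x, y), tolerance = 1e-4)
  }
})

test_that("unregularized correlations are invariant to invertible transforms", {
  set.seed(36)
  x <- rand_view(40, 3)
  y <- rand_view(40, 4, prefix = "h")
  y[, 2] <- y[, 2] + x[, 3]
  base <- rcca(x, y, alpha = c(0, 0))$cor
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  xt <- x %*% A
  dimnames(xt) <- dimnames(x)
  expect_equal(rcca(xt, y, alpha = c(0, 0))$cor, base, tolerance = 1e-6)
})

test_that("the first canonical correlation is non-increasing in the ridge", {
  set.seed(37)
  x <- rand_view(25, 6)
  y <- rand_view(25, 6, prefix = "h")
  y <- y + 0.4 * x
  dimnames(y) <- list(rownames(x), paste0("h", 1:6))
  rhos <- vapply(c(0, 0.1, 1, 10, 100),
                 function(a) rcca(x, y, alpha = c(a, a), k = 1)$cor[1], 0)
  expect_true(all(diff(rhos) <= 1e-10))
})

test_that("weights satisfy generalized orthogonality and the sign convention", {
  set.seed(38)
  x <- rand_view(50, 5)
  y <- rand_view(50, 6, prefix = "h")
  y[, 1:2] <- y[, 1:2] + x[, 1:2]
  fit <- rcca(x, y)
  n <- nrow(x)
  Creg <- crossprod(scale(x, scale = FALSE)) / (n - 1)
  diag(Creg) <- diag(Creg) + fit$alpha["left"]
  gram <- t(fit$w_left) %*% Creg %*% fit$w_left
  expect_equal(unname(gram), diag(fit$k), tolerance = 1e-8)
  for (m in seq_len(fit$k)) {
    expect_gt(fit$w_left[which.max(abs(fit$w_left[, m])), m], 0)
    expect_gt(fit$w_right[which.max(abs(fit$w_right[, m])), m], 0)
  }
  expect_true(all(diff(fit$cor) <= 1e-12))
  expect_true(all(fit$cor >= 0 & fit$cor <= 1))
})

test_that("Laplacian smoothing pulls within-module weights together", {
  wins <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 80; d <- 20
    z <- rnorm(n)
    x <- matrix(rnorm(n * d, sd = 1), n, d)
    x[, 1:8] <- x[, 1:8] + z  # module features share the factor equally
    x <- mk_view(x)
    y <- mk_view(matrix(z + rnorm(n, sd = 0.5), n, 1), prefix = "h")
    L <- rand_laplacian(d, p = 0)  # start from no edges
    A <- matrix(0, d, d); A[1:8, 1:8] <- 1; diag(A) <- 0
    deg <- rowSums(A); inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    L <- -A * tcrossprod(inv); diag(L) <- 1
    plain <- rcca(x, y, k = 1)
    smooth <- rcca(x, y, Li = L, k = 1)
    if (var(smooth$w_left[1:8, 1]) < var(plain$w_left[1:8, 1])) wins <- wins + 1L
  }
  expect_gte(wins, 14L)
})

test_that("degenerate inputs are rejected", {
  x <- rand_view(2, 2)
  expect_error(rcca(x, x), "2 samples")
  x <- rand_view(10, 2)
  y <- x; y[1, 1] <- NA
  expect_error(rcca(x, y), "non-finite")
})
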