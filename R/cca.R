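#' Regularized two-view canonical correlation analysis
#'
#' Finds paired linear projections \eqn{u = \bar{X}_i w_i},
#' \eqn{v = \bar{X}_j w_j} of two sample-aligned views maximizing the
#' correlation of the projected variables, with the within-view covariances
#' regularized by reconditioning:
#' \eqn{\tilde{C}_{ii} = C_{ii} + \alpha_i I} (no network) or
#' \eqn{\tilde{C}_{ii} = C_{ii} + \alpha_i (I + L_i)} when a normalized
#' graph Laplacian is supplied, in which case the quadratic form
#' \eqn{w^\top L w} additionally penalizes weight differences between
#' interacting features.  Each ridge \eqn{\alpha_i} is chosen so the
#' regularized covariance attains (or is bounded by) the target condition
#' number `c`; see [recondition_alpha()] and
#' [recondition_alpha_laplacian()].
#'
#' The solver whitens each view with the inverse square root of its
#' regularized covariance and takes the SVD of the whitened
#' cross-covariance; this is the numerically stable equivalent of the
#' generalized eigenproblem formulation.  Successive components are
#' generalized-orthogonal: \eqn{W^\top \tilde{C} W = I} on both sides.
#' The sign of each weight column is fixed so its largest-magnitude entry
#' is positive.
#'
#' @param xi,xj Sample-aligned view matrices (n x d_i, n x d_j), n > 2.
#' @param Li,Lj Optional normalized Laplacians (d x d, matching each view's
#'   feature count) enabling network smoothing for that side.
#' @param c Target condition number for the regularized within-view
#'   covariances (default 4).
#' @param percent Percentage of the canonical-correlation spectrum retained
#'   when choosing the number of components (default 85); see [choose_k()].
#' @param k Force the number of components instead of using the `percent`
#'   rule.
#' @param alpha Optional length-2 numeric overriding the automatic ridge
#'   strengths (e.g. `c(0, 0)` for unregularized CCA).
#' @return Object of class `"rcca"`: list with weight matrices `w_left`,
#'   `w_right` (features x k), canonical correlations `cor` (descending, in
#'   `[0, 1]`), ridge record `alpha`, `used_laplacian`, the column `centers`
#'   of both views, `k`, and the training scores `scores$left`,
#'   `scores$right` (n x k each).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), paste0("g", 1:3)))
#' y <- x %*% matrix(rnorm(9), 3) + 0.1 * rnorm(60)
#' dimnames(y) <- list(rownames(x), paste0("e", 1:3))
#' fit <- rcca(x, y)
#' fit$cor
#' @export
rcca <- function(xi, xj, Li = NULL, Lj = NULL, c = 4, percent = 85,
                 k = NULL, alpha = NULL) {
  if (nrow(xi) != nrow(xj)) stop("views have different sample counts")
  if (!is.null(rownames(xi)) && !is.null(rownames(xj)) &&
      !identical(rownames(xi), rownames(xj)))
    stop("views are not sample-aligned; run align_samples() first")
  n <- nrow(xi)
  if (n <= 2L) stop("need more than 2 samples")
  if (!all(is.finite(xi)) || !all(is.finite(xj))) stop("non-finite values in views")
  if (!is.null(Li) && !identical(dim(Li), c(ncol(xi), ncol(xi))))
    stop("Li dimension does not match left view feature count")
  if (!is.null(Lj) && !identical(dim(Lj), c(ncol(xj), ncol(xj))))
    stop("Lj dimension does not match right view feature count")

  ci <- colMeans(xi); cj <- colMeans(xj)
  xic <- sweep(xi, 2L, ci, "-"); xjc <- sweep(xj, 2L, cj, "-")
  Cii <- crossprod(xic) / (n - 1)
  Cjj <- crossprod(xjc) / (n - 1)
  Cij <- crossprod(xic, xjc) / (n - 1)

  side <- function(C, L, a_forced) {
    if (is.null(L)) {
      a <- if (is.null(a_forced)) recondition_alpha(C, c) else a_forced
      Creg <- C
      if (a > 0) diag(Creg) <- diag(Creg) + a
    } else {
      a <- if (is.null(a_forced)) recondition_alpha_laplacian(C, c) else a_forced
      Creg <- if (a > 0) C + a * (diag(nrow(C)) + L) else C
    }
    list(alpha = a, W = inv_sqrt_sym(Creg))
  }
  left <- side(Cii, Li, alpha[1L])
  right <- side(Cjj, Lj, alpha[2L])

  s <- svd(left$W %*% Cij %*% right$W)
  rho <- pmin(pmax(s$d, 0), 1)
  kmax <- min(ncol(xi), ncol(xj))
  kk <- if (is.null(k)) choose_k(rho[seq_len(kmax)], percent) else as.integer(k)
  kk <- max(1L, min(kk, kmax))

  wl <- left$W %*% s$u[, seq_len(kk), drop = FALSE]
  wr <- right$W %*% s$v[, seq_len(kk), drop = FALSE]
  wl <- fix_signs(wl); wr <- fix_signs(wr)
  comp <- paste0("c", seq_len(kk))
  dimnames(wl) <- list(colnames(xi), comp)
  dimnames(wr) <- list(colnames(xj), comp)
  ul <- xic %*% wl; ur <- xjc %*% wr
  rownames(ul) <- rownames(xi); rownames(ur) <- rownames(xj)

  structure(list(
    w_left = wl, w_right = wr, cor = rho[seq_len(kk)], k = kk,
    alpha = c(left = left$alpha, right = right$alpha),
    used_laplacian = c(left = !is.null(Li), right = !is.null(Lj)),
    centers = list(left = ci, right = cj),
    feature_ids = list(left = colnames(xi), right = colnames(xj)),
    scores = list(left = ul, right = ur),
    c = c, percent = percent, n = n), class = "rcca")
}

#' @export
print.rcca <- function(x, ...) {
  cat("Regularized CCA:", length(x$feature_ids$left), "x",
      length(x$feature_ids$right), "features,", x$n, "samples\n")
  cat("  components:", x$k, " ridge alpha:",
      format(x$alpha, digits = 4), "\n")
  cat("  canonical correlations:",
      paste(format(x$cor, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.rcca <- function(object, ...) {
  list(left = object$w_left, right = object$w_right)
}

#' Number of components retained from a spectrum
#'
#' PCA-style rule: the largest `k` whose cumulative share of the spectrum's
#' total does not exceed `percent`, with a floor of 1.  Entries below
#' `1e-12` times the leading value are numerical zeros and excluded from
#' the total first.
#'
#' @param values Nonincreasing nonnegative spectrum (e.g. canonical
#'   correlations).
#' @param percent Cutoff percentage in `(0, 100]`.
#' @return Integer `>= 1`.
#' @export
choose_k <- function(values, percent = 85) {
  if (!length(values)) stop("empty spectrum")
  if (percent <= 0 || percent > 100) stop("'percent' must be in (0, 100]")
  if (max(values) <= 0) {
    warning("all-zero spectrum; keeping 1 component")
    return(1L)
  }
  values <- values[values > 1e-12 * values[1L]]
  frac <- cumsum(values) / sum(values)
  max(1L, sum(frac <= percent / 100))
}

#' Project a view with stored centers and weights
#'
#' Computes the canonical variables \eqn{U = (X - \mu) W}.
#'
#' @param x View matrix.
#' @param w Weight matrix (features x k).
#' @param center Column means to subtract (default: those of `x`).
#' @return Score matrix (n x k).
#' @export
project_view <- function(x, w, center = colMeans(x)) {
  if (ncol(x) != nrow(w)) stop("weight rows (", nrow(w),
                               ") do not match view features (", ncol(x), ")")
  out <- sweep(x, 2L, center, "-") %*% w
  rownames(out) <- rownames(x)
  out
}

#' Concatenate the coprojection of two views
#'
#' The merged pseudo-view used at the next hierarchy level: the two score
#' matrices side by side, left block first, with synthetic feature IDs
#' `<node>:<side>:<component>`.
#'
#' @param ul,ur Score matrices with equal row counts (n x k each).
#' @param node Node label used in the synthetic feature IDs.
#' @return Matrix n x (ncol(ul) + ncol(ur)).
#' @export
coproject <- function(ul, ur, node = "node") {
  if (nrow(ul) != nrow(ur)) stop("score matrices have different row counts")
  out <- cbind(ul, ur)
  colnames(out) <- c(paste(node, "L", seq_len(ncol(ul)), sep = ":"),
                     paste(node, "R", seq_len(ncol(ur)), sep = ":"))
  rownames(out) <- rownames(ul)
  out
}

# symmetric inverse square root; eigenvalues below a relative floor are
# treated as zero and projected out (pseudo-inverse behavior)
inv_sqrt_sym <- function(C, tol = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * tol
  if (!any(pos)) stop("covariance matrix is numerically zero")
  v <- e$vectors[, pos, drop = FALSE]
  v %*% (t(v) / sqrt(e$values[pos]))
}

# flip each column so its largest-|entry| is positive (deterministic across
# linear-algebra backends)
fix_signs <- function(w) {
  for (m in seq_len(ncol(w))) {
    i <- which.max(abs(w[, m]))
    if (w[i, m] < 0) w[, m] <- -w[, m]
  }
  w
}
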