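#' Pairwise (multiset) CCA over several views
#'
#' Maximizes the sum of pairwise correlations among all views'
#' canonical variables, subject to unit-variance constraints per view, via
#' the standard SUMCOR generalized-eigenproblem relaxation: the block
#' matrix of whitened cross-covariances
#' \eqn{\tilde{C}_{vv}^{-1/2} C_{vw} \tilde{C}_{ww}^{-1/2}} (zero diagonal
#' blocks) is eigendecomposed, eigenvector blocks are back-transformed
#' through the whitening, and each view's weight vector is rescaled to
#' satisfy its own unit-variance constraint per component.  Within-view
#' covariances are regularized exactly as in [rcca()].
#'
#' @param views List of >= 2 sample-aligned view matrices.
#' @param c Target condition number for regularization (default 4).
#' @param percent Spectrum percentage for component selection (default 85).
#' @param k Force the number of components.
#' @return Object of class `"mcca"`: per-view weight list `w`, `k`, the
#'   leading eigenvalues `spectrum`, per-view ridge `alpha`, the achieved
#'   sum of pairwise correlations of the first component `objective`, and
#'   `scores` (list of n x k score matrices).
#' @export
pcca <- function(views, c = 4, percent = 85, k = NULL) {
  check_multiview(views)
  N <- length(views)
  n <- nrow(views[[1L]])
  nm <- view_names(views)
  cen <- lapply(views, colMeans)
  xc <- lapply(seq_len(N), function(v) sweep(views[[v]], 2L, cen[[v]], "-"))
  Cvv <- lapply(xc, function(x) crossprod(x) / (n - 1))
  alpha <- vapply(Cvv, recondition_alpha, 0, c = c)
  Wh <- lapply(seq_len(N), function(v) {
    Creg <- Cvv[[v]]
    if (alpha[v] > 0) diag(Creg) <- diag(Creg) + alpha[v]
    inv_sqrt_sym(Creg)
  })
  dims <- vapply(views, ncol, 0L)
  off <- cumsum(c(0L, dims))
  M <- matrix(0, sum(dims), sum(dims))
  for (v in seq_len(N - 1L)) for (w in (v + 1L):N) {
    K <- Wh[[v]] %*% (crossprod(xc[[v]], xc[[w]]) / (n - 1)) %*% Wh[[w]]
    M[(off[v] + 1L):off[v + 1L], (off[w] + 1L):off[w + 1L]] <- K
    M[(off[w] + 1L):off[w + 1L], (off[v] + 1L):off[v + 1L]] <- t(K)
  }
  e <- eigen(M, symmetric = TRUE)
  pos <- e$values[e$values > 0]
  kmax <- min(dims)
  kk <- if (is.null(k)) choose_k(pos[seq_len(min(length(pos), kmax))], percent)
        else as.integer(k)
  kk <- max(1L, min(kk, kmax))
  w <- vector("list", N)
  for (v in seq_len(N)) {
    block <- e$vectors[(off[v] + 1L):off[v + 1L], seq_len(kk), drop = FALSE]
    wv <- Wh[[v]] %*% block
    # enforce the per-view unit-variance constraint component-wise
    Creg <- Cvv[[v]]
    if (alpha[v] > 0) diag(Creg) <- diag(Creg) + alpha[v]
    for (m in seq_len(kk)) {
      nrm <- sqrt(drop(crossprod(wv[, m], Creg %*% wv[, m])))
      if (nrm > 1e-12) wv[, m] <- wv[, m] / nrm
    }
    wv <- fix_signs(wv)
    dimnames(wv) <- list(colnames(views[[v]]), paste0("c", seq_len(kk)))
    w[[v]] <- wv
  }
  names(w) <- nm
  scores <- lapply(seq_len(N), function(v) {
    u <- xc[[v]] %*% w[[v]]
    rownames(u) <- rownames(views[[v]])
    u
  })
  names(scores) <- nm
  obj <- sum_pairwise_cor(scores, 1L)
  structure(list(method = "pcca", w = w, k = kk,
                 spectrum = e$values[seq_len(kk)], alpha = alpha,
                 objective = obj, scores = scores, centers = cen,
                 c = c, percent = percent),
            class = "mcca")
}

#' Tensor CCA via CP decomposition of the whitened covariance tensor
#'
#' Maximizes the high-order correlation
#' \eqn{\mathcal{C} \bar{\times}_1 w_1 \cdots \bar{\times}_N w_N} of all
#' views simultaneously, where \eqn{\mathcal{C}} is the order-`N`
#' covariance tensor of the whitened views, under per-view unit-variance
#' constraints.  Solved by greedy rank-1 alternating least squares
#' (higher-order power iterations with deflation): each component's
#' multilinear objective is non-decreasing over iterations, initialization
#' is the leading singular vector of each mode's matricization
#' (deterministic), and convergence is declared when the relative objective
#' change drops below `tol`.
#'
#' @param views List of >= 2 sample-aligned view matrices.
#' @param k Number of components (default 1).
#' @param c Target condition number for regularization (default 4).
#' @param max_iter Maximum ALS iterations per component; `0` is an error
#'   (the method cannot silently return an unoptimized solution).
#' @param tol Relative objective-change convergence threshold.
#' @param element_budget Refuse to materialize a covariance tensor with
#'   more than this many elements (default 1e7); reduce dimensionality
#'   first.
#' @return Object of class `"mcca"` with per-view weights `w`, component
#'   strengths `lambda`, the per-iteration `objective_trace` (list, one
#'   vector per component), a `converged` flag vector and `scores`.
#' @export
tcca <- function(views, k = 1L, c = 4, max_iter = 200L, tol = 1e-8,
                 element_budget = 1e7) {
  check_multiview(views)
  if (max_iter < 1L) stop("'max_iter' must be >= 1: with 0 iterations the ",
                          "solution would be unoptimized")
  N <- length(views)
  n <- nrow(views[[1L]])
  nm <- view_names(views)
  dims <- vapply(views, ncol, 0L)
  if (prod(dims) > element_budget)
    stop("covariance tensor would hold ", format(prod(dims), big.mark = ","),
         " elements (budget ", format(element_budget, big.mark = ","),
         "); reduce dimensionality first")
  cen <- lapply(views, colMeans)
  xc <- lapply(seq_len(N), function(v) sweep(views[[v]], 2L, cen[[v]], "-"))
  alpha <- numeric(N)
  Wh <- vector("list", N)
  for (v in seq_len(N)) {
    Cvv <- crossprod(xc[[v]]) / (n - 1)
    alpha[v] <- recondition_alpha(Cvv, c)
    if (alpha[v] > 0) diag(Cvv) <- diag(Cvv) + alpha[v]
    Wh[[v]] <- inv_sqrt_sym(Cvv)
  }
  y <- lapply(seq_len(N), function(v) xc[[v]] %*% Wh[[v]])  # whitened views

  # order-N covariance tensor, built sample by sample
  TT <- array(0, dim = dims)
  for (s in seq_len(n)) {
    o <- y[[1L]][s, ]
    for (v in 2L:N) o <- outer(o, y[[v]][s, ])
    TT <- TT + o
  }
  TT <- TT / (n - 1)

  kmax <- min(dims)
  kk <- max(1L, min(as.integer(k), kmax))
  a <- lapply(dims, function(d) matrix(0, d, kk))
  lambda <- numeric(kk)
  traces <- vector("list", kk)
  converged <- logical(kk)
  mult_but <- function(TT, vecs, skip) {
    # contract the tensor with every mode's vector except `skip`
    out <- TT
    for (v in rev(seq_len(N))) {
      if (v == skip) next
      out <- apply_mode_vec(out, vecs, v)
    }
    as.numeric(out)
  }
  apply_mode_vec <- function(arr, vecs, v) {
    d <- dim(arr); if (is.null(d)) d <- length(arr)
    perm <- c(v, seq_along(d)[-v])
    m <- matrix(aperm(arr, perm), nrow = d[v])
    res <- drop(crossprod(m, vecs[[v]]))
    if (length(d) > 2L) array(res, dim = d[-v]) else res
  }
  for (comp in seq_len(kk)) {
    vecs <- lapply(seq_len(N), function(v) {
      m <- matrix(aperm(TT, c(v, seq_len(N)[-v])), nrow = dims[v])
      u1 <- svd(m, nu = 1L, nv = 0L)$u[, 1L]
      u1 / sqrt(sum(u1^2))
    })
    obj <- abs(mult_all(TT, vecs))
    trace <- obj
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      for (v in seq_len(N)) {
        g <- mult_but(TT, vecs, v)
        nrm <- sqrt(sum(g^2))
        if (nrm > 1e-300) vecs[[v]] <- g / nrm
      }
      new_obj <- abs(mult_all(TT, vecs))
      trace <- c(trace, new_obj)
      if (abs(new_obj - obj) <= tol * max(obj, 1e-300)) { conv <- TRUE; obj <- new_obj; break }
      obj <- new_obj
    }
    lam <- mult_all(TT, vecs)
    if (lam < 0) { vecs[[1L]] <- -vecs[[1L]]; lam <- -lam }
    lambda[comp] <- lam
    traces[[comp]] <- trace
    converged[comp] <- conv
    for (v in seq_len(N)) a[[v]][, comp] <- vecs[[v]]
    # deflate
    o <- vecs[[1L]]
    for (v in 2L:N) o <- outer(o, vecs[[v]])
    TT <- TT - lam * array(o, dim = dims)
  }
  w <- vector("list", N)
  for (v in seq_len(N)) {
    wv <- Wh[[v]] %*% a[[v]]
    wv <- fix_signs(wv)
    dimnames(wv) <- list(colnames(views[[v]]), paste0("c", seq_len(kk)))
    w[[v]] <- wv
  }
  names(w) <- nm
  scores <- lapply(seq_len(N), function(v) {
    u <- xc[[v]] %*% w[[v]]
    rownames(u) <- rownames(views[[v]])
    u
  })
  names(scores) <- nm
  structure(list(method = "tcca", w = w, k = kk, lambda = lambda,
                 alpha = alpha, objective_trace = traces,
                 converged = converged, scores = scores, centers = cen,
                 c = c),
            class = "mcca")
}

mult_all <- function(TT, vecs) {
  out <- TT
  for (v in rev(seq_along(vecs))) {
    d <- dim(out); if (is.null(d)) d <- length(out)
    if (length(d) == 1L || is.null(dim(out))) {
      out <- sum(out * vecs[[v]])
    } else {
      m <- matrix(out, ncol = d[length(d)])
      out <- array(m %*% vecs[[v]], dim = d[-length(d)])
    }
  }
  as.numeric(out)
}

#' @export
print.mcca <- function(x, ...) {
  cat(toupper(x$method), "fit:", length(x$w), "views,", x$k, "component(s)\n")
  if (x$method == "pcca")
    cat("  first-component pairwise-correlation sum:",
        format(x$objective, digits = 4), "\n")
  if (x$method == "tcca")
    cat("  component strengths:", format(x$lambda, digits = 4),
        " converged:", paste(x$converged, collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.mcca <- function(object, ...) object$w

#' Stack views into a single wide matrix
#'
#' The naive integration baseline: horizontal concatenation of
#' sample-aligned views, feature IDs prefixed with the view name.
#'
#' @param views Non-empty list of sample-aligned view matrices.
#' @return Matrix n x sum(d_v).
#' @export
stack_views <- function(views) {
  if (!is.list(views) || !length(views)) stop("'views' must be a non-empty list")
  lapply(views, check_view)
  ref <- rownames(views[[1L]])
  for (v in views) if (!identical(rownames(v), ref))
    stop("views are not sample-aligned; run align_samples() first")
  nm <- view_names(views)
  out <- do.call(cbind, views)
  colnames(out) <- unlist(lapply(seq_along(views), function(v)
    paste(nm[v], colnames(views[[v]]), sep = ":")))
  out
}

#' Sum of pairwise correlations of one component across views
#'
#' @param scores List of score matrices.
#' @param component Component index.
#' @return Sum over unordered view pairs of the Pearson correlation.
#' @keywords internal
sum_pairwise_cor <- function(scores, component = 1L) {
  N <- length(scores)
  tot <- 0
  for (v in seq_len(N - 1L)) for (w in (v + 1L):N) {
    sv <- scores[[v]][, component]; sw <- scores[[w]][, component]
    if (stats::sd(sv) > 0 && stats::sd(sw) > 0)
      tot <- tot + stats::cor(sv, sw)
  }
  tot
}

check_multiview <- function(views) {
  if (!is.list(views) || length(views) < 2L) stop("need at least 2 views")
  lapply(views, check_view)
  ref <- rownames(views[[1L]])
  for (v in views) if (!identical(rownames(v), ref))
    stop("views are not sample-aligned; run align_samples() first")
  invisible(views)
}

view_names <- function(views) {
  nm <- names(views)
  if (is.null(nm)) nm <- paste0("view", seq_along(views))
  nm[!nzchar(nm)] <- paste0("view", which(!nzchar(nm)))
  nm
}
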