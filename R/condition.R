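#' Condition number of a matrix
#'
#' Ratio of the largest to the smallest singular value, taken over
#' `min(nrow, ncol)` singular values.  For a symmetric positive
#' semidefinite matrix this equals the eigenvalue ratio
#' \eqn{\lambda_{max}/\lambda_{min}}.  When the smallest singular value is
#' below `sigma_max * 1e-14` (double-precision noise floor) the matrix is
#' numerically singular and `Inf` is returned.
#'
#' @param m Nonempty numeric matrix.
#' @return Condition number, `>= 1`, possibly `Inf`.
#' @export
condition_number <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (!length(m)) stop("empty matrix")
  if (!all(is.finite(m))) stop("non-finite values in matrix")
  s <- svd(m, nu = 0L, nv = 0L)$d[seq_len(min(dim(m)))]
  smax <- max(s)
  if (smax == 0) return(Inf)
  smin <- min(s)
  if (smin < smax * 1e-14) Inf else smax / smin
}

#' Condition number of the cross-covariance of two views
#'
#' Computes \eqn{\kappa(C_{ij})} with
#' \eqn{C_{ij} = \bar{X}_i^\top \bar{X}_j / (n-1)} on column-centered
#' views.  The scalar factor is immaterial for the condition number; the
#' centering matches the standardized inputs the integration pipeline uses.
#'
#' @param xi,xj Sample-aligned view matrices (same rows, same order).
#' @return Condition number of the cross-covariance.
#' @export
cross_condition <- function(xi, xj) {
  if (nrow(xi) != nrow(xj)) stop("views have different sample counts")
  if (!is.null(rownames(xi)) && !is.null(rownames(xj)) &&
      !identical(rownames(xi), rownames(xj)))
    stop("views are not sample-aligned; run align_samples() first")
  n <- nrow(xi)
  cij <- crossprod(center_cols(xi), center_cols(xj)) / (n - 1)
  condition_number(cij)
}

#' Select the view pair with the best-conditioned cross-covariance
#'
#' Enumerates all unordered pairs and returns the pair whose
#' cross-covariance has the smallest condition number; ties break
#' lexicographically on `(i, j)`.  A numerically singular pair
#' (`kappa = Inf`) is only returned when every pair is singular.
#'
#' @param views List of >= 2 sample-aligned view matrices.
#' @return Integer vector `c(i, j)` (`i < j`) with attribute `"table"`, a
#'   data frame of all pairs and their condition numbers.
#' @export
select_pair <- function(views) {
  if (length(views) < 2L) stop("need at least 2 views")
  pairs <- utils::combn(length(views), 2L)
  kappa <- apply(pairs, 2L, function(p) cross_condition(views[[p[1L]]], views[[p[2L]]]))
  tab <- data.frame(i = pairs[1L, ], j = pairs[2L, ], kappa = kappa)
  best <- which.min(kappa)  # first minimum = lexicographic tie-break
  structure(c(tab$i[best], tab$j[best]), table = tab)
}

#' Ridge strength attaining a target condition number
#'
#' Reconditioning: for a symmetric PSD matrix `C` with
#' \eqn{\kappa(C) > c}, the ridge
#' \deqn{\alpha = \frac{\lambda_{max}(C) - c\,\lambda_{min}(C)}{c - 1}}
#' makes \eqn{\kappa(C + \alpha I) = c} exactly.  If `C` is already at
#' least as well conditioned as `c`, no ridge is needed and 0 is returned
#' (the formula would go negative; negative ridge is unsound).
#'
#' @param C Symmetric positive semidefinite matrix.
#' @param c Target condition number, `> 1` (default 4).
#' @return Ridge strength `alpha >= 0`.
#' @export
recondition_alpha <- function(C, c = 4) {
  if (c <= 1) stop("'c' must be > 1")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  lmin <- max(min(ev), 0)  # clip numerically negative PSD eigenvalues
  if (lmax <= 0) return(0)
  if (lmin > 0 && lmax / lmin <= c) return(0)
  (lmax - c * lmin) / (c - 1)
}

#' Ridge strength bounding the condition number under Laplacian smoothing
#'
#' When the regularizer is \eqn{\alpha(I + L)} with `L` a normalized graph
#' Laplacian (eigenvalues in `[0, 2]`), Weyl's inequality gives
#' \eqn{\lambda_{max}(C + \alpha(I+L)) \le \lambda_{max}(C) + 3\alpha} and
#' \eqn{\lambda_{min} \ge \lambda_{min}(C) + \alpha}, so
#' \deqn{\alpha = \max\!\left(0, \frac{\lambda_{max}(C) - c\,\lambda_{min}(C)}{c - 3}\right)}
#' guarantees \eqn{\kappa(C + \alpha(I+L)) \le c} for *any* such Laplacian.
#' The bound's denominator requires `c > 3`.
#'
#' @param C Symmetric positive semidefinite matrix.
#' @param c Target condition-number bound, `> 3` (default 4).
#' @return Ridge strength `alpha >= 0`.
#' @export
recondition_alpha_laplacian <- function(C, c = 4) {
  if (c <= 3) stop("'c' must be > 3: the Weyl bound divides by (c - 3) since ",
                   "lambda_max(I + L) can reach 3 for a normalized Laplacian")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  lmin <- max(min(ev), 0)
  if (lmax <= 0) return(0)
  if (lmin > 0 && lmax / lmin <= c) return(0)
  max(0, (lmax - c * lmin) / (c - 3))
}

#' Normalized graph Laplacian on a fixed feature set
#'
#' Builds \eqn{L = I - D^{-1/2} A D^{-1/2}} from an interaction network,
#' restricted and aligned to `feature_ids`.  Nodes absent from the network
#' (or isolated after restriction) get `L_{ii} = 1` and no off-diagonal
#' entries; eigenvalues stay in `[0, 2]`.
#'
#' @param network An `"interaction_network"` (see [read_network()]).
#' @param feature_ids Character vector: the view's feature IDs, in order.
#' @return Dense symmetric `length(feature_ids)` square matrix.
#' @export
normalized_laplacian <- function(network, feature_ids) {
  if (!inherits(network, "interaction_network"))
    stop("'network' must be an interaction_network")
  d <- length(feature_ids)
  A <- matrix(0, d, d, dimnames = list(feature_ids, feature_ids))
  e <- network$edges
  keep <- e$from %in% feature_ids & e$to %in% feature_ids
  e <- e[keep, , drop = FALSE]
  if (nrow(e)) {
    i <- match(e$from, feature_ids); j <- match(e$to, feature_ids)
    A[cbind(i, j)] <- e$weight
    A[cbind(j, i)] <- e$weight
  }
  deg <- rowSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- -A * tcrossprod(inv_sqrt)
  diag(L) <- 1
  L
}

# column-center without attaching attributes
center_cols <- function(x) sweep(x, 2L, colMeans(x), "-")
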