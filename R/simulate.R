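#' Generate multiview data driven by shared latent factors
#'
#' Gaussian linear-factor model: latent factors
#' \eqn{Z \sim N(0, I)} (n x r), per-view loading matrices \eqn{B_v} with
#' *orthonormal rows* scaled by the factor scales, and
#' \eqn{X_v = Z_{\mathrm{vis}(v)} B_v + E_v} with independent Gaussian
#' noise.  Shared factors are visible to every view; each group entry
#' makes its factors visible only to that group's views, which is what
#' creates group structure among the views (views inside a group correlate
#' strongly, views across groups only through shared factors).  Orthonormal
#' loading rows keep every within- and cross-view covariance
#' well-conditioned on its signal subspace, so population quantities
#' (canonical correlations, condition-number orderings) have closed forms.
#'
#' @param n Number of samples (>= 4).
#' @param dims Integer vector of per-view feature counts.
#' @param shared List `list(r =, scale =)`: number and scale of globally
#'   shared factors (r = 0 for none).
#' @param groups List of group entries `list(views =, r =, scale =)`;
#'   factors of a group load only on its member views.
#' @param noise_sd Noise standard deviation, scalar or per view.
#' @param seed Integer seed; generation is bit-reproducible.
#' @param view_names Optional names for the views.
#' @param transform Optional monotone function applied elementwise to each
#'   view after generation (e.g. to emulate count-like marginals).
#' @return List with `views` (list of matrices) and `truth`, an object of
#'   class `"synthetic_truth"` holding `Z`, the per-view loading matrices
#'   `B`, the per-factor visibility map, scales, noise levels and the seed.
#' @export
sim_multiview <- function(n, dims, shared = list(r = 1, scale = 1),
                          groups = list(), noise_sd = 0.3, seed = 1L,
                          view_names = NULL, transform = NULL) {
  if (n < 4L) stop("'n' must be >= 4")
  if (any(dims < 1L)) stop("all view dimensions must be >= 1")
  nv <- length(dims)
  if (is.null(view_names)) view_names <- paste0("view", seq_len(nv))
  noise_sd <- rep_len(noise_sd, nv)
  r_shared <- if (is.null(shared$r)) 0L else as.integer(shared$r)
  for (g in groups) {
    if (is.null(g$views) || is.null(g$r))
      stop("each group needs 'views' and 'r'")
    if (any(g$views < 1L | g$views > nv))
      stop("group refers to view index outside 1..", nv)
  }
  r_total <- r_shared + sum(vapply(groups, function(g) as.integer(g$r), 0L))
  if (r_total < 1L) stop("need at least one factor")

  # factor -> (scale, visible views)
  scales <- numeric(r_total)
  vis <- vector("list", r_total)
  idx <- 0L
  if (r_shared > 0L) {
    scales[seq_len(r_shared)] <- if (is.null(shared$scale)) 1 else shared$scale
    for (f in seq_len(r_shared)) vis[[f]] <- seq_len(nv)
    idx <- r_shared
  }
  for (g in groups) {
    sc <- if (is.null(g$scale)) 1 else g$scale
    for (f in seq_len(g$r)) {
      idx <- idx + 1L
      scales[idx] <- sc
      vis[[idx]] <- sort(as.integer(g$views))
    }
  }
  # per-view visible factor count must fit the feature dimension
  for (v in seq_len(nv)) {
    rv <- sum(vapply(vis, function(s) v %in% s, TRUE))
    if (rv > dims[v])
      stop("view ", view_names[v], " sees ", rv, " factors but has only ",
           dims[v], " features; orthonormal loadings need r <= d")
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n * r_total), n, r_total)
  colnames(Z) <- paste0("f", seq_len(r_total))
  sample_ids <- sprintf("s%03d", seq_len(n))
  rownames(Z) <- sample_ids

  views <- vector("list", nv)
  B <- vector("list", nv)
  for (v in seq_len(nv)) {
    fv <- which(vapply(vis, function(s) v %in% s, TRUE))
    d <- dims[v]
    Bv <- t(qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))[, seq_along(fv), drop = FALSE])
    Bv <- Bv * scales[fv]  # scale each orthonormal row by its factor's scale
    rownames(Bv) <- colnames(Z)[fv]
    X <- Z[, fv, drop = FALSE] %*% Bv +
      matrix(stats::rnorm(n * d, sd = noise_sd[v]), n, d)
    if (!is.null(transform)) X <- transform(X)
    dimnames(X) <- list(sample_ids,
                        paste0(view_names[v], "_g", seq_len(d)))
    colnames(Bv) <- colnames(X)
    views[[v]] <- X
    B[[v]] <- Bv
  }
  names(views) <- names(B) <- view_names
  truth <- structure(list(Z = Z, B = B, factor_scales = scales,
                          factor_views = vis, noise_sd = noise_sd,
                          dims = dims, view_names = view_names,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(views = views, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic multiview truth:", nrow(x$Z), "samples,",
      ncol(x$Z), "factors,", length(x$dims), "views (dims:",
      paste(x$dims, collapse = ", "), ")\n")
  if (!is.null(x$phenotype))
    cat("  phenotype ceiling:", format(x$phenotype$ceiling, digits = 4),
        "(population", format(x$phenotype$ceiling_population, digits = 4), ")\n")
  invisible(x)
}

#' Generate a phenotype from the latent factors
#'
#' \eqn{y = \mathrm{intercept} + Z\beta + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, \sigma^2)}.  Two R-squared ceilings are
#' recorded: the population value
#' \eqn{\sum\beta^2 / (\sum\beta^2 + \sigma^2)} and the realized value
#' computed from the variances of the drawn signal and noise vectors —
#' the ceiling of *this* dataset, which at moderate n can differ from the
#' population value by more than the draw-to-draw tolerance of downstream
#' comparisons.
#'
#' @param truth A `"synthetic_truth"` from [sim_multiview()].
#' @param beta Coefficient vector over the factors (length = number of
#'   factors; zeros for unused factors).
#' @param noise_sd Phenotype noise standard deviation.
#' @param intercept Added constant (e.g. a plausible trait mean).
#' @param seed Integer seed.
#' @return The `truth` object with a `phenotype` element added: named
#'   vector `y`, `beta`, `noise_sd`, `intercept`, realized `ceiling` and
#'   `ceiling_population`.
#' @export
sim_phenotype <- function(truth, beta, noise_sd = 1, intercept = 0, seed = 1L) {
  if (!inherits(truth, "synthetic_truth")) stop("'truth' must be a synthetic_truth")
  r <- ncol(truth$Z)
  if (length(beta) != r)
    stop("'beta' must have one coefficient per factor (", r, ")")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  signal <- drop(truth$Z %*% beta)
  eps <- stats::rnorm(nrow(truth$Z), sd = noise_sd)
  y <- intercept + signal + eps
  names(y) <- rownames(truth$Z)
  pop <- sum(beta^2) / (sum(beta^2) + noise_sd^2)
  realized <- if (noise_sd == 0 && stats::var(signal) > 0) 1 else
    stats::var(signal) / (stats::var(signal) + stats::var(eps))
  truth$phenotype <- list(y = y, beta = beta, noise_sd = noise_sd,
                          intercept = intercept, ceiling = realized,
                          ceiling_population = pop)
  truth
}

#' Generate a module-structured interaction network
#'
#' Stochastic block graph on a feature set: pairs inside a common module
#' are connected with probability `p_within`, pairs without a common
#' module with `p_between`.  Modules may overlap (overlap is allowed and
#' reported).  With modules matching loading support, Laplacian smoothing
#' helps by construction.
#'
#' @param feature_ids Character vector of node IDs.
#' @param modules Named list of feature-ID vectors.
#' @param p_within,p_between Edge probabilities, `p_within > p_between >= 0`.
#' @param seed Integer seed.
#' @return An `"interaction_network"` with unit edge weights.
#' @export
sim_network <- function(feature_ids, modules, p_within, p_between = 0,
                        seed = 1L) {
  if (p_within <= p_between || p_between < 0 || p_within > 1)
    stop("need p_within > p_between >= 0 (and p_within <= 1)")
  unknown <- setdiff(unlist(modules), feature_ids)
  if (length(unknown)) stop("module feature(s) not in feature_ids: ",
                            paste(utils::head(unknown, 5L), collapse = ", "))
  memb <- lapply(feature_ids, function(f)
    which(vapply(modules, function(m) f %in% m, TRUE)))
  overlap <- sum(lengths(memb) > 1L)
  if (overlap) message(overlap, " feature(s) belong to multiple modules")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  d <- length(feature_ids)
  from <- character(0); to <- character(0)
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    p <- if (length(intersect(memb[[i]], memb[[j]]))) p_within else p_between
    if (p > 0 && stats::runif(1L) < p) {
      from <- c(from, feature_ids[i]); to <- c(to, feature_ids[j])
    }
  }
  as_network(from, to, rep(1, length(from)))
}

#' Canned synthetic scenarios
#'
#' Two ready-made study designs used throughout the package's tests and
#' examples:
#'
#' * `"grouped"` — three 6-feature views; views 1 and 2 share six
#'   full-rank latent factors (noise sd 0.3) while view 3 is driven by six
#'   factors of its own.  The cross-covariance of the shared pair is the
#'   only one whose spectrum is signal-dominated, so condition-number pair
#'   selection should merge views 1 and 2 first.
#' * `"flowering"` — a flowering-time-like design with three wide
#'   "genomic" views (60 features, noise sd 0.3) and one narrow
#'   "geoclimate" view (3 features, noise sd 0.6).  A single strong global
#'   factor (scale 2) drives all views and the phenotype
#'   (`y = 60 + 2 z + N(0, 1)`, population ceiling 0.8); two group-factor
#'   pairs — `{mut, clim}` and `{expr, meth}` — give the hierarchy its
#'   structure, making the mutation/geoclimate pair the best-conditioned
#'   level-1 merge.  Integration should predict the phenotype near its
#'   ceiling while every single view is handicapped by its own noise and
#'   width.
#'
#' @param name `"grouped"` or `"flowering"`.
#' @param n Number of samples (defaults: 120 for `"grouped"`, 300 for
#'   `"flowering"`).
#' @param seed Integer seed.
#' @return List with `views`, `truth` (phenotype attached for
#'   `"flowering"`), and for `"flowering"` also `y` for convenience.
#' @export
sim_scenario <- function(name = c("flowering", "grouped"), n = NULL,
                         seed = 1L) {
  name <- match.arg(name)
  if (name == "grouped") {
    if (is.null(n)) n <- 120L
    sim <- sim_multiview(
      n = n, dims = c(6L, 6L, 6L), shared = list(r = 0),
      groups = list(list(views = c(1L, 2L), r = 6L, scale = 1),
                    list(views = 3L, r = 6L, scale = 1)),
      noise_sd = 0.3, seed = seed)
    sim$planted_pair <- c(1L, 2L)
    return(sim)
  }
  if (is.null(n)) n <- 300L
  sim <- sim_multiview(
    n = n, dims = c(60L, 60L, 60L, 3L), shared = list(r = 1, scale = 2),
    groups = list(list(views = c(1L, 2L), r = 2L, scale = 1),
                  list(views = c(3L, 4L), r = 2L, scale = 1)),
    noise_sd = c(0.3, 0.3, 0.3, 0.6), seed = seed,
    view_names = c("expr", "meth", "mut", "clim"))
  beta <- c(2, rep(0, 4))
  sim$truth <- sim_phenotype(sim$truth, beta = beta, noise_sd = 1,
                             intercept = 60, seed = seed + 1000L)
  sim$y <- sim$truth$phenotype$y
  sim$planted_pair <- c(3L, 4L)
  sim
}
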