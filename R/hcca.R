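#' Hierarchical canonical correlation analysis
#'
#' Integrates `N >= 1` sample-aligned views into one joint representation
#' by recursive pairwise CCA.  At every level the pair of remaining
#' datasets whose cross-covariance has the smallest condition number is
#' merged (see [select_pair()]); the pair is coprojected with [rcca()] and
#' replaced by the concatenation of its canonical variables, until a single
#' dataset — the joint representation — remains.  The procedure is fully
#' deterministic.
#'
#' Merged pseudo-views are plain matrices of canonical variables: they
#' carry no interaction network (Laplacian smoothing applies to original
#' feature spaces only) and are not re-standardized, since canonical
#' variables already have unit generalized norm.  The ridge strength is
#' re-estimated from the same condition-number rule at every level.
#'
#' @param views Non-empty list of sample-aligned view matrices, ideally
#'   named.
#' @param networks Optional list (same length as `views`) of normalized
#'   Laplacian matrices or `"interaction_network"` objects (converted with
#'   [normalized_laplacian()]); use `NULL` entries for views without a
#'   network.
#' @param c Target condition number for within-view regularization
#'   (default 4).
#' @param percent Spectrum percentage for component selection (default 85).
#' @param fixed_first_pair Optional integer pair constraining the level-1
#'   merge (e.g. to pin the pair whose association is under study); later
#'   levels revert to condition-number selection.
#' @return Object of class `"hcca"`: list with the joint representation `U`
#'   (n x 2k), the merge tree `root`, a `merge_log` data frame (one row per
#'   merge: level, member views, condition number, ridge strengths, number
#'   of components) and the per-level condition-number tables
#'   (`pair_tables`).
#' @seealso [predict.hcca()], [path_loadings()], [evaluate_joint()]
#' @examples
#' sc <- sim_scenario("grouped", seed = 1)
#' fit <- hcca(sc$views)
#' fit
#' @export
hcca <- function(views, networks = NULL, c = 4, percent = 85,
                 fixed_first_pair = NULL) {
  if (!is.list(views) || !length(views)) stop("'views' must be a non-empty list")
  lapply(views, check_view)
  nm <- names(views)
  if (is.null(nm)) nm <- paste0("view", seq_along(views))
  nm[!nzchar(nm)] <- paste0("view", which(!nzchar(nm)))
  ref <- rownames(views[[1L]])
  for (v in seq_along(views))
    if (!identical(rownames(views[[v]]), ref))
      stop("view ", nm[v], " is not sample-aligned; run align_samples() first")
  if (!is.null(networks)) {
    if (length(networks) != length(views))
      stop("'networks' must have one entry (possibly NULL) per view")
    networks <- lapply(seq_along(views), function(v) {
      L <- networks[[v]]
      if (is.null(L)) return(NULL)
      if (inherits(L, "interaction_network"))
        L <- normalized_laplacian(L, colnames(views[[v]]))
      if (!identical(dim(L), c(ncol(views[[v]]), ncol(views[[v]]))))
        stop("Laplacian for view ", nm[v], " has wrong dimension")
      L
    })
  } else networks <- vector("list", length(views))

  if (!is.null(fixed_first_pair)) {
    fixed_first_pair <- as.integer(fixed_first_pair)
    if (length(fixed_first_pair) != 2L ||
        any(fixed_first_pair < 1L | fixed_first_pair > length(views)) ||
        fixed_first_pair[1L] == fixed_first_pair[2L])
      stop("'fixed_first_pair' must be two distinct view indices in 1..",
           length(views))
    fixed_first_pair <- sort(fixed_first_pair)
  }

  act <- lapply(seq_along(views), function(v)
    list(node = list(kind = "leaf", view = v, name = nm[v],
                     feature_ids = colnames(views[[v]])),
         data = views[[v]], laplacian = networks[[v]]))
  merge_log <- NULL
  pair_tables <- list()
  level <- 0L
  while (length(act) > 1L) {
    level <- level + 1L
    tab <- attr(select_pair(lapply(act, `[[`, "data")), "table")
    if (level == 1L && !is.null(fixed_first_pair)) {
      i <- fixed_first_pair[1L]; j <- fixed_first_pair[2L]
      kap <- tab$kappa[tab$i == i & tab$j == j]
    } else {
      best <- which.min(tab$kappa)
      i <- tab$i[best]; j <- tab$j[best]; kap <- tab$kappa[best]
    }
    pair_tables[[level]] <- tab
    fit <- rcca(act[[i]]$data, act[[j]]$data,
                Li = act[[i]]$laplacian, Lj = act[[j]]$laplacian,
                c = c, percent = percent)
    node_name <- paste0("(", act[[i]]$node$name, "+", act[[j]]$node$name, ")")
    U <- coproject(fit$scores$left, fit$scores$right, node = node_name)
    merge_log <- rbind(merge_log, data.frame(
      level = level, i = i, j = j,
      left = act[[i]]$node$name, right = act[[j]]$node$name,
      kappa = kap, alpha_left = unname(fit$alpha[1L]),
      alpha_right = unname(fit$alpha[2L]), k = fit$k,
      stringsAsFactors = FALSE))
    node <- list(kind = "merge", name = node_name,
                 left = act[[i]]$node, right = act[[j]]$node, fit = fit)
    act <- c(act[-c(i, j)],
             list(list(node = node, data = U, laplacian = NULL)))
  }
  structure(list(U = act[[1L]]$data, root = act[[1L]]$node,
                 merge_log = merge_log, pair_tables = pair_tables,
                 view_names = nm, c = c, percent = percent,
                 n = nrow(act[[1L]]$data)),
            class = "hcca")
}

#' @export
print.hcca <- function(x, ...) {
  nviews <- length(x$view_names)
  cat("Hierarchical CCA:", nviews, "view(s),", x$n, "samples, joint representation",
      nrow(x$U), "x", ncol(x$U), "\n")
  if (!is.null(x$merge_log)) {
    cat("Merge order (condition-number guided, target c =", x$c, "):\n")
    for (r in seq_len(nrow(x$merge_log)))
      cat(sprintf("  level %d: %s + %s  (kappa = %.4g, k = %d)\n",
                  x$merge_log$level[r], x$merge_log$left[r],
                  x$merge_log$right[r], x$merge_log$kappa[r], x$merge_log$k[r]))
  }
  invisible(x)
}

#' @export
summary.hcca <- function(object, ...) {
  structure(list(merge_log = object$merge_log,
                 pair_tables = object$pair_tables,
                 view_names = object$view_names,
                 dim_joint = dim(object$U)), class = "summary.hcca")
}

#' @export
print.summary.hcca <- function(x, ...) {
  cat("Views:", paste(x$view_names, collapse = ", "), "\n")
  cat("Joint representation:", x$dim_joint[1L], "samples x",
      x$dim_joint[2L], "canonical variables\n\n")
  if (!is.null(x$merge_log)) {
    cat("Merge log:\n")
    print(x$merge_log, row.names = FALSE)
    cat("\nPer-level condition-number tables:\n")
    for (l in seq_along(x$pair_tables)) {
      cat(" level", l, "\n")
      print(x$pair_tables[[l]], row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
coef.hcca <- function(object, ...) {
  out <- list()
  walk <- function(node) {
    if (node$kind == "merge") {
      out[[node$name]] <<- list(left = node$fit$w_left, right = node$fit$w_right,
                                cor = node$fit$cor)
      walk(node$left); walk(node$right)
    }
  }
  walk(object$root)
  out
}

#' Project new samples through a fitted hierarchy
#'
#' Replays the merge tree on new data using the stored column centers and
#' weight matrices, producing the joint representation for unseen samples.
#' Feature IDs of each supplied view must match the training views.
#'
#' @param object Fitted `"hcca"` model.
#' @param newviews List of view matrices in the same order (or with the
#'   same names) as at fit time.  Defaults to reproducing the training
#'   representation.
#' @param ... Unused.
#' @return Joint representation matrix for the new samples.
#' @export
predict.hcca <- function(object, newviews = NULL, ...) {
  if (is.null(newviews)) return(object$U)
  if (!is.list(newviews)) stop("'newviews' must be a list of view matrices")
  if (length(newviews) != length(object$view_names))
    stop("expected ", length(object$view_names), " views")
  if (!is.null(names(newviews)) && all(nzchar(names(newviews)))) {
    miss <- setdiff(object$view_names, names(newviews))
    if (length(miss)) stop("missing view(s): ", paste(miss, collapse = ", "))
    newviews <- newviews[object$view_names]
  }
  eval_node <- function(node) {
    if (node$kind == "leaf") {
      x <- newviews[[node$view]]
      if (!identical(colnames(x), node$feature_ids))
        stop("feature IDs of view '", node$name, "' do not match the training view")
      return(x)
    }
    xl <- eval_node(node$left); xr <- eval_node(node$right)
    ul <- project_view(xl, node$fit$w_left, node$fit$centers$left)
    ur <- project_view(xr, node$fit$w_right, node$fit$centers$right)
    coproject(ul, ur, node = node$name)
  }
  eval_node(object$root)
}

#' Plot the merge tree of a fitted hierarchy
#'
#' Dendrogram-style display: leaves are the input views, merge heights are
#' the levels, and each join is annotated with the condition number that
#' selected it.
#'
#' @param x Fitted `"hcca"` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hcca <- function(x, ...) {
  nv <- length(x$view_names)
  if (nv < 2L) {
    graphics::plot(0, 0, type = "n", axes = FALSE, xlab = "", ylab = "")
    graphics::text(0, 0, paste("single view:", x$view_names))
    return(invisible(x))
  }
  pos <- new.env()
  leaf_x <- 0
  assign_pos <- function(node) {
    if (node$kind == "leaf") {
      leaf_x <<- leaf_x + 1
      assign(node$name, c(leaf_x, 0), envir = pos)
      return(c(leaf_x, 0))
    }
    pl <- assign_pos(node$left); pr <- assign_pos(node$right)
    p <- c((pl[1L] + pr[1L]) / 2, max(pl[2L], pr[2L]) + 1)
    assign(node$name, p, envir = pos)
    p
  }
  assign_pos(x$root)
  graphics::plot(NA, xlim = c(0.5, nv + 0.5),
                 ylim = c(-0.4, nrow(x$merge_log) + 0.5),
                 axes = FALSE, xlab = "", ylab = "merge level",
                 main = "HCCA merge tree", ...)
  graphics::axis(2, at = 0:nrow(x$merge_log))
  draw <- function(node) {
    if (node$kind == "leaf") {
      p <- get(node$name, envir = pos)
      graphics::text(p[1L], -0.2, node$name, cex = 0.9)
      return(invisible())
    }
    p <- get(node$name, envir = pos)
    pl <- get(node$left$name, envir = pos)
    pr <- get(node$right$name, envir = pos)
    graphics::segments(pl[1L], pl[2L], pl[1L], p[2L])
    graphics::segments(pr[1L], pr[2L], pr[1L], p[2L])
    graphics::segments(pl[1L], p[2L], pr[1L], p[2L])
    kap <- x$merge_log$kappa[match(node$name,
      paste0("(", x$merge_log$left, "+", x$merge_log$right, ")"))]
    graphics::text(p[1L], p[2L] + 0.15,
                   bquote(kappa == .(format(kap, digits = 3))), cex = 0.8)
    draw(node$left); draw(node$right)
  }
  draw(x$root)
  invisible(x)
}

.hcca_model_version <- 1L

#' Save or restore a fitted hierarchy
#'
#' The on-disk format is versioned; files written by an incompatible
#' version, or truncated/corrupt files, are rejected.
#'
#' @param model Fitted `"hcca"` model.
#' @param path File path.
#' @return `write_hcca()`: `path` invisibly; `read_hcca()`: the model.
#' @export
write_hcca <- function(model, path) {
  if (!inherits(model, "hcca")) stop("'model' must be an hcca fit")
  saveRDS(list(format = "hcca_model", version = .hcca_model_version,
               model = model), path)
  invisible(path)
}

#' @rdname write_hcca
#' @export
read_hcca <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file (truncated or corrupt): ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "hcca_model"))
    stop("not an hcca model file")
  if (!identical(obj$version, .hcca_model_version))
    stop("model file version ", obj$version, " is not supported (expected ",
         .hcca_model_version, ")")
  obj$model
}
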