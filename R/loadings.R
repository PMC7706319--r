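#' Canonical factor loadings (structure correlation coefficients)
#'
#' Pearson correlation of every original feature with each of the first
#' `n_components` canonical variables.  Loadings place features from
#' different views in one shared component space, so features of one view
#' can be associated with features of another by proximity of their
#' loading vectors.  Constant (zero-variance) features get loading 0 and
#' are flagged rather than propagating `NaN`.
#'
#' @param x View matrix (n x features), same sample order as `u`.
#' @param u Canonical-variable matrix (n x >= n_components).
#' @param n_components Number of leading canonical variables to correlate
#'   against (default 2).
#' @param view Optional label recorded as the loading table's source view.
#' @param node Optional label of the hierarchy node `u` came from.
#' @return Object of class `"loading_table"`: a features x components
#'   matrix of correlations in `[-1, 1]` with attributes `view`, `node`
#'   and `constant` (logical flag per feature).
#' @export
factor_loadings <- function(x, u, n_components = 2L, view = NULL, node = NULL) {
  if (nrow(x) != nrow(u)) stop("sample counts differ between view and scores")
  if (nrow(x) < 3L) stop("need at least 3 samples for correlation loadings")
  if (n_components > ncol(u))
    stop("n_components (", n_components, ") exceeds available canonical variables (",
         ncol(u), ")")
  u <- u[, seq_len(n_components), drop = FALSE]
  sx <- apply(x, 2L, stats::sd)
  su <- apply(u, 2L, stats::sd)
  const <- sx == 0
  L <- matrix(0, ncol(x), n_components,
              dimnames = list(colnames(x), paste0("c", seq_len(n_components))))
  ok <- !const
  if (any(ok) && all(su > 0)) L[ok, ] <- stats::cor(x[, ok, drop = FALSE], u)
  L[!is.finite(L)] <- 0
  L <- pmin(pmax(L, -1), 1)
  structure(L, class = c("loading_table", "matrix"),
            view = view, node = node, constant = const)
}

#' @export
print.loading_table <- function(x, ...) {
  cat("canonical factor loadings:", nrow(x), "features x", ncol(x),
      "components")
  if (!is.null(attr(x, "view"))) cat(" (view ", attr(x, "view"), ")", sep = "")
  if (!is.null(attr(x, "node"))) cat(" at node ", attr(x, "node"), sep = "")
  cat("\n")
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Loadings of a view's features at a node on its path to the root
#'
#' In a hierarchy the canonical variables relevant to a view are those of
#' the merge nodes on the path from the view's leaf to the root; loadings
#' can be computed at each such level, and later levels fold in
#' information from the views merged after it.
#'
#' @param model Fitted `"hcca"` model.
#' @param view View name or index.
#' @param level Which merge on the path to use: 1 = the view's first merge,
#'   up to the root.
#' @param views The training views (needed to recover the original feature
#'   matrix).
#' @param n_components Number of components (default 2).
#' @return A `"loading_table"` of the view's features against that node's
#'   canonical variables.
#' @export
path_loadings <- function(model, view, views, level = 1L, n_components = 2L) {
  if (!inherits(model, "hcca")) stop("'model' must be an hcca fit")
  if (is.character(view)) {
    vi <- match(view, model$view_names)
    if (is.na(vi)) stop("unknown view '", view, "'")
  } else vi <- as.integer(view)
  vname <- model$view_names[vi]
  # collect merge nodes from the leaf up to the root
  path <- list()
  walk <- function(node) {
    if (node$kind == "leaf") return(identical(node$view, vi))
    if (walk(node$left) || walk(node$right)) {
      path[[length(path) + 1L]] <<- node
      TRUE
    } else FALSE
  }
  if (!walk(model$root)) stop("view not present in the hierarchy")
  if (level < 1L || level > length(path))
    stop("level must index a merge on the path from view '", vname,
         "' to the root; valid levels: 1..", length(path))
  node <- path[[level]]
  # scores of that node's coprojection (training-time, recomputed from tree)
  u <- node_scores(node)
  x <- views[[vi]]
  if (!identical(colnames(x), leaf_feature_ids(model$root, vi)))
    stop("supplied view does not match the training view '", vname, "'")
  factor_loadings(x, u, n_components = n_components, view = vname,
                  node = node$name)
}

node_scores <- function(node) {
  stopifnot(node$kind == "merge")
  coproject(node$fit$scores$left, node$fit$scores$right, node = node$name)
}

leaf_feature_ids <- function(node, vi) {
  if (node$kind == "leaf")
    return(if (identical(node$view, vi)) node$feature_ids else NULL)
  out <- leaf_feature_ids(node$left, vi)
  if (is.null(out)) out <- leaf_feature_ids(node$right, vi)
  out
}

#' Nearest features in canonical-loading space
#'
#' Ranks the features of one loading table by Euclidean distance (over the
#' first `n_components` loadings) to a target feature of another table.
#' Both tables must come from the same hierarchy node: loadings computed
#' at different nodes live in different component spaces and cannot be
#' compared.
#'
#' @param table_a `"loading_table"` containing the target feature.
#' @param table_b `"loading_table"` whose features are ranked.
#' @param target_id Feature ID in `table_a`.
#' @param m Number of nearest features to return (default 100); all if `m`
#'   exceeds the table size.
#' @param n_components Number of leading components used for the distance
#'   (default 2).
#' @return Data frame with columns `rank`, `feature_id`, `distance`,
#'   ascending by distance with ties broken by feature ID.
#' @export
nearest_features <- function(table_a, table_b, target_id, m = 100L,
                             n_components = 2L) {
  if (!is.null(attr(table_a, "node")) && !is.null(attr(table_b, "node")) &&
      !identical(attr(table_a, "node"), attr(table_b, "node")))
    stop("loading tables come from different hierarchy nodes (",
         attr(table_a, "node"), " vs ", attr(table_b, "node"),
         "); recompute both at the same node")
  if (n_components > ncol(table_a) || n_components > ncol(table_b))
    stop("n_components exceeds the tables' component count")
  ti <- match(target_id, rownames(table_a))
  if (is.na(ti)) stop("unknown target feature '", target_id, "'")
  tv <- unclass(table_a)[ti, seq_len(n_components)]
  B <- unclass(table_b)[, seq_len(n_components), drop = FALSE]
  d <- sqrt(colSums((t(B) - tv)^2))
  ord <- order(d, rownames(table_b))
  take <- utils::head(ord, m)
  data.frame(rank = seq_along(take), feature_id = rownames(table_b)[take],
             distance = unname(d[take]), stringsAsFactors = FALSE)
}

#' Export a ranked feature list as TSV
#'
#' Writes `rank`, `feature_id`, `distance` columns deterministically, for
#' consumption by external enrichment tools.
#'
#' @param ranked Data frame from [nearest_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_gene_list <- function(ranked, path) {
  df <- ranked[, c("rank", "feature_id", "distance"), drop = FALSE]
  df$distance <- format(df$distance, digits = 12, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
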