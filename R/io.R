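#' Read a sample-by-feature matrix from delimited text
#'
#' Views are plain numeric matrices with unique sample IDs as row names and
#' unique feature IDs as column names.  Files are tab- or comma-separated with
#' a header row of feature IDs and a first column of sample IDs; the
#' `orientation` argument says which axis is on the rows of the *file*, and
#' the returned matrix is always samples x features.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"samples_rows"` (default) if file rows are samples,
#'   `"features_rows"` if the file stores the transposed matrix.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param na_action `"error"` (default) rejects missing values;
#'   `"drop_features"` removes any feature column containing missing values
#'   (with a message).
#' @return Numeric matrix, samples x features, with ID dimnames.
#' @seealso [write_omics()], [align_samples()]
#' @export
read_omics <- function(path, orientation = c("samples_rows", "features_rows"),
                       sep = NULL, na_action = c("error", "drop_features")) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("expected an ID column plus at least one data column in ", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop(sprintf("non-numeric value %s at data row %d, column '%s' of %s",
                   dQuote(col[bad]), bad, colnames(body)[j], path))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "features_rows") m <- t(m)
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup)) stop("duplicate sample ID(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup)) stop("duplicate feature ID(s): ", paste(dup, collapse = ", "))
  if (anyNA(m)) {
    if (na_action == "error") {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at sample '%s', feature '%s' (use na_action = \"drop_features\")",
                   rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
    }
    drop <- colSums(is.na(m)) > 0L
    message("dropping ", sum(drop), " feature(s) with missing values")
    m <- m[, !drop, drop = FALSE]
    if (ncol(m) == 0L) stop("all features contained missing values")
  }
  check_view(m)
  m
}

#' Write a view matrix as tab-separated text
#'
#' Inverse of [read_omics()] with `orientation = "samples_rows"`; full
#' double precision is retained so a read/write round trip is exact to
#' formatting tolerance.
#'
#' @param x Numeric matrix with sample row names and feature column names.
#' @param path Output path.
#' @param id_col Name for the leading sample-ID column.
#' @return `path`, invisibly.
#' @export
write_omics <- function(x, path, id_col = "sample_id") {
  check_view(x)
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a view matrix
#'
#' @param x Object to validate.
#' @return `x`, invisibly; errors on violation.
#' @keywords internal
check_view <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("view must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("view must carry sample row names and feature column names")
  if (anyDuplicated(rownames(x))) stop("duplicate sample IDs in view")
  if (anyDuplicated(colnames(x))) stop("duplicate feature IDs in view")
  invisible(x)
}

#' Read an undirected weighted interaction network
#'
#' Expects a 2- or 3-column edge list (node, node, optional nonnegative
#' weight, default 1), STRING-style.  The network is made undirected:
#' duplicate edges (in either orientation) keep the maximum weight and
#' self-loops are dropped.
#'
#' @param path Path to a whitespace/tab-separated edge list.  Lines starting
#'   with `#` are ignored.
#' @param min_weight Edges with weight strictly below this value are dropped.
#' @return An object of class `"interaction_network"`: a list with `edges`
#'   (data frame: `from`, `to`, `weight`) and `nodes` (character vector).
#' @export
read_network <- function(path, min_weight = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(as_network(character(0), character(0), numeric(0)))
  parts <- strsplit(lines, "[\t ]+")
  nfield <- lengths(parts)
  bad <- which(nfield < 2L)
  if (length(bad)) stop("malformed network line ", bad[1L], ": ", dQuote(lines[bad[1L]]))
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  w <- vapply(parts, function(p) {
    if (length(p) >= 3L) suppressWarnings(as.numeric(p[[3L]])) else 1
  }, 0)
  if (anyNA(w)) stop("malformed network line ", which(is.na(w))[1L], ": non-numeric weight")
  if (any(w < 0)) stop("negative edge weight at line ", which(w < 0)[1L])
  as_network(from, to, w, min_weight)
}

as_network <- function(from, to, weight, min_weight = 0) {
  keep <- from != to & weight >= min_weight
  from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  # canonical orientation, then dedup keeping max weight
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (length(key)) {
    w <- tapply(weight, key, max)
    uk <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(uk, `[[`, "", 1L),
                        to = vapply(uk, `[[`, "", 2L),
                        weight = as.numeric(w),
                        stringsAsFactors = FALSE, row.names = NULL)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  structure(list(edges = edges, nodes = sort(unique(c(edges$from, edges$to)))),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read gene intervals from a BED file
#'
#' BED coordinates are 0-based, half-open.  At least four columns are
#' required (chrom, start, end, name); a sixth column, if present, is used
#' as the strand.  Repeated gene IDs are kept (multi-interval genes) and
#' reported with a message.
#'
#' @param path Path to a BED4+ file.
#' @param one_based Set `TRUE` for GFF-style 1-based inclusive input, which
#'   is converted to the internal 0-based half-open convention on read.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_intervals <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track|browser)", trimws(lines))
  lines <- lines[keep]
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) < 4L)
  if (length(bad)) stop("BED line ", bad[1L], " has fewer than 4 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  name <- vapply(parts, `[[`, "", 4L)
  strand <- vapply(parts, function(p) if (length(p) >= 6L && p[[6L]] %in% c("+", "-")) p[[6L]] else ".", "")
  if (anyNA(start) || anyNA(end))
    stop("non-integer coordinate at BED line ", which(is.na(start) | is.na(end))[1L])
  if (one_based) start <- start - 1L
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stop(sprintf("invalid interval at BED line %d: start %d, end %d", bad[1L], start[bad[1L]], end[bad[1L]]))
  dup <- unique(name[duplicated(name)])
  if (length(dup))
    message("gene ID(s) with multiple intervals kept: ", paste(utils::head(dup, 5L), collapse = ", "))
  data.frame(gene_id = name, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read per-sample genomic events
#'
#' Events (e.g. SNPs or methylated-site read counts) are rows of
#' `sample_id`, `chrom`, `pos` (0-based) and an optional positive `count`
#' (default 1).
#'
#' @param path Tab-separated file with a header.
#' @return Data frame with columns `sample_id`, `chrom`, `pos`, `count`.
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "chrom", "pos")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("events file lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$count)) df$count <- 1L
  if (any(df$pos < 0)) stop("negative event position at row ", which(df$pos < 0)[1L])
  if (any(df$count <= 0)) stop("non-positive event count at row ", which(df$count <= 0)[1L])
  df[, c("sample_id", "chrom", "pos", "count")]
}

#' Read a phenotype vector keyed by sample ID
#'
#' @param path 2-column tab-separated file (sample_id, value) with a header.
#' @return Named numeric vector.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs 2 columns (sample_id, value)")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ID(s) in phenotype: ",
                               ids[duplicated(ids)][1L])
  v <- df[[2L]]
  if (!is.numeric(v)) stop("phenotype values must be numeric")
  names(v) <- ids
  v
}

#' Write a phenotype vector
#'
#' @param y Named numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(y, path) {
  utils::write.table(data.frame(sample_id = names(y),
                                value = format(y, digits = 17, trim = TRUE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align views (and optionally a phenotype) on a common sample set
#'
#' Restricts every view to the sorted intersection of all sample-ID sets
#' (including the phenotype's names when given) and reorders rows so every
#' output shares the same sample order.  Alignment is idempotent.
#'
#' @param views List of view matrices (see [read_omics()]).
#' @param phenotype Optional named numeric vector.
#' @return List with `views` (aligned list) and `phenotype` (aligned vector
#'   or `NULL`).
#' @export
align_samples <- function(views, phenotype = NULL) {
  if (!is.list(views) || !length(views)) stop("'views' must be a non-empty list")
  lapply(views, check_view)
  common <- Reduce(intersect, lapply(views, rownames))
  if (!is.null(phenotype)) {
    if (is.null(names(phenotype))) stop("phenotype must be a named vector")
    common <- intersect(common, names(phenotype))
  }
  if (!length(common)) {
    counts <- vapply(views, nrow, 0L)
    stop("no common samples across inputs (per-view sample counts: ",
         paste(counts, collapse = ", "), ")")
  }
  common <- sort(common)
  out <- lapply(views, function(v) v[common, , drop = FALSE])
  names(out) <- names(views)
  list(views = out,
       phenotype = if (is.null(phenotype)) NULL else phenotype[common])
}
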