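#' Log-transform count-like values after adding a pseudocount
#'
#' Elementwise `log_base(x + pseudocount)`, the usual skewness-removing
#' transform for normalized read counts.
#'
#' @param x View matrix with nonnegative values.
#' @param pseudocount Added before taking logs (default 1).
#' @param base Logarithm base (default 10).
#' @return Transformed matrix, same shape and dimnames.
#' @export
log_pseudo <- function(x, pseudocount = 1, base = 10) {
  check_view(x)
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  out <- log(x + pseudocount, base = base)
  dimnames(out) <- dimnames(x)
  out
}

#' Standardize each feature across samples
#'
#' Centers every feature column to mean 0 and scales to sample standard
#' deviation 1 (denominator `n - 1`).  Constant columns cannot be scaled;
#' they are set to all zeros with a warning so that feature IDs stay stable
#' (a zero column carries no correlation signal downstream).
#'
#' @param x View matrix with at least 2 samples.
#' @return Standardized matrix.
#' @export
zscore_features <- function(x) {
  check_view(x)
  if (nrow(x) < 2L) stop("z-scoring needs at least 2 samples")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  if (any(const)) {
    warning(sum(const), " constant feature(s) set to zero: ",
            paste(utils::head(colnames(x)[const], 5L), collapse = ", "))
    sd[const] <- 1
  }
  out <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  out[, const] <- 0
  out
}

#' Keep the k features with the highest variance
#'
#' Sample variance (denominator `n - 1`) per feature; ties at the cutoff are
#' broken in favor of the earlier column.  Surviving features keep their
#' original column order.  Run on pre-normalization values in the default
#' genomics pipeline, before [zscore_features()].
#'
#' @param x View matrix.
#' @param k Number of features to keep; if `k >= ncol(x)`, `x` is returned
#'   unchanged.
#' @return Matrix with at most `k` columns.
#' @export
top_variance_features <- function(x, k) {
  check_view(x)
  if (k < 1L) stop("'k' must be >= 1")
  d <- ncol(x)
  if (k >= d) return(x)
  v <- apply(x, 2L, stats::var)
  keep <- sort(order(-v, seq_len(d))[seq_len(k)])
  x[, keep, drop = FALSE]
}

#' Count genomic events per gene within flanked windows
#'
#' Builds a samples x genes matrix whose cells sum the counts of events
#' falling in the half-open window `[start - flank, end + flank)` of each
#' gene (clipped at 0) on the matching chromosome.  An event inside several
#' flanked windows contributes to each of them.  Flanks are symmetric, so
#' strand is irrelevant.
#'
#' @param events Data frame of events (see [read_events()]).
#' @param genes Data frame of intervals (see [read_intervals()]).
#' @param flank Nonnegative flank size in bp (default 500).
#' @param samples Optional character vector fixing the output's sample set
#'   and order (samples with no events get all-zero rows); defaults to the
#'   samples present in `events`.
#' @return Numeric matrix, samples x genes.  Multi-interval genes contribute
#'   one column per interval occurrence summed under one gene ID.
#' @export
count_events_per_gene <- function(events, genes, flank = 500L, samples = NULL) {
  if (flank < 0L) stop("'flank' must be >= 0")
  if (is.null(samples)) samples <- sort(unique(as.character(events$sample_id)))
  gene_ids <- unique(genes$gene_id)
  out <- matrix(0, length(samples), length(gene_ids),
                dimnames = list(samples, gene_ids))
  if (!nrow(events) || !nrow(genes)) return(out)
  ev <- events[events$sample_id %in% samples, , drop = FALSE]
  si <- match(ev$sample_id, samples)
  for (g in seq_len(nrow(genes))) {
    lo <- max(0L, genes$start[g] - flank)
    hi <- genes$end[g] + flank
    hit <- ev$chrom == genes$chrom[g] & ev$pos >= lo & ev$pos < hi
    if (any(hit)) {
      gi <- match(genes$gene_id[g], gene_ids)
      tot <- tapply(ev$count[hit], si[hit], sum)
      rows <- as.integer(names(tot))
      out[cbind(rows, gi)] <- out[cbind(rows, gi)] + as.numeric(tot)
    }
  }
  out
}

#' Default per-view genomics preprocessing pipeline
#'
#' Applies, in order: optional log transform with pseudocount, the
#' top-variance feature filter on pre-normalization values, and per-feature
#' z-scoring.
#'
#' @param x View matrix.
#' @param log_transform Apply [log_pseudo()] first?
#' @param top_k Number of highest-variance features to keep (`Inf` keeps all).
#' @param pseudocount,base Passed to [log_pseudo()].
#' @return Preprocessed matrix.
#' @export
preprocess_view <- function(x, log_transform = FALSE, top_k = Inf,
                            pseudocount = 1, base = 10) {
  if (log_transform) x <- log_pseudo(x, pseudocount, base)
  if (is.finite(top_k)) x <- top_variance_features(x, top_k)
  zscore_features(x)
}
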