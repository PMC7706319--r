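# Independent oracles and small fixture builders used across the suite.

# samples x features matrix with IDs
mk_view <- function(values, n = nrow(values), d = ncol(values),
                    prefix = "g", samples = NULL) {
  m <- as.matrix(values)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(m)))
  dimnames(m) <- list(samples, paste0(prefix, seq_len(ncol(m))))
  m
}

rand_view <- function(n, d, prefix = "g", sd = 1) {
  mk_view(matrix(rnorm(n * d, sd = sd), n, d), prefix = prefix)
}

# brute-force event-per-gene counter: explicit double loop over all
# event x gene pairs
brute_count <- function(events, genes, flank = 500L, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(events$sample_id))
  gene_ids <- unique(genes$gene_id)
  out <- matrix(0, length(samples), length(gene_ids),
                dimnames = list(samples, gene_ids))
  for (e in seq_len(nrow(events))) {
    if (!(events$sample_id[e] %in% samples)) next
    for (g in seq_len(nrow(genes))) {
      lo <- max(0L, genes$start[g] - flank)
      hi <- genes$end[g] + flank
      if (events$chrom[e] == genes$chrom[g] &&
          events$pos[e] >= lo && events$pos[e] < hi) {
        out[events$sample_id[e], genes$gene_id[g]] <-
          out[events$sample_id[e], genes$gene_id[g]] + events$count[e]
      }
    }
  }
  out
}

# direct numerical maximization of the two-view correlation objective over
# unit-sphere weight pairs (multi-start BFGS); independent of the SVD path
cca_rho_oracle <- function(xi, xj, n_starts = 8L) {
  xic <- scale(xi, scale = FALSE); xjc <- scale(xj, scale = FALSE)
  di <- ncol(xi); dj <- ncol(xj)
  obj <- function(w) {
    wi <- w[seq_len(di)]; wj <- w[di + seq_len(dj)]
    ui <- xic %*% wi; uj <- xjc %*% wj
    den <- sqrt(sum(ui^2) * sum(uj^2))
    if (den < 1e-12) return(0)
    -abs(sum(ui * uj) / den)
  }
  best <- 0
  for (s in seq_len(n_starts)) {
    w0 <- rnorm(di + dj)
    fit <- optim(w0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    best <- max(best, -fit$value)
  }
  best
}

# random symmetric positive definite matrix with a prescribed eigenvalue range
rand_spd <- function(d, ev = sort(runif(d, 0.1, 20), decreasing = TRUE)) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  q %*% (t(q) * ev)
}

# normalized Laplacian of an Erdos-Renyi graph on d nodes
rand_laplacian <- function(d, p = 0.3) {
  A <- matrix(0, d, d)
  up <- upper.tri(A)
  A[up] <- as.numeric(runif(sum(up)) < p)
  A <- A + t(A)
  deg <- rowSums(A)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- -A * tcrossprod(inv)
  diag(L) <- 1
  L
}

# exhaustive pair enumeration oracle for select_pair
brute_best_pair <- function(views) {
  best <- NULL; best_k <- Inf
  N <- length(views)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    k <- cross_condition(views[[i]], views[[j]])
    if (k < best_k) { best_k <- k; best <- c(i, j) }
  }
  best
}

# small, fast SVR settings for unit tests
tiny_grid <- svr_grid(cost = c(1, 10), epsilon = 0.1, gamma_scale = 1)
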