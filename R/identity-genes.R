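#' Parameters of the resampling-based identity-gene caller
#'
#' The caller repeats, `n_reps` times: draw `n_cells_per_cluster` cells from
#' every cluster without replacement, compute each gene's `q`-quantile
#' expression over the pooled draw, and score the gene a hit for a cluster
#' when at least `in_frac` of that cluster's drawn cells exceed the
#' threshold while no other cluster exceeds it in more than `out_frac` of
#' its drawn cells.  Genes with more than `min_hits` hits for a cluster are
#' its identity genes.  Defaults are the published criterion: 100 cells per
#' cluster, 85th percentile, 60% in / 40% out, 100 repetitions, more than
#' 30 hits.
#'
#' @param n_cells_per_cluster cells drawn per cluster and repetition.
#' @param q quantile defining "high expression", in (0, 1).
#' @param in_frac minimum fraction of the target cluster's drawn cells above
#'   threshold.
#' @param out_frac maximum fraction allowed in any other cluster.
#' @param n_reps number of resampling repetitions.
#' @param min_hits a gene is called when its hit count is strictly greater
#'   than this.
#' @param strict_greater compare expression with `>` (default) or `>=`
#'   against the threshold.
#' @param undersized_clusters `"fail"` (default) or `"resample"` (with
#'   replacement) when a cluster has fewer than `n_cells_per_cluster` cells.
#' @return list of class `identity_params`.
#' @export
identity_params <- function(n_cells_per_cluster = 100L, q = 0.85,
                            in_frac = 0.60, out_frac = 0.40,
                            n_reps = 100L, min_hits = 30L,
                            strict_greater = TRUE,
                            undersized_clusters = c("fail", "resample")) {
  p <- list(n_cells_per_cluster = as.integer(n_cells_per_cluster), q = q,
            in_frac = in_frac, out_frac = out_frac,
            n_reps = as.integer(n_reps), min_hits = as.integer(min_hits),
            strict_greater = isTRUE(strict_greater),
            undersized_clusters = match.arg(undersized_clusters))
  if (p$q <= 0 || p$q >= 1) stop("'q' must lie in (0, 1)")
  if (!(p$out_frac >= 0 && p$out_frac < p$in_frac && p$in_frac <= 1))
    stop("need 0 <= out_frac < in_frac <= 1")
  if (p$min_hits > p$n_reps) stop("'min_hits' cannot exceed 'n_reps'")
  if (p$n_cells_per_cluster < 1 || p$n_reps < 1)
    stop("counts must be positive")
  structure(p, class = "identity_params")
}

#' Quantile expression threshold for one gene
#'
#' The `q`-quantile of a gene's expression over a set of cells, using linear
#' interpolation between order statistics (the common quantile default).
#'
#' @param values non-negative expression counts, non-empty.
#' @param q quantile in (0, 1).
#' @return scalar threshold.
#' @examples
#' gene_percentile_threshold(c(0, 0, 0, 10), 0.85)
#' @export
gene_percentile_threshold <- function(values, q = 0.85) {
  if (length(values) == 0) stop("'values' must be non-empty")
  if (any(values < 0)) stop("'values' must be non-negative")
  unname(quantile(as.numeric(values), probs = q, type = 7, names = FALSE))
}

# row-wise type-7 quantiles of a dense matrix, vectorized via row sorting
row_quantiles <- function(m, q) {
  n <- ncol(m)
  if (n == 1L) return(as.numeric(m[, 1]))
  srt <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
  h <- (n - 1) * q
  lo <- floor(h)
  x_lo <- srt[, lo + 1L]
  if (lo + 2L > n) return(as.numeric(x_lo))
  x_hi <- srt[, lo + 2L]
  as.numeric(x_lo + (h - lo) * (x_hi - x_lo))
}

#' Call cell-type-identity genes by percentile resampling
#'
#' Implements the repeated-subsampling identity-gene criterion (see
#' [identity_params()]).  The quantile threshold is computed per gene over
#' the pooled subsample of all clusters.  With `in_frac > out_frac` a gene
#' can score a hit for at most one cluster per repetition.
#'
#' @param expr genes-by-cells count matrix (dense or sparse) with dimnames.
#' @param labels cell-type label per cell; either named by cell barcode or
#'   in column order of `expr`.
#' @param params an [identity_params()].
#' @param seed integer seed governing all repetitions.
#' @return list of class `identity_result`:
#'   \item{genes}{named list: cell type -> character vector of identity
#'     gene ids (hit count > `min_hits`)}
#'   \item{hits}{integer matrix genes x cell types of hit counts}
#'   \item{params, seed}{the inputs, for provenance}
#' @export
call_identity_genes <- function(expr, labels, params = identity_params(),
                                seed = 1L) {
  stopifnot(inherits(params, "identity_params"))
  if (!is.null(names(labels)) && !is.null(colnames(expr))) {
    if (!all(colnames(expr) %in% names(labels)))
      stop("'labels' must cover all cells of 'expr'")
    labels <- labels[colnames(expr)]
  }
  if (length(labels) != ncol(expr))
    stop("'labels' must have one entry per cell")
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  idx_by_cluster <- split(seq_along(labels), labels)
  sizes <- lengths(idx_by_cluster)
  if (any(sizes < params$n_cells_per_cluster) &&
      params$undersized_clusters == "fail")
    stop(sprintf(
      "cluster(s) %s have fewer than %d cells; set undersized_clusters = 'resample' to sample with replacement",
      paste(names(sizes)[sizes < params$n_cells_per_cluster],
            collapse = ", "),
      params$n_cells_per_cluster))

  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(expr)))
  hits <- matrix(0L, nrow = nrow(expr), ncol = length(clusters),
                 dimnames = list(genes, clusters))
  k <- params$n_cells_per_cluster
  cmp <- if (params$strict_greater) `>` else `>=`

  with_seed(substream_seed(seed, "identity"), {
    for (rep_i in seq_len(params$n_reps)) {
      sampled <- lapply(idx_by_cluster, function(ix) {
        if (length(ix) >= k) ix[sample.int(length(ix), k)]
        else ix[sample.int(length(ix), k, replace = TRUE)]
      })
      pooled <- as.matrix(expr[, unlist(sampled, use.names = FALSE),
                               drop = FALSE])
      thr <- row_quantiles(pooled, params$q)
      # fraction of each cluster's sampled cells above threshold, per gene
      frac <- vapply(seq_along(clusters), function(ci) {
        block <- pooled[, ((ci - 1L) * k + 1L):(ci * k), drop = FALSE]
        rowMeans(cmp(block, thr))
      }, numeric(nrow(expr)))
      if (is.null(dim(frac))) frac <- matrix(frac, nrow = nrow(expr))
      pass_in <- frac >= params$in_frac
      pass_out <- frac <= params$out_frac
      # a cluster passing 'in' cannot also pass 'out' (out_frac < in_frac),
      # so "every other cluster low" == at least n_clusters - 1 low overall
      n_low <- rowSums(pass_out)
      hit <- pass_in & (n_low >= length(clusters) - 1L)
      hits <- hits + hit
    }
  })

  called <- lapply(seq_along(clusters), function(ci)
    genes[hits[, ci] > params$min_hits])
  names(called) <- clusters
  structure(list(genes = called, hits = hits, params = params, seed = seed),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat("identity_result:", length(x$genes), "cell types,",
      x$params$n_reps, "repetitions\n")
  for (t in names(x$genes))
    cat(sprintf("  %s: %d identity genes\n", t, length(x$genes[[t]])))
  invisible(x)
}
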