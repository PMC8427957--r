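#' Parameters of strain-differential peak calling
#'
#' @param fdr Benjamini-Hochberg FDR cutoff (default 0.05).
#' @param top_logfc_frac fraction of peaks retained per logFC tail
#'   (default 0.01, "top 1% of logFC"); applied two-sidedly, i.e. the most
#'   positive and the most negative tail each contribute.
#' @param low_count_mad_k MAD multiplier of the low-count filter
#'   (default 1.5), used by callers that pre-filter on bulk counts.
#' @param logfc_pseudocount pseudocount added to group means inside the
#'   log2 ratio; `NULL` (default) uses `1 / (n cells total)`.
#' @param empty_cells `"keep"` (default; a cell with no accessible peak
#'   keeps an all-zero normalized profile, with a warning), `"drop"`, or
#'   `"error"`.
#' @return list of class `diff_peak_params`.
#' @export
diff_peak_params <- function(fdr = 0.05, top_logfc_frac = 0.01,
                             low_count_mad_k = 1.5,
                             logfc_pseudocount = NULL,
                             empty_cells = c("keep", "drop", "error")) {
  p <- list(fdr = fdr, top_logfc_frac = top_logfc_frac,
            low_count_mad_k = low_count_mad_k,
            logfc_pseudocount = logfc_pseudocount,
            empty_cells = match.arg(empty_cells))
  if (p$fdr <= 0 || p$fdr >= 1) stop("'fdr' must lie in (0, 1)")
  if (p$top_logfc_frac <= 0 || p$top_logfc_frac > 1)
    stop("'top_logfc_frac' must lie in (0, 1]")
  structure(p, class = "diff_peak_params")
}

#' Two-sided Wilcoxon rank-sum p value
#'
#' Exact permutation enumeration of all `choose(n1 + n2, n1)` group
#' assignments when that count is at most `max_exact` (ties handled through
#' midranks); otherwise the normal approximation with tie correction and no
#' continuity correction, as used by single-cell pseudobulk packages.
#'
#' @param x,y numeric samples of the two groups.
#' @param max_exact switch to the approximation above this enumeration size.
#' @return two-sided p value in (0, 1].
#' @export
rank_sum_test <- function(x, y, max_exact = 5000) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (choose(n, n1) <= max_exact) {
    combs <- combn(n, n1)
    wnull <- colSums(matrix(r[combs], nrow = n1))
    return(mean(abs(wnull - mu) >= abs(w - mu) - 1e-12))
  }
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecor)
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

# vectorized tie-corrected normal-approximation rank-sum across matrix rows;
# groups are column blocks 1..n1 and (n1+1)..n
rank_sum_rows_normal <- function(mat, n1) {
  n <- ncol(mat); n2 <- n - n1
  ranks <- t(apply(mat, 1L, rank))
  w <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  mu <- n1 * (n + 1) / 2
  tiecor <- apply(ranks, 1L, function(r) {
    t <- table(r); sum(t^3 - t)
  }) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecor)
  p <- rep(1, nrow(mat))
  ok <- sigma2 > 0
  p[ok] <- pmin(1, 2 * pnorm(-abs((w[ok] - mu) / sqrt(sigma2[ok]))))
  p
}

#' Differential accessibility between strains on binary peak matrices
#'
#' Each cell's binary accessibility vector is normalized by its total
#' accessible-peak count; per peak, the normalized values of the two
#' strains are compared with a two-sided Wilcoxon rank-sum test
#' ([rank_sum_test()]: exact for small groups, tie-corrected normal
#' approximation otherwise), p values are Benjamini-Hochberg adjusted, and
#' `logFC = log2((mean_A + eps) / (mean_B + eps))`.  A peak is called
#' differential when `FDR < fdr` and its logFC lies in the top
#' `top_logfc_frac` of either tail across all tested peaks.
#'
#' @param matA,matB binary peaks-by-cells matrices over the same peak
#'   universe (strain 1 / strain 2).
#' @param params a [diff_peak_params()].
#' @return data.frame of class `diff_peak_table`: `peak_id`, `mean_a`,
#'   `mean_b`, `logfc`, `p`, `fdr`, `is_differential`.
#' @export
differential_peaks <- function(matA, matB, params = diff_peak_params()) {
  stopifnot(inherits(params, "diff_peak_params"))
  if (nrow(matA) != nrow(matB))
    stop("matrices must share one peak universe")
  if (!is.null(rownames(matA)) && !is.null(rownames(matB)) &&
      !identical(rownames(matA), rownames(matB)))
    stop("matrices must share one peak universe (row names differ)")
  if (ncol(matA) == 0 || ncol(matB) == 0)
    stop("each strain needs at least one cell")

  norm_cells <- function(m, label) {
    m <- as.matrix(m)
    tot <- colSums(m)
    if (any(tot == 0)) {
      msg <- sprintf("%d cell(s) in %s have no accessible peak", sum(tot == 0),
                     label)
      if (params$empty_cells == "error") stop(msg)
      if (params$empty_cells == "drop") {
        warning(msg, "; dropped")
        m <- m[, tot > 0, drop = FALSE]
        tot <- tot[tot > 0]
        if (length(tot) == 0) stop("no cells left in ", label)
      } else {
        warning(msg, "; kept with all-zero normalized profile")
        tot[tot == 0] <- 1
      }
    }
    sweep(m, 2L, tot, "/")
  }
  a <- norm_cells(matA, "strain A")
  b <- norm_cells(matB, "strain B")
  n1 <- ncol(a); n2 <- ncol(b)

  if (choose(n1 + n2, n1) <= 5000) {
    p <- vapply(seq_len(nrow(a)), function(i)
      rank_sum_test(a[i, ], b[i, ]), numeric(1))
  } else {
    p <- rank_sum_rows_normal(cbind(a, b), n1)
  }
  eps <- if (is.null(params$logfc_pseudocount)) 1 / (n1 + n2)
    else params$logfc_pseudocount
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  logfc <- log2((mean_a + eps) / (mean_b + eps))
  fdr <- p.adjust(p, method = "BH")
  up_thr <- quantile(logfc, 1 - params$top_logfc_frac, names = FALSE)
  dn_thr <- quantile(logfc, params$top_logfc_frac, names = FALSE)
  in_top <- logfc >= up_thr | logfc <= dn_thr
  res <- data.frame(
    peak_id = if (!is.null(rownames(matA))) rownames(matA)
      else sprintf("peak%d", seq_len(nrow(matA))),
    mean_a = mean_a, mean_b = mean_b, logfc = logfc, p = p, fdr = fdr,
    is_differential = fdr < params$fdr & in_top,
    stringsAsFactors = FALSE)
  class(res) <- c("diff_peak_table", "data.frame")
  res
}

#' @export
print.diff_peak_table <- function(x, ...) {
  cat(sprintf("diff_peak_table: %d peaks, %d differential (FDR + top-logFC)\n",
              nrow(x), sum(x$is_differential)))
  NextMethod()
}

#' Bootstrap enrichment of a peak set at gene regulatory domains
#'
#' Measures how many of the differential peaks overlap DEG regulatory
#' domains and compares against a null of equally sized peak sets drawn
#' uniformly (without replacement) from the full peak universe, repeated
#' `n_boot` times.  The empirical p uses the +1/+1 correction:
#' `p = (1 + #{null >= observed}) / (n_boot + 1)`.
#'
#' @param diff_peaks GRanges of the peak subset of interest.
#' @param all_peaks GRanges of the tested peak universe (superset).
#' @param domains GRanges of (DEG) regulatory domains.
#' @param n_boot bootstrap repetitions (default 1000).
#' @param seed integer seed.
#' @return list of class `peak_enrichment`: `observed` (count),
#'   `observed_frac`, `null` (length-`n_boot` counts), `p`.
#' @export
peakset_enrichment_at_genes <- function(diff_peaks, all_peaks, domains,
                                        n_boot = 1000L, seed = 1L) {
  diff_peaks <- as_intervals(diff_peaks)
  all_peaks <- as_intervals(all_peaks)
  k <- length(diff_peaks)
  if (k > length(all_peaks))
    stop("'diff_peaks' cannot outnumber 'all_peaks'")
  in_dom <- GenomicRanges::countOverlaps(all_peaks, domains,
                                         ignore.strand = TRUE) > 0
  obs_hit <- GenomicRanges::countOverlaps(diff_peaks, domains,
                                          ignore.strand = TRUE) > 0
  observed <- sum(obs_hit)
  null <- with_seed(substream_seed(seed, "peak_boot"), {
    vapply(seq_len(n_boot), function(i)
      sum(in_dom[sample.int(length(all_peaks), k)]), numeric(1))
  })
  structure(list(observed = observed,
                 observed_frac = if (k > 0) observed / k else 0,
                 null = null,
                 p = (1 + sum(null >= observed)) / (n_boot + 1),
                 n_boot = n_boot, seed = seed),
            class = "peak_enrichment")
}

#' @export
print.peak_enrichment <- function(x, ...) {
  cat(sprintf(
    "peak_enrichment: observed %d peaks in domains (frac %.3f), null mean %.1f, p = %.4g\n",
    x$observed, x$observed_frac, mean(x$null), x$p))
  invisible(x)
}
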