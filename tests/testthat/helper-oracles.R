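# Independent brute-force oracles shared across test files.  These
# deliberately use naive loops / enumeration, never the package's own code
# paths.

# type-7 quantile by explicit sort-and-index interpolation
oracle_quantile <- function(values, q) {
  s <- sort(values)
  n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# literal basal-plus-extension domain construction, one gene at a time
oracle_domains <- function(gene_table, chrom_sizes, basal_up = 5000,
                           basal_down = 1000, max_ext = 100000) {
  n <- nrow(gene_table)
  out <- data.frame(gene_id = gene_table$gene_id, start = NA_real_,
                    end = NA_real_)
  basal <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    tss <- gene_table$tss[i]
    if (gene_table$strand[i] == "+") {
      b <- c(tss - basal_up, tss + basal_down)
    } else {
      b <- c(tss - basal_down + 1, tss + basal_up + 1)
    }
    b[1] <- max(0, b[1])
    b[2] <- min(chrom_sizes[[gene_table$chrom[i]]], b[2])
    basal[i, ] <- b
  }
  for (i in seq_len(n)) {
    left <- 0
    right <- chrom_sizes[[gene_table$chrom[i]]]
    for (j in seq_len(n)) {
      if (j == i || gene_table$chrom[j] != gene_table$chrom[i]) next
      if (basal[j, 2] <= basal[i, 1]) left <- max(left, basal[j, 2])
      if (basal[j, 1] >= basal[i, 2]) right <- min(right, basal[j, 1])
    }
    out$start[i] <- max(basal[i, 1] - max_ext, left)
    out$end[i] <- min(basal[i, 2] + max_ext, right)
  }
  out
}

# all-vs-all half-open overlap of two BED-style frames
oracle_overlap_pairs <- function(a, b) {
  pairs <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i])
      pairs <- rbind(pairs, data.frame(i = i, j = j))
  }
  pairs
}

# exact two-sided rank-sum p by bitmask enumeration of group assignments
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != n1) next
    total <- total + 1L
    if (abs(sum(r[bits == 1L]) - mu) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# small default config for fast generator tests; any field overridable
tiny_cfg <- function(...) {
  defaults <- list(n_cell_types = 3, cells_per_type = 30, n_genes = 120,
                   n_identity_per_type = 5,
                   genome = c(chrA = 3e6, chrB = 2e6),
                   n_peaks = 60, n_footprints = 150, n_variants = 300,
                   peak_width = 400)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

recall_precision <- function(called, truth_pairs) {
  called_pairs <- do.call(rbind, lapply(names(called), function(t)
    if (length(called[[t]])) data.frame(gene_id = called[[t]], cell_type = t)))
  key <- function(d) paste(d$gene_id, d$cell_type)
  tp <- length(intersect(key(called_pairs), key(truth_pairs)))
  c(recall = tp / nrow(truth_pairs),
    precision = if (is.null(called_pairs)) NaN else tp / nrow(called_pairs))
}
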