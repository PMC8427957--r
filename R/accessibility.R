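#' Gene-activity counting from read positions
#'
#' Counts, per cell, the reads falling in each gene's body plus 2 kb
#' upstream of its TSS — the standard chromatin proxy for gene expression.
#' A read is counted once for every gene whose window it overlaps.
#'
#' @param reads data.frame `(chrom, pos, barcode)` of read positions
#'   (0-based points).
#' @param gene_table data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open gene body).
#' @param upstream bp added upstream of the TSS (default 2000).
#' @return sparse genes-by-cells count matrix.
#' @export
gene_activity <- function(reads, gene_table, upstream = 2000L) {
  stopifnot(all(c("chrom", "pos", "barcode") %in% names(reads)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(gene_table)))
  plus <- gene_table$strand == "+"
  win_start <- pmax(0, ifelse(plus, gene_table$start - upstream,
                              gene_table$start))
  win_end <- ifelse(plus, gene_table$end, gene_table$end + upstream)
  windows <- GenomicRanges::GRanges(
    gene_table$chrom,
    IRanges::IRanges(start = win_start + 1L, end = win_end))
  cells <- sort(unique(reads$barcode))
  m <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(nrow(gene_table), length(cells)),
    dimnames = list(gene_table$gene_id, cells))
  if (nrow(reads) == 0) return(m)
  pts <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$pos + 1L,
                                                 reads$pos + 1L))
  hits <- GenomicRanges::findOverlaps(pts, windows, ignore.strand = TRUE)
  if (length(hits) == 0) return(m)
  i <- S4Vectors::subjectHits(hits)
  j <- match(reads$barcode[S4Vectors::queryHits(hits)], cells)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(nrow(gene_table), length(cells)),
                       dimnames = list(gene_table$gene_id, cells))
}

#' Parameters of identity-peak signal aggregation
#'
#' @param window bp each side of the peak center profiled (default 3000,
#'   i.e. the 3 kb up- and downstream display window).
#' @param bin bin width in bp (default 100).
#' @param background_reads_per_type reads sampled per cell type into the
#'   pooled background (the published pipeline used 366,278).
#' @param pseudocount added to each bin count before the ratio.
#' @param sample_with_replacement allow background sampling with
#'   replacement when a cell type has too few reads (default fail).
#' @param seed seed of the background draw.
#' @return list of class `signal_params`.
#' @export
signal_params <- function(window = 3000L, bin = 100L,
                          background_reads_per_type = 366278L,
                          pseudocount = 1.0,
                          sample_with_replacement = FALSE, seed = 1L) {
  p <- list(window = as.integer(window), bin = as.integer(bin),
            background_reads_per_type = as.integer(background_reads_per_type),
            pseudocount = pseudocount,
            sample_with_replacement = isTRUE(sample_with_replacement),
            seed = as.integer(seed))
  if (p$bin <= 0 || p$window < p$bin) stop("need window >= bin > 0")
  if (p$background_reads_per_type <= 0)
    stop("'background_reads_per_type' must be positive")
  structure(p, class = "signal_params")
}

# bin counts of reads around peak centers: matrix peaks x bins
bin_read_counts <- function(reads, centers_chrom, centers, window, bin) {
  n_bins <- as.integer(2L * window / bin)
  counts <- matrix(0, nrow = length(centers), ncol = n_bins)
  if (nrow(reads) == 0 || length(centers) == 0) return(counts)
  win <- GenomicRanges::GRanges(
    centers_chrom,
    IRanges::IRanges(start = centers - window + 1L,
                     end = centers + window))
  pts <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$pos + 1L,
                                                 reads$pos + 1L))
  hits <- GenomicRanges::findOverlaps(pts, win, ignore.strand = TRUE)
  if (length(hits) == 0) return(counts)
  pk <- S4Vectors::subjectHits(hits)
  off <- reads$pos[S4Vectors::queryHits(hits)] - (centers[pk] - window)
  b <- pmin(n_bins, floor(off / bin) + 1L)
  tab <- table(factor(pk, levels = seq_along(centers)),
               factor(b, levels = seq_len(n_bins)))
  counts[] <- as.numeric(tab)
  counts
}

#' Aggregate background-normalized accessibility signal at identity peaks
#'
#' Builds a pooled background by sampling `background_reads_per_type` reads
#' uniformly without replacement from every cell type, then profiles each
#' cell type's coverage across `[center - window, center + window)` of every
#' identity-peak set in `bin`-bp bins.  The per-bin signal is
#' `log2(((n_type + pc) / lib_type) / ((n_bg + pc) / lib_bg))` — raw signal
#' normalized to background and library depth, log2-transformed.  The
#' heatmap entry for (cell type, peak set) is the mean over all bins of all
#' peaks in the set.
#'
#' @param reads_by_type named list (cell type -> data.frame
#'   `(chrom, pos)`), 0-based read points.
#' @param peaks_by_type named list (cell type -> GRanges) of identity peaks.
#' @param params a [signal_params()].
#' @param background optional explicit background read data.frame; when
#'   `NULL` it is sampled from `reads_by_type`.
#' @param lib_sizes optional named numeric of library sizes per cell type
#'   plus `"background"`; defaults to the read-set sizes.
#' @return list of class `signal_heatmap`:
#'   \item{heatmap}{matrix cell types x identity-peak sets of mean
#'     normalized log2 signal}
#'   \item{profiles}{list (cell type -> peak set -> per-bin mean profile)}
#' @export
aggregate_identity_signal <- function(reads_by_type, peaks_by_type,
                                      params = signal_params(),
                                      background = NULL, lib_sizes = NULL) {
  stopifnot(inherits(params, "signal_params"))
  types <- names(reads_by_type)
  if (is.null(background)) {
    short <- types[vapply(reads_by_type, nrow, 1L) <
                     params$background_reads_per_type]
    if (length(short) && !params$sample_with_replacement)
      stop("cell type(s) ", paste(short, collapse = ", "),
           " have fewer than background_reads_per_type reads; ",
           "set sample_with_replacement = TRUE to allow resampling")
    background <- with_seed(substream_seed(params$seed, "background"), {
      do.call(rbind, lapply(reads_by_type, function(r) {
        idx <- sample.int(nrow(r), params$background_reads_per_type,
                          replace = nrow(r) <
                            params$background_reads_per_type)
        r[idx, c("chrom", "pos"), drop = FALSE]
      }))
    })
  }
  if (is.null(lib_sizes)) {
    lib_sizes <- c(vapply(reads_by_type, nrow, 1L),
                   background = nrow(background))
  }
  pc <- params$pseudocount
  sets <- names(peaks_by_type)
  heat <- matrix(NA_real_, length(types), length(sets),
                 dimnames = list(types, sets))
  profiles <- list()
  centers_of <- function(gr) {
    bed <- granges_to_bed(gr)
    list(chrom = bed$chrom, center = floor((bed$start + bed$end) / 2))
  }
  n_bins <- as.integer(2L * params$window / params$bin)
  bg_bins <- lapply(peaks_by_type, function(pk) {
    ce <- centers_of(as_intervals(pk))
    bin_read_counts(background, ce$chrom, ce$center, params$window,
                    params$bin)
  })
  for (t in types) {
    profiles[[t]] <- list()
    for (s in sets) {
      ce <- centers_of(as_intervals(peaks_by_type[[s]]))
      ct <- bin_read_counts(reads_by_type[[t]], ce$chrom, ce$center,
                            params$window, params$bin)
      sig <- log2(((ct + pc) / lib_sizes[[t]]) /
                    ((bg_bins[[s]] + pc) / lib_sizes[["background"]]))
      heat[t, s] <- mean(sig)
      profiles[[t]][[s]] <- colMeans(matrix(sig, ncol = n_bins))
    }
  }
  structure(list(heatmap = heat, profiles = profiles, params = params),
            class = "signal_heatmap")
}

#' @export
print.signal_heatmap <- function(x, ...) {
  cat("signal_heatmap: mean normalized log2 signal\n")
  print(round(x$heatmap, 3))
  invisible(x)
}

#' Plot a signal heatmap
#' @param x a `signal_heatmap`.
#' @param ... passed to [graphics::image()].
#' @export
plot.signal_heatmap <- function(x, ...) {
  h <- x$heatmap
  graphics::image(seq_len(ncol(h)), seq_len(nrow(h)), t(h),
                  xlab = "identity peak set", ylab = "cell type",
                  axes = FALSE, ...)
  graphics::axis(1, seq_len(ncol(h)), colnames(h), las = 2)
  graphics::axis(2, seq_len(nrow(h)), rownames(h), las = 1)
  invisible(x)
}

#' Filter peaks with low bulk read count
#'
#' Keeps peaks whose `log10(count + pseudocount)` is at least
#' `median - k * MAD`, with the MAD unscaled
#' (`median(|x - median(x)|)`).  The published cutoff is `k = 1.5`.
#'
#' @param counts non-negative per-peak bulk read counts.
#' @param k MAD multiplier.
#' @param pseudocount added before `log10` (default 0; zero counts then map
#'   to `-Inf` and are always filtered).
#' @return logical vector, `TRUE` for kept peaks.
#' @examples
#' filter_low_count_peaks(c(10, 100, 100, 100, 1000))  # drops the first
#' @export
filter_low_count_peaks <- function(counts, k = 1.5, pseudocount = 0) {
  if (length(counts) == 0) stop("'counts' must be non-empty")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  x <- log10(counts + pseudocount)
  med <- median(x)
  mad_u <- median(abs(x - med))
  x >= med - k * mad_u
}
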