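#' Variant positions as genomic ranges
#'
#' Variants are points at the VCF POS (first reference base); indels occupy
#' `[POS, POS + nchar(ref))` in 0-based terms.
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`
#'   (optional; defaults to single-base).
#' @return GRanges with `id` metadata when present.
#' @export
variants_to_granges <- function(variants) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  len <- if ("ref" %in% names(variants)) nchar(variants$ref) else 1L
  gr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(start = variants$pos, end = variants$pos + len - 1L))
  if ("id" %in% names(variants)) S4Vectors::mcols(gr)$id <- variants$id
  gr
}

#' Flag putative cis-regulatory variants
#'
#' A variant is putative-regulatory when it lies inside at least one
#' transcription-factor footprint AND that same footprint overlaps an
#' H3K27ac enhancer peak of either strain (union of the two sets) — i.e. a
#' variant disrupting a TF binding site engaged in transcriptional activity
#' in at least one strain.  With `enhancer_on = "variant"` the enhancer
#' condition is instead evaluated at the variant position itself.
#'
#' @param variants data.frame `(chrom, pos, id, ref, alt)`; malformed rows
#'   (non-positive or missing positions) are skipped with a reported count.
#' @param footprints GRanges (or BED data.frame) of TF footprints.
#' @param enhancers_strain1,enhancers_strain2 GRanges of per-strain H3K27ac
#'   peaks.
#' @param enhancer_on evaluate the activity condition on the `"footprint"`
#'   (default) or on the `"variant"` position.
#' @return the input data.frame plus logical columns `in_footprint`,
#'   `footprint_active`, `is_putative_regulatory`, and attribute
#'   `n_skipped`.
#' @export
call_putative_regulatory_variants <- function(variants, footprints,
                                              enhancers_strain1,
                                              enhancers_strain2,
                                              enhancer_on = c("footprint",
                                                              "variant")) {
  enhancer_on <- match.arg(enhancer_on)
  footprints <- as_intervals(footprints)
  enh <- c(GenomicRanges::granges(as_intervals(enhancers_strain1)),
           GenomicRanges::granges(as_intervals(enhancers_strain2)))
  ok <- !is.na(variants$pos) & variants$pos >= 1 &
    !is.na(variants$chrom) & nzchar(variants$chrom)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(n_skipped, " malformed variant record(s) skipped")
  v <- variants[ok, , drop = FALSE]
  vgr <- variants_to_granges(v)
  hits <- GenomicRanges::findOverlaps(vgr, footprints, ignore.strand = TRUE)
  in_fp <- rep(FALSE, nrow(v))
  in_fp[unique(S4Vectors::queryHits(hits))] <- TRUE
  fp_active_any <- GenomicRanges::countOverlaps(footprints, enh,
                                                ignore.strand = TRUE) > 0
  active <- rep(FALSE, nrow(v))
  if (enhancer_on == "footprint") {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    active[unique(qh[fp_active_any[sh]])] <- TRUE
  } else {
    active <- in_fp &
      GenomicRanges::countOverlaps(vgr, enh, ignore.strand = TRUE) > 0
  }
  out <- variants
  out$in_footprint <- FALSE
  out$footprint_active <- FALSE
  out$in_footprint[ok] <- in_fp
  out$footprint_active[ok] <- active
  out$is_putative_regulatory <- out$in_footprint & out$footprint_active
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Putative regulatory variants per gene
#'
#' Counts, for every gene of `gene_set`, the flagged variants whose position
#' overlaps the gene's regulatory domain (a variant may count toward several
#' genes) and returns the mean over the set.
#'
#' @param variants output of [call_putative_regulatory_variants()].
#' @param domains GRanges from [build_regulatory_domains()].
#' @param gene_set character vector of gene ids (must all have domains).
#' @return list: `mean` (variants per gene), `per_gene` (named integer).
#' @export
variants_per_gene <- function(variants, domains, gene_set) {
  if (length(gene_set) == 0) stop("'gene_set' is empty")
  dom_ids <- as.character(S4Vectors::mcols(domains)$name)
  missing <- setdiff(gene_set, dom_ids)
  if (length(missing))
    stop("gene(s) without domain: ", paste(head(missing, 5), collapse = ", "))
  flagged <- variants[variants$is_putative_regulatory, , drop = FALSE]
  counts <- integer(length(gene_set))
  names(counts) <- gene_set
  if (nrow(flagged) > 0) {
    vgr <- variants_to_granges(flagged)
    dom <- domains[match(gene_set, dom_ids)]
    counts[] <- GenomicRanges::countOverlaps(dom, vgr, ignore.strand = TRUE)
  }
  list(mean = mean(counts), per_gene = counts)
}

#' Bootstrap enrichment of regulatory variants at differentially expressed
#' genes
#'
#' Reports mean putative-regulatory variants per gene for the DEG set, the
#' non-DEG set, and one random draw of `n_random` genes from the expressed
#' universe; the null distribution is `n_boot` draws of `|DEG|` genes from
#' the universe, and `p = (1 + #{null mean >= DEG mean}) / (n_boot + 1)`
#' (one-sided enrichment, +1 corrected).
#'
#' @param variants output of [call_putative_regulatory_variants()].
#' @param domains GRanges domain map covering the universe.
#' @param deg_genes,nondeg_genes,universe character gene-id vectors;
#'   `deg_genes` and `nondeg_genes` must be subsets of `universe`.
#' @param n_random size of the random display set (default 5000, capped at
#'   the universe size).
#' @param n_boot bootstrap repetitions (default 1000).
#' @param seed integer seed.
#' @return list of class `enrichment_result`: `mean_deg`, `mean_nondeg`,
#'   `mean_random`, `null_means`, `p`, `n_random`, `n_boot`, `seed`.
#' @export
deg_variant_enrichment <- function(variants, domains, deg_genes,
                                   nondeg_genes, universe,
                                   n_random = 5000L, n_boot = 1000L,
                                   seed = 1L) {
  if (!all(deg_genes %in% universe) || !all(nondeg_genes %in% universe))
    stop("DEG and non-DEG sets must be subsets of the expressed universe")
  if (length(deg_genes) > length(universe))
    stop("more DEGs than universe genes")
  n_random <- min(as.integer(n_random), length(universe))
  per_gene <- variants_per_gene(variants, domains, universe)$per_gene
  mean_deg <- mean(per_gene[deg_genes])
  mean_nondeg <- if (length(nondeg_genes)) mean(per_gene[nondeg_genes])
    else NA_real_
  res <- with_seed(substream_seed(seed, "deg_boot"), {
    mean_random <- mean(per_gene[sample(universe, n_random)])
    null_means <- vapply(seq_len(n_boot), function(i)
      mean(per_gene[sample(universe, length(deg_genes))]), numeric(1))
    list(mean_random = mean_random, null_means = null_means)
  })
  structure(list(mean_deg = mean_deg, mean_nondeg = mean_nondeg,
                 mean_random = res$mean_random,
                 null_means = res$null_means,
                 p = (1 + sum(res$null_means >= mean_deg)) / (n_boot + 1),
                 n_random = n_random, n_boot = n_boot, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: variants/gene DEG %.3f | non-DEG %.3f | random %.3f; p = %.4g (%d bootstraps)\n",
    x$mean_deg, x$mean_nondeg, x$mean_random, x$p, x$n_boot))
  invisible(x)
}

#' Cell-type accessibility breadth of flagged variants
#'
#' Breadth = number of cell types with at least one accessible peak
#' overlapping the variant position.  Reports per-variant breadth, the
#' histogram over `0..n_cell_types`, and cumulative fractions.
#'
#' @param variants output of [call_putative_regulatory_variants()]; only
#'   flagged variants are scored.
#' @param peaks_by_type named list (cell type -> GRanges peak set).
#' @return list of class `breadth_result`: `breadth` (named integer per
#'   flagged variant), `histogram` (counts over 0..n types),
#'   `frac_ge` / `frac_le` (cumulative fractions by breadth).
#' @export
accessibility_breadth <- function(variants, peaks_by_type) {
  if (length(peaks_by_type) == 0) stop("need at least one cell type")
  flagged <- variants[variants$is_putative_regulatory, , drop = FALSE]
  n_types <- length(peaks_by_type)
  breadth <- integer(nrow(flagged))
  if (nrow(flagged) > 0) {
    vgr <- variants_to_granges(flagged)
    for (t in names(peaks_by_type))
      breadth <- breadth +
        (GenomicRanges::countOverlaps(vgr, as_intervals(peaks_by_type[[t]]),
                                      ignore.strand = TRUE) > 0)
    names(breadth) <- if ("id" %in% names(flagged)) flagged$id else NULL
  }
  hist <- tabulate(breadth + 1L, nbins = n_types + 1L)
  names(hist) <- 0:n_types
  tot <- max(1L, length(breadth))
  frac_ge <- rev(cumsum(rev(hist))) / tot
  frac_le <- cumsum(hist) / tot
  structure(list(breadth = breadth, histogram = hist,
                 frac_ge = frac_ge, frac_le = frac_le,
                 n_cell_types = n_types),
            class = "breadth_result")
}

#' @export
print.breadth_result <- function(x, ...) {
  cat("breadth_result over", x$n_cell_types, "cell types:\n")
  print(x$histogram)
  invisible(x)
}

#' Flagged variants inside differential-enhancer regions
#'
#' @param variants output of [call_putative_regulatory_variants()].
#' @param diff_regions GRanges of differential H3K27ac regions.
#' @return list: `variants` (flagged subset overlapping a region),
#'   `count`, `n_flagged`.
#' @export
overlap_differential_enhancers <- function(variants, diff_regions) {
  flagged <- variants[variants$is_putative_regulatory, , drop = FALSE]
  if (nrow(flagged) == 0)
    return(list(variants = flagged, count = 0L, n_flagged = 0L))
  vgr <- variants_to_granges(flagged)
  hit <- GenomicRanges::countOverlaps(vgr, as_intervals(diff_regions),
                                      ignore.strand = TRUE) > 0
  list(variants = flagged[hit, , drop = FALSE],
       count = sum(hit), n_flagged = nrow(flagged))
}
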