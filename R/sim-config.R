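#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generator.  The defaults
#' describe the study conditions the downstream callers are validated under:
#' five cell types of 300 cells over 2000 genes with 40 planted identity
#' genes per type (negative-binomial means 20 for planted type-selective
#' expression vs 1 background), a small two-chromosome genome carrying
#' non-overlapping 500-bp peaks, and variant/footprint/enhancer tracks in
#' which putative-regulatory-variant density at differentially-expressed-gene
#' (DEG) domains is `variant_enrichment_factor` times the non-DEG density.
#'
#' One global integer seed drives deterministic per-component substreams, so
#' regenerating a single input leaves the others byte-identical.
#'
#' @param n_cell_types number of cell types (clusters).
#' @param cells_per_type cells simulated per type.
#' @param n_genes total genes.
#' @param n_identity_per_type planted identity genes per type; the planted
#'   sets are disjoint, so `n_identity_per_type * n_cell_types <= n_genes`.
#' @param nb_mean_background,nb_mean_identity negative-binomial expected
#'   counts for background and planted identity expression.
#' @param nb_dispersion negative-binomial `size` parameter (smaller = more
#'   overdispersed).
#' @param genome named integer vector of chromosome lengths in bp.
#' @param peak_width width of simulated accessibility peaks (bp).
#' @param n_peaks,n_footprints,n_variants track sizes.
#' @param frac_deg fraction of genes flagged as DEGs.  Kept small by default
#'   so the expressed-gene universe approximates the non-DEG background in
#'   enrichment analyses.
#' @param variant_enrichment_factor ratio of planted regulatory-variant
#'   density at DEG domains vs non-DEG domains (>= 1).
#' @param reg_variant_rate expected planted regulatory variants per non-DEG
#'   gene domain.
#' @param diff_peak_frac fraction of peaks planted as strain-differential.
#' @param acc_p_background Bernoulli accessibility probability of
#'   non-differential peaks (both strains).
#' @param acc_p1,acc_p2 accessibility probabilities of planted differential
#'   peaks in strain 1 / strain 2; planted directions are balanced (half the
#'   planted peaks get the pair swapped).
#' @param seed global integer seed.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_cell_types = 2, cells_per_type = 30,
#'                   n_identity_per_type = 5, seed = 1)
#' @export
sim_config <- function(n_cell_types = 5L,
                       cells_per_type = 300L,
                       n_genes = 2000L,
                       n_identity_per_type = 40L,
                       nb_mean_background = 1,
                       nb_mean_identity = 20,
                       nb_dispersion = 2,
                       genome = c(chr1 = 60e6, chr2 = 40e6),
                       peak_width = 500L,
                       n_peaks = 1000L,
                       n_footprints = 2000L,
                       n_variants = 5000L,
                       frac_deg = 0.05,
                       variant_enrichment_factor = 3,
                       reg_variant_rate = 0.5,
                       diff_peak_frac = 0.02,
                       acc_p_background = 0.3,
                       acc_p1 = 0.9,
                       acc_p2 = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type = as.integer(cells_per_type),
    n_genes = as.integer(n_genes),
    n_identity_per_type = as.integer(n_identity_per_type),
    nb_mean_background = nb_mean_background,
    nb_mean_identity = nb_mean_identity,
    nb_dispersion = nb_dispersion,
    genome = genome,
    peak_width = as.integer(peak_width),
    n_peaks = as.integer(n_peaks),
    n_footprints = as.integer(n_footprints),
    n_variants = as.integer(n_variants),
    frac_deg = frac_deg,
    variant_enrichment_factor = variant_enrichment_factor,
    reg_variant_rate = reg_variant_rate,
    diff_peak_frac = diff_peak_frac,
    acc_p_background = acc_p_background,
    acc_p1 = acc_p1,
    acc_p2 = acc_p2,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  cnt <- c("n_cell_types", "cells_per_type", "n_genes", "peak_width")
  for (f in cnt)
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop(sprintf("'%s' must be a positive integer", f))
  for (f in c("n_identity_per_type", "n_peaks", "n_footprints", "n_variants"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop(sprintf("'%s' must be a non-negative integer", f))
  for (f in c("frac_deg", "acc_p_background", "acc_p1", "acc_p2"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", f))
  if (cfg$variant_enrichment_factor < 1)
    stop("'variant_enrichment_factor' must be >= 1")
  if (cfg$nb_mean_background < 0 || cfg$nb_mean_identity < 0 ||
      cfg$nb_dispersion <= 0)
    stop("negative-binomial parameters must be non-negative (size > 0)")
  if (is.null(names(cfg$genome)) || any(!nzchar(names(cfg$genome))) ||
      any(cfg$genome <= 0))
    stop("'genome' must be a named vector of positive chromosome lengths")
  if (cfg$n_identity_per_type * cfg$n_cell_types > cfg$n_genes)
    stop("n_identity_per_type * n_cell_types exceeds n_genes")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cell_types, "cell types x", x$cells_per_type,
      "cells,", x$n_genes, "genes (", x$n_identity_per_type,
      "planted identity genes/type )\n")
  cat("  NB mean identity/background:", x$nb_mean_identity, "/",
      x$nb_mean_background, " size:", x$nb_dispersion, "\n")
  cat("  genome:", paste(names(x$genome), x$genome, sep = ":",
                         collapse = ", "), "\n")
  cat("  peaks:", x$n_peaks, " footprints:", x$n_footprints,
      " variants:", x$n_variants, "\n")
  cat("  frac_deg:", x$frac_deg, " enrichment factor:",
      x$variant_enrichment_factor, " seed:", x$seed, "\n")
  invisible(x)
}
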