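#' Generate and write a complete synthetic dataset
#'
#' Runs every generator ([simulate_expression()],
#' [simulate_genome_annotation()], [simulate_accessibility()],
#' [simulate_variant_tracks()], [simulate_reads()]) under one seed hierarchy
#' and writes all pipeline inputs plus machine-readable truth tables to
#' `outdir`.  Identical configurations (including the seed) produce
#' byte-identical files.
#'
#' Files written: `expression.{mtx,rows.tsv,cols.tsv}`, `labels.tsv`,
#' `genes.tsv`, `chrom.sizes.tsv`, `peaks.bed`,
#' `peakmat_<type>_strain{1,2}.{mtx,rows.tsv,cols.tsv}`, `reads.tsv`,
#' `variants.vcf`, `footprints.bed`, `enhancers_strain{1,2}.bed`,
#' `diff_enhancers.bed`, `deg_table.tsv`, and
#' `truth_{identity_genes,diff_peaks,variants}.tsv`.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param reads_per_type reads simulated per cell type for the signal /
#'   gene-activity stages.
#' @return (invisibly) the list of generated objects.
#' @export
simulate_dataset <- function(cfg, outdir, reads_per_type = 20000L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)

  expr <- simulate_expression(cfg)
  write_mtx(expr$counts, fp("expression"))
  write_tsv(data.frame(barcode = names(expr$labels),
                       cell_type = unname(expr$labels)), fp("labels.tsv"))
  write_tsv(expr$truth, fp("truth_identity_genes.tsv"))

  genes <- simulate_genome_annotation(cfg)
  write_tsv(genes, fp("genes.tsv"))
  write_tsv(data.frame(chrom = names(cfg$genome),
                       length = as.integer(cfg$genome)),
            fp("chrom.sizes.tsv"))

  acc <- simulate_accessibility(cfg, genes)
  write_bed(acc$peaks, fp("peaks.bed"))
  for (t in names(acc$matrices)) {
    write_mtx(acc$matrices[[t]]$strain1, fp(sprintf("peakmat_%s_strain1", t)))
    write_mtx(acc$matrices[[t]]$strain2, fp(sprintf("peakmat_%s_strain2", t)))
  }
  write_tsv(acc$truth, fp("truth_diff_peaks.tsv"))

  domains <- build_regulatory_domains(genes, cfg$genome)
  write_bed(domains, fp("domains.bed"))

  trk <- simulate_variant_tracks(cfg, genes, domains)
  write_sites_vcf(trk$variants, fp("variants.vcf"))
  write_bed(trk$footprints, fp("footprints.bed"))
  write_bed(trk$enhancers_strain1, fp("enhancers_strain1.bed"))
  write_bed(trk$enhancers_strain2, fp("enhancers_strain2.bed"))
  write_bed(trk$diff_enhancers, fp("diff_enhancers.bed"))
  write_tsv(trk$deg_table, fp("deg_table.tsv"))
  write_tsv(trk$truth, fp("truth_variants.tsv"))

  types <- names(acc$matrices)
  reads <- simulate_reads(cfg, acc$peaks,
                          stats::setNames(rep(list(acc$peaks), length(types)),
                                          types),
                          reads_per_type = reads_per_type)
  write_tsv(reads, fp("reads.tsv"))

  invisible(list(expression = expr, genes = genes, accessibility = acc,
                 domains = domains, tracks = trk, reads = reads))
}
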