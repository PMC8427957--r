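mk_variants <- function(pos, chrom = "c") {
  data.frame(chrom = chrom, pos = pos,
             id = sprintf("v%03d", seq_along(pos)),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}
mk_bed <- function(start, end, chrom = "c", prefix = "iv") {
  bed_to_granges(data.frame(chrom = chrom, start = start, end = end,
                            name = sprintf("%s%02d", prefix,
                                           seq_along(start))))
}

test_that("putative-regulatory flags implement footprint AND active-enhancer", {
  fp <- mk_bed(c(10480, 30000), c(10520, 30020), prefix = "fp")
  enh1 <- mk_bed(10000, 10500, prefix = "e")   # overlaps footprint 1 only
  enh2 <- mk_bed(90000, 91000, prefix = "e")
  v <- mk_variants(c(10501, 30010, 50000))  # 1-based: 10501 = 0-based 10500
  res <- call_putative_regulatory_variants(v, fp, enh1, enh2)
  # inside fp1 which is active in strain 1 only -> flagged ("either strain")
  expect_equal(res$is_putative_regulatory, c(TRUE, FALSE, FALSE))
  expect_equal(res$in_footprint, c(TRUE, TRUE, FALSE))
  # variant-position semantics: position itself must be in the enhancer
  res_v <- call_putative_regulatory_variants(v, fp, enh1, enh2,
                                             enhancer_on = "variant")
  expect_equal(res_v$is_putative_regulatory, c(FALSE, FALSE, FALSE))
  v2 <- mk_variants(10490)
  expect_true(call_putative_regulatory_variants(
    v2, fp, enh1, enh2, enhancer_on = "variant")$is_putative_regulatory)
  # malformed records skipped with count
  bad <- rbind(v, data.frame(chrom = "c", pos = NA_integer_, id = "vbad",
                             ref = "A", alt = "G"))
  expect_message(res_bad <- call_putative_regulatory_variants(
    bad, fp, enh1, enh2), "1 malformed")
  expect_equal(attr(res_bad, "n_skipped"), 1)
  expect_false(res_bad$is_putative_regulatory[4])
})

test_that("flags equal a nested-loop brute-force oracle on random toys", {
  set.seed(19)
  for (case in 1:5) {
    fs <- sort(sample.int(9e4, 10))
    fp <- mk_bed(fs, fs + 30, prefix = "fp")
    es <- sort(sample.int(9e4, 5))
    enh1 <- mk_bed(es[1:3], es[1:3] + 400, prefix = "e")
    enh2 <- mk_bed(es[4:5], es[4:5] + 400, prefix = "e")
    v <- mk_variants(sample.int(95000, 50))
    res <- call_putative_regulatory_variants(v, fp, enh1, enh2)
    fpdf <- granges_to_bed(fp)
    edf <- rbind(granges_to_bed(enh1), granges_to_bed(enh2))
    for (i in seq_len(nrow(v))) {
      p0 <- v$pos[i] - 1  # 0-based point
      want <- FALSE
      for (j in seq_len(nrow(fpdf))) {
        if (p0 < fpdf$start[j] || p0 >= fpdf$end[j]) next
        for (k in seq_len(nrow(edf)))
          if (fpdf$start[j] < edf$end[k] && edf$start[k] < fpdf$end[j])
            want <- TRUE
      }
      expect_equal(res$is_putative_regulatory[i], want)
    }
    # flag decomposition invariant
    expect_lte(sum(res$is_putative_regulatory), sum(res$in_footprint))
    expect_lte(sum(res$in_footprint), nrow(res))
  }
})

test_that("variants-per-gene counting composes with domain association", {
  gt <- data.frame(gene_id = c("gA", "gB"), chrom = "c",
                   tss = c(100000, 600000), strand = "+")
  dom <- build_regulatory_domains(gt, c(c = 1e6))
  fp <- mk_bed(c(98000, 98050, 597000), c(98030, 98080, 597030),
               prefix = "fp")
  enh <- mk_bed(97000, 99000, prefix = "e")  # activates the two gA footprints
  v <- mk_variants(c(98010, 98060, 98065, 597010, 800000))
  res <- call_putative_regulatory_variants(v, fp, enh, enh[0])
  vpg <- variants_per_gene(res, dom, c("gA", "gB"))
  expect_equal(unname(vpg$per_gene), c(3, 0))  # gB's footprint is inactive
  expect_equal(vpg$mean, 1.5)
  # no flagged variants -> mean 0
  none <- call_putative_regulatory_variants(mk_variants(800000), fp, enh,
                                            enh[0])
  expect_equal(variants_per_gene(none, dom, c("gA", "gB"))$mean, 0)
  expect_error(variants_per_gene(res, dom, character(0)), "empty")
  expect_error(variants_per_gene(res, dom, "gZ"), "without domain")
})

test_that("DEG enrichment has the documented degenerate behavior", {
  gt <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "c",
                   tss = seq(50000, 950000, length.out = 20), strand = "+")
  dom <- build_regulatory_domains(gt, c(c = 1e6))
  # zero flagged variants anywhere -> all means 0, p = 1
  fp <- mk_bed(1, 31, prefix = "fp")
  v0 <- call_putative_regulatory_variants(mk_variants(500), fp,
                                          mk_bed(2000, 2400), mk_bed(1, 2)[0])
  e0 <- deg_variant_enrichment(v0, dom, gt$gene_id[1:5], gt$gene_id[6:20],
                               gt$gene_id, n_boot = 100, seed = 1)
  expect_equal(e0$mean_deg, 0)
  expect_equal(e0$p, 1)
  # DEG set with no variants while others have some -> p = 1 (one-sided)
  fp2 <- mk_bed(899990, 900020, prefix = "fp")   # in g18's domain only
  enh2 <- mk_bed(899000, 901000)
  v1 <- call_putative_regulatory_variants(mk_variants(900001), fp2, enh2,
                                          enh2[0])
  e1 <- deg_variant_enrichment(v1, dom, gt$gene_id[1:3], gt$gene_id[4:20],
                               gt$gene_id, n_boot = 200, seed = 2)
  expect_equal(e1$mean_deg, 0)
  expect_equal(e1$p, 1)
  # determinism and universe containment
  expect_identical(
    deg_variant_enrichment(v1, dom, gt$gene_id[1:3], gt$gene_id[4:20],
                           gt$gene_id, n_boot = 50, seed = 7),
    deg_variant_enrichment(v1, dom, gt$gene_id[1:3], gt$gene_id[4:20],
                           gt$gene_id, n_boot = 50, seed = 7))
  expect_error(deg_variant_enrichment(v1, dom, "gX", gt$gene_id[4:20],
                                      gt$gene_id), "subsets")
})

test_that("planted variant enrichment is detected with calibrated power", {
  cfg <- sim_config(n_cell_types = 2, cells_per_type = 20, n_genes = 250,
                    n_identity_per_type = 0, genome = c(c1 = 5e7),
                    n_variants = 700, frac_deg = 0.08,
                    variant_enrichment_factor = 3, reg_variant_rate = 1.5,
                    seed = 12)
  gt <- simulate_genome_annotation(cfg)
  dom <- build_regulatory_domains(gt, cfg$genome)
  trk <- simulate_variant_tracks(cfg, gt, dom)
  fl <- call_putative_regulatory_variants(trk$variants, trk$footprints,
                                          trk$enhancers_strain1,
                                          trk$enhancers_strain2)
  deg <- trk$deg_table$gene_id[trk$deg_table$fdr < 0.05]
  nondeg <- setdiff(trk$deg_table$gene_id, deg)
  en <- deg_variant_enrichment(fl, dom, deg, nondeg, trk$deg_table$gene_id,
                               n_boot = 300, seed = 4)
  expect_lte(en$p, 0.01)
  expect_gt(en$mean_deg / en$mean_nondeg, 1.8)
})

test_that("accessibility breadth counts cell types and is monotone", {
  fp <- mk_bed(10000, 10040, prefix = "fp")
  enh <- mk_bed(9000, 11000)
  v <- call_putative_regulatory_variants(mk_variants(c(10010, 10020)), fp,
                                         enh, enh[0])
  pk_hit <- mk_bed(10000, 10500, prefix = "pk")
  pk_miss <- mk_bed(50000, 50500, prefix = "pk")
  ten <- c(rep(list(pk_hit), 7), rep(list(pk_miss), 3))
  names(ten) <- sprintf("t%02d", 1:10)
  br <- accessibility_breadth(v, ten)
  expect_equal(unname(br$breadth), c(7, 7))
  expect_equal(unname(br$histogram["7"]), 2)
  expect_equal(unname(br$frac_ge[["6"]]), 1)
  expect_equal(unname(br$frac_le[["2"]]), 0)
  # variant in no peak -> breadth 0
  br0 <- accessibility_breadth(v, list(t1 = pk_miss))
  expect_equal(unname(br0$breadth), c(0, 0))
  # adding a cell type never decreases breadth
  br_less <- accessibility_breadth(v, ten[1:5])
  br_more <- accessibility_breadth(v, ten)
  expect_true(all(br_more$breadth >= br_less$breadth))
  expect_error(accessibility_breadth(v, list()), "at least one")
})

test_that("differential-enhancer overlap returns the flagged subset", {
  fp <- mk_bed(c(10000, 20000), c(10040, 20040), prefix = "fp")
  enh <- mk_bed(c(9000, 19000), c(11000, 21000))
  v <- call_putative_regulatory_variants(
    mk_variants(c(10010, 20010, 90000)), fp, enh, enh[0])
  # no differential regions -> count 0
  expect_equal(overlap_differential_enhancers(v, enh[0])$count, 0)
  # one huge region captures every flagged variant
  big <- mk_bed(0, 1e6)
  ov <- overlap_differential_enhancers(v, big)
  expect_equal(ov$count, 2)
  expect_equal(ov$n_flagged, 2)
  # point-in-interval oracle on a split region set
  regions <- mk_bed(c(9990, 30000), c(10011, 30100))
  ov2 <- overlap_differential_enhancers(v, regions)
  expect_equal(ov2$variants$id, "v001")  # 0-based 10009 in [9990,10011)
})
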