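dom_bed <- function(gr) {
  b <- granges_to_bed(gr)
  b[, c("name", "chrom", "start", "end")]
}

test_that("basal-plus-extension domains match hand-derived cases", {
  # isolated + strand gene: basal [145k, 151k) extended +/- 100 kb
  gt <- data.frame(gene_id = "g1", chrom = "chr1", tss = 150000,
                   strand = "+")
  d <- dom_bed(build_regulatory_domains(gt, c(chr1 = 1e6)))
  expect_equal(c(d$start, d$end), c(45000, 251000))
  # two + strand genes truncate each other at basal boundaries
  gt2 <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss = c(50000, 60000), strand = "+")
  d2 <- dom_bed(build_regulatory_domains(gt2, c(chr1 = 200000)))
  expect_equal(d2$start, c(0, 51000))
  expect_equal(d2$end, c(55000, 161000))
  # basal clipped at the chromosome start
  gt3 <- data.frame(gene_id = "g", chrom = "c", tss = 2000, strand = "+")
  d3 <- dom_bed(build_regulatory_domains(gt3, c(c = 1e6)))
  expect_equal(d3$start, 0)
  expect_equal(d3$end, 103000)
  # minus strand mirrors the basal region
  gtm <- data.frame(gene_id = "g", chrom = "c", tss = 500000, strand = "-")
  dm <- dom_bed(build_regulatory_domains(
    gtm, c(c = 1e6), domain_params(max_extension = 0)))
  expect_equal(c(dm$start, dm$end), c(499001, 505001))
  # error cases
  expect_error(build_regulatory_domains(
    data.frame(gene_id = "g", chrom = "cX", tss = 10, strand = "+"),
    c(c = 1e6)), "unknown chromosome")
  expect_error(build_regulatory_domains(
    data.frame(gene_id = "g", chrom = "c", tss = 2e6, strand = "+"),
    c(c = 1e6)), "outside chromosome")
})

test_that("domains equal the brute-force construction on random toy chromosomes", {
  set.seed(31)
  for (case in 1:30) {
    n <- sample(1:50, 1)
    len <- sample(2e5:2e6, 1)
    gt <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "c",
                     tss = sort(sample.int(len, n)),
                     strand = sample(c("+", "-"), n, replace = TRUE))
    d <- dom_bed(build_regulatory_domains(gt, c(c = len)))
    o <- oracle_domains(gt, c(c = len))
    expect_equal(d$start, o$start)
    expect_equal(d$end, o$end)
  }
})

test_that("domain invariants hold: basal containment, neighbor exclusion, monotonicity", {
  set.seed(17)
  for (case in 1:10) {
    n <- sample(5:40, 1)
    len <- 1500000
    gt <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "c",
                     tss = sort(sample.int(len, n)),
                     strand = sample(c("+", "-"), n, replace = TRUE))
    big <- dom_bed(build_regulatory_domains(gt, c(c = len)))
    small <- dom_bed(build_regulatory_domains(
      gt, c(c = len), domain_params(max_extension = 20000)))
    # domain contains the basal region
    basal <- oracle_domains(gt, c(c = len), max_ext = 0)
    expect_true(all(big$start <= basal$start & big$end >= basal$end))
    # shrinking max_extension never grows a domain
    expect_true(all(small$start >= big$start & small$end <= big$end))
    # a domain never reaches into a non-overlapping neighbor's basal region
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (basal$end[j] <= basal$start[i])
        expect_gte(big$start[i], basal$end[j])
      if (basal$start[j] >= basal$end[i])
        expect_lte(big$end[i], basal$start[j])
    }
  }
})

test_that("interval-to-gene association obeys half-open overlap semantics", {
  gt <- data.frame(gene_id = "g1", chrom = "chr1", tss = 150000,
                   strand = "+")
  dom <- build_regulatory_domains(gt, c(chr1 = 1e6))  # [45000, 251000)
  pk <- function(s, e) bed_to_granges(
    data.frame(chrom = "chr1", start = s, end = e, name = "p"))
  expect_equal(nrow(associate_intervals_to_genes(pk(46000, 46500),
                                                 dom)$pairs), 1)
  # abutting at the domain end: no pair; 1 bp inside: pair
  expect_equal(nrow(associate_intervals_to_genes(pk(251000, 251500),
                                                 dom)$pairs), 0)
  expect_equal(nrow(associate_intervals_to_genes(pk(250999, 251500),
                                                 dom)$pairs), 1)
  # abutting at the start
  expect_equal(nrow(associate_intervals_to_genes(pk(44000, 45000),
                                                 dom)$pairs), 0)
  # empty inputs
  empty <- associate_intervals_to_genes(pk(1, 2)[0], dom)
  expect_equal(nrow(empty$pairs), 0)
})

test_that("association matches the quadratic overlap oracle on random peaks", {
  set.seed(13)
  for (case in 1:5) {
    gt <- data.frame(gene_id = sprintf("g%d", 1:5), chrom = "c",
                     tss = sort(sample.int(9e5, 5)) ,
                     strand = sample(c("+", "-"), 5, replace = TRUE))
    dom <- build_regulatory_domains(gt, c(c = 1e6))
    peaks <- data.frame(chrom = "c",
                        start = sample.int(950000, 20),
                        name = sprintf("p%02d", 1:20))
    peaks$end <- peaks$start + sample(200:5000, 20, replace = TRUE)
    got <- associate_intervals_to_genes(bed_to_granges(peaks), dom)
    domdf <- granges_to_bed(dom)
    want <- oracle_overlap_pairs(peaks, domdf)
    got_keys <- sort(paste(got$pairs$interval_idx, got$pairs$gene_id))
    want_keys <- if (is.null(want)) character(0)
      else sort(paste(want$i, domdf$name[want$j]))
    expect_equal(got_keys, want_keys)
    # unmapped = peaks absent from every pair
    expect_setequal(got$unmapped, setdiff(1:20, got$pairs$interval_idx))
  }
})

test_that("identity-peak selection composes association with identity lists", {
  gt <- data.frame(gene_id = c("gA", "gB"), chrom = "c",
                   tss = c(100000, 600000), strand = "+")
  dom <- build_regulatory_domains(gt, c(c = 1e6))
  peaks <- bed_to_granges(data.frame(
    chrom = "c", start = c(50000, 120000, 550000, 900000),
    end = c(50500, 120500, 550500, 900500),
    name = sprintf("p%d", 1:4)))
  by_type <- list(t1 = peaks, t2 = peaks)
  sel <- select_identity_peaks(by_type, list(t1 = "gA", t2 = "gB"), dom)
  expect_equal(S4Vectors::mcols(sel$t1)$name, c("p1", "p2"))
  expect_equal(S4Vectors::mcols(sel$t2)$name, "p3")
  # no identity genes -> empty set with warning
  expect_warning(sel0 <- select_identity_peaks(by_type,
                                               list(t1 = character(0)), dom),
                 "no identity genes")
  expect_equal(length(sel0$t1), 0)
  # all peaks inside one identity-gene domain are retained
  inside <- bed_to_granges(data.frame(chrom = "c",
                                      start = c(96000, 98000),
                                      end = c(96500, 98500),
                                      name = c("q1", "q2")))
  expect_equal(length(select_identity_peaks(list(t1 = inside),
                                            list(t1 = "gA"), dom)$t1), 2)
  # unknown identity gene rejected
  expect_error(select_identity_peaks(by_type, list(t1 = "nope"), dom),
               "missing from the domain map")
})
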