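#' Simulate peak intervals and binary accessibility matrices for two strains
#'
#' Peaks are non-overlapping fixed-width intervals: one subset centered on
#' gene TSSs, the remainder placed uniformly (rejection-sampled against
#' overlap).  For every cell type a pair of binary peaks-by-cells matrices is
#' drawn (strain 1 / strain 2).  Most peaks are Bernoulli(`acc_p_background`)
#' in both strains; per cell type, a planted fraction `diff_peak_frac` of
#' peaks is strain-differential with accessibility `acc_p1` vs `acc_p2`, the
#' direction balanced (half the planted peaks have the pair swapped) so both
#' gain and loss of accessibility occur.
#'
#' @param cfg a [sim_config()].
#' @param gene_table output of [simulate_genome_annotation()].
#' @param frac_tss_peaks fraction of peaks centered on TSSs.
#' @return list with
#'   \item{peaks}{GRanges of the shared peak universe, `name` = peak id}
#'   \item{matrices}{per cell type, a list of two binary dgCMatrix
#'     (`strain1`, `strain2`), peaks x cells}
#'   \item{truth}{data.frame `(peak_id, cell_type, p1, p2)` of planted
#'     differential peaks}
#' @export
simulate_accessibility <- function(cfg, gene_table, frac_tss_peaks = 0.5) {
  validate_sim_config(cfg)
  if (any(c(cfg$acc_p_background, cfg$acc_p1, cfg$acc_p2) < 0) ||
      any(c(cfg$acc_p_background, cfg$acc_p1, cfg$acc_p2) > 1))
    stop("accessibility probabilities must lie in [0, 1]")
  w <- cfg$peak_width
  types <- sprintf("type%02d", seq_len(cfg$n_cell_types))

  with_seed(substream_seed(cfg$seed, "accessibility"), {
    n_tss <- min(as.integer(round(cfg$n_peaks * frac_tss_peaks)),
                 nrow(gene_table))
    tss_idx <- sort(sample.int(nrow(gene_table), n_tss))
    starts <- pmax(0L, gene_table$tss[tss_idx] - as.integer(w / 2))
    df <- data.frame(chrom = gene_table$chrom[tss_idx], start = starts,
                     end = starts + w, stringsAsFactors = FALSE)
    # uniform non-overlapping remainder by rejection
    need <- cfg$n_peaks - nrow(df)
    lens <- cfg$genome
    tries <- 0L
    while (need > 0 && tries < 200L) {
      chrom <- sample(names(lens), need, replace = TRUE,
                      prob = lens / sum(lens))
      start <- floor(runif(need, 0, lens[chrom] - w))
      cand <- data.frame(chrom = chrom, start = as.integer(start),
                         end = as.integer(start) + w,
                         stringsAsFactors = FALSE)
      all <- rbind(df, cand)
      gr <- bed_to_granges(all)
      # a candidate is kept if it hits nothing but itself
      ov <- GenomicRanges::countOverlaps(gr, gr)
      cand_ok <- which(ov[(nrow(df) + 1):nrow(all)] == 1L)
      df <- rbind(df, cand[cand_ok, , drop = FALSE])
      need <- cfg$n_peaks - nrow(df)
      tries <- tries + 1L
    }
    if (need > 0)
      stop("could not place the requested number of non-overlapping peaks")
    o <- order(df$chrom, df$start)
    df <- df[o, , drop = FALSE]
    df$name <- sprintf("peak%05d", seq_len(nrow(df)))
    peaks <- bed_to_granges(df)

    n_cells <- cfg$cells_per_type
    n_planted <- as.integer(round(cfg$n_peaks * cfg$diff_peak_frac))
    truth <- list()
    mats <- list()
    for (t in types) {
      planted <- if (n_planted > 0)
        sort(sample.int(cfg$n_peaks, n_planted)) else integer(0)
      p1 <- rep(cfg$acc_p_background, cfg$n_peaks)
      p2 <- p1
      if (n_planted > 0) {
        flip <- seq_along(planted) %% 2L == 0L  # balanced directions
        p1[planted] <- ifelse(flip, cfg$acc_p2, cfg$acc_p1)
        p2[planted] <- ifelse(flip, cfg$acc_p1, cfg$acc_p2)
        truth[[t]] <- data.frame(peak_id = df$name[planted], cell_type = t,
                                 p1 = p1[planted], p2 = p2[planted],
                                 stringsAsFactors = FALSE)
      }
      draw <- function(p, strain) {
        m <- matrix(rbinom(cfg$n_peaks * n_cells, 1L, rep(p, n_cells)),
                    nrow = cfg$n_peaks, ncol = n_cells)
        dimnames(m) <- list(df$name,
                            sprintf("%s_%s_cell%04d", t, strain,
                                    seq_len(n_cells)))
        methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
      }
      mats[[t]] <- list(strain1 = draw(p1, "s1"), strain2 = draw(p2, "s2"))
    }
  })
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
    else data.frame(peak_id = character(), cell_type = character(),
                    p1 = numeric(), p2 = numeric(), stringsAsFactors = FALSE)
  list(peaks = peaks, matrices = mats, truth = truth)
}

#' Simulate variant, footprint and enhancer tracks with planted enrichment
#'
#' Builds the inputs of the putative-regulatory-variant analysis with known
#' truth.  Each gene's regulatory domain receives a fixed number of short
#' transcription-factor footprints; a fraction of footprints is made
#' "active" by overlapping it with an H3K27ac enhancer peak assigned to
#' strain 1, strain 2 or both.  Planted regulatory variants are placed
#' inside active footprints of each gene's domain with Poisson rate
#' `reg_variant_rate` per non-DEG gene and `variant_enrichment_factor`
#' times that for DEG genes, so the density of (footprint AND active
#' enhancer) variants at DEG domains exceeds the non-DEG density by exactly
#' the configured factor in expectation.  Background variants are placed
#' uniformly outside all footprints, keeping the planted truth exact.
#'
#' @param cfg a [sim_config()].
#' @param gene_table output of [simulate_genome_annotation()].
#' @param domains output of [build_regulatory_domains()] for `gene_table`.
#' @param fp_per_gene footprints planted per gene domain.
#' @param fp_width,enh_width footprint / enhancer widths (bp).
#' @param frac_active fraction of footprints overlapped by an enhancer.
#' @param frac_diff_enh fraction of enhancers marked differential.
#' @return list with
#'   \item{variants}{data.frame `(chrom, pos, id, ref, alt)` (1-based)}
#'   \item{footprints, enhancers_strain1, enhancers_strain2,
#'     diff_enhancers}{GRanges tracks}
#'   \item{deg_table}{data.frame `(gene_id, log2fc, fdr)`}
#'   \item{truth}{data.frame per variant: `id`, `is_regulatory`, `gene_id`
#'     (target domain or NA), `in_deg_domain`}
#' @export
simulate_variant_tracks <- function(cfg, gene_table, domains,
                                    fp_per_gene = 3L, fp_width = 20L,
                                    enh_width = 1000L, frac_active = 0.8,
                                    frac_diff_enh = 0.3) {
  validate_sim_config(cfg)
  dom <- granges_to_bed(domains)
  if (nrow(dom) == 0) stop("'domains' is empty")
  stopifnot(identical(dom$name, gene_table$gene_id))
  lens <- cfg$genome

  with_seed(substream_seed(cfg$seed, "variants"), {
    ## DEG designation
    n_deg <- as.integer(round(nrow(gene_table) * cfg$frac_deg))
    deg_idx <- sort(sample.int(nrow(gene_table), n_deg))
    is_deg <- seq_len(nrow(gene_table)) %in% deg_idx
    deg_table <- data.frame(
      gene_id = gene_table$gene_id,
      log2fc = round(ifelse(is_deg,
                            sample(c(-1, 1), nrow(gene_table), TRUE) *
                              runif(nrow(gene_table), 1.2, 4),
                            stats::rnorm(nrow(gene_table), 0, 0.3)), 4),
      fdr = round(ifelse(is_deg, runif(nrow(gene_table), 1e-6, 0.049),
                         runif(nrow(gene_table), 0.051, 1)), 6),
      stringsAsFactors = FALSE)

    ## footprints inside each gene domain
    fp <- list()
    for (i in seq_len(nrow(dom))) {
      lo <- dom$start[i]; hi <- dom$end[i] - fp_width
      if (hi <= lo) hi <- lo + 1L
      s <- floor(runif(fp_per_gene, lo, hi))
      fp[[i]] <- data.frame(chrom = dom$chrom[i], start = as.integer(s),
                            end = as.integer(s) + fp_width,
                            gene_idx = i, stringsAsFactors = FALSE)
    }
    fp <- do.call(rbind, fp)
    ## extra intergenic footprints up to n_footprints
    extra <- max(0L, cfg$n_footprints - nrow(fp))
    if (extra > 0) {
      chrom <- sample(names(lens), extra, replace = TRUE,
                      prob = lens / sum(lens))
      s <- floor(runif(extra, 0, lens[chrom] - fp_width))
      fp <- rbind(fp, data.frame(chrom = chrom, start = as.integer(s),
                                 end = as.integer(s) + fp_width,
                                 gene_idx = NA_integer_,
                                 stringsAsFactors = FALSE))
    }
    o <- order(fp$chrom, fp$start)
    fp <- fp[o, , drop = FALSE]
    fp$name <- sprintf("fp%05d", seq_len(nrow(fp)))
    rownames(fp) <- NULL

    ## activity: each gene's domain keeps >= 1 active footprint so planted
    ## variants always have a target; others active with prob frac_active
    active <- runif(nrow(fp)) < frac_active
    for (i in seq_len(nrow(dom))) {
      members <- which(fp$gene_idx == i)
      if (length(members) && !any(active[members]))
        active[members[1]] <- TRUE
    }
    enh_src <- which(active)
    centers <- floor((fp$start[enh_src] + fp$end[enh_src]) / 2)
    es <- pmax(0L, as.integer(centers - enh_width / 2))
    enh <- data.frame(chrom = fp$chrom[enh_src], start = es,
                      end = es + as.integer(enh_width),
                      name = sprintf("enh%05d", seq_along(enh_src)),
                      stringsAsFactors = FALSE)
    strain_of <- sample(c("strain1", "strain2", "both"), nrow(enh),
                        replace = TRUE, prob = c(0.3, 0.3, 0.4))
    is_diff <- runif(nrow(enh)) < frac_diff_enh

    ## planted regulatory variants inside active domain footprints
    rate <- cfg$reg_variant_rate *
      ifelse(is_deg, cfg$variant_enrichment_factor, 1)
    k <- rpois(nrow(dom), rate)
    reg <- list()
    for (i in which(k > 0)) {
      members <- which(fp$gene_idx == i & active)
      pick <- members[sample.int(length(members), k[i], replace = TRUE)]
      pos <- fp$start[pick] + floor(runif(k[i], 0, fp_width))  # 0-based
      reg[[length(reg) + 1L]] <- data.frame(
        chrom = fp$chrom[pick], pos0 = as.integer(pos),
        gene_id = gene_table$gene_id[i], in_deg = is_deg[i],
        stringsAsFactors = FALSE)
    }
    reg <- if (length(reg)) do.call(rbind, reg) else
      data.frame(chrom = character(), pos0 = integer(),
                 gene_id = character(), in_deg = logical(),
                 stringsAsFactors = FALSE)

    ## background variants strictly outside all footprints
    n_bg <- max(0L, cfg$n_variants - nrow(reg))
    fp_gr <- bed_to_granges(fp)
    bg <- data.frame(chrom = character(), pos0 = integer(),
                     stringsAsFactors = FALSE)
    while (nrow(bg) < n_bg) {
      m <- n_bg - nrow(bg)
      chrom <- sample(names(lens), m, replace = TRUE, prob = lens / sum(lens))
      pos0 <- floor(runif(m, 0, lens[chrom] - 1))
      cand <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(pos0 + 1, pos0 + 1))
      outside <- GenomicRanges::countOverlaps(cand, fp_gr) == 0L
      bg <- rbind(bg, data.frame(chrom = chrom[outside],
                                 pos0 = as.integer(pos0[outside]),
                                 stringsAsFactors = FALSE))
    }

    nt <- c("A", "C", "G", "T")
    all_v <- rbind(
      data.frame(chrom = reg$chrom, pos0 = reg$pos0,
                 is_regulatory = rep(TRUE, nrow(reg)),
                 gene_id = reg$gene_id, in_deg_domain = reg$in_deg,
                 stringsAsFactors = FALSE),
      data.frame(chrom = bg$chrom, pos0 = bg$pos0,
                 is_regulatory = rep(FALSE, nrow(bg)),
                 gene_id = rep(NA_character_, nrow(bg)),
                 in_deg_domain = rep(FALSE, nrow(bg)),
                 stringsAsFactors = FALSE))
    o <- order(all_v$chrom, all_v$pos0)
    all_v <- all_v[o, , drop = FALSE]
    all_v$id <- sprintf("var%06d", seq_len(nrow(all_v)))
    ref <- sample(nt, nrow(all_v), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")
  })

  variants <- data.frame(chrom = all_v$chrom, pos = all_v$pos0 + 1L,
                         id = all_v$id, ref = ref, alt = unname(alt),
                         stringsAsFactors = FALSE)
  fp$score <- 0L
  fp$strand <- "."
  list(
    variants = variants,
    footprints = bed_to_granges(fp[, c("chrom", "start", "end", "name")]),
    enhancers_strain1 = bed_to_granges(
      enh[strain_of %in% c("strain1", "both"), , drop = FALSE]),
    enhancers_strain2 = bed_to_granges(
      enh[strain_of %in% c("strain2", "both"), , drop = FALSE]),
    diff_enhancers = bed_to_granges(enh[is_diff, , drop = FALSE]),
    deg_table = deg_table,
    truth = data.frame(id = all_v$id, is_regulatory = all_v$is_regulatory,
                       gene_id = all_v$gene_id,
                       in_deg_domain = all_v$in_deg_domain,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate per-cell-type read positions around peaks
#'
#' A deliberately simple read model for exercising the signal-aggregation
#' and gene-activity stages: each cell type's reads are a mixture of reads
#' uniform over its own peaks (weighted toward its identity peaks) and
#' uniform genomic background.  Not a fragment-level ATAC simulator.
#'
#' @param cfg a [sim_config()].
#' @param peaks GRanges peak universe.
#' @param peaks_by_type named list (cell type -> GRanges) of the peaks each
#'   type is enriched in.
#' @param reads_per_type reads generated per cell type.
#' @param frac_in_peaks fraction of reads falling in the type's own peaks.
#' @return data.frame `(chrom, pos, barcode, cell_type)`; `pos` 0-based.
#' @export
simulate_reads <- function(cfg, peaks, peaks_by_type,
                           reads_per_type = 20000L, frac_in_peaks = 0.6) {
  validate_sim_config(cfg)
  lens <- cfg$genome
  out <- list()
  with_seed(substream_seed(cfg$seed, "reads"), {
    for (t in names(peaks_by_type)) {
      own <- granges_to_bed(peaks_by_type[[t]])
      n_in <- if (nrow(own)) as.integer(round(reads_per_type * frac_in_peaks))
        else 0L
      n_bg <- reads_per_type - n_in
      pk <- if (n_in > 0) own[sample.int(nrow(own), n_in, replace = TRUE), ]
        else own[0, ]
      pos_in <- if (n_in > 0)
        as.integer(floor(runif(n_in, pk$start, pk$end))) else integer(0)
      chrom_bg <- sample(names(lens), n_bg, replace = TRUE,
                         prob = lens / sum(lens))
      pos_bg <- as.integer(floor(runif(n_bg, 0, lens[chrom_bg])))
      out[[t]] <- data.frame(
        chrom = c(pk$chrom, chrom_bg),
        pos = c(pos_in, pos_bg),
        barcode = sprintf("%s_cell%04d", t,
                          sample.int(cfg$cells_per_type,
                                     reads_per_type, replace = TRUE)),
        cell_type = t, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
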