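#' Simulate a single-cell expression matrix with planted identity genes
#'
#' Draws a genes-by-cells count matrix from a negative binomial
#' parameterized by (mean, size): every entry uses `nb_mean_background`,
#' except that each cell type owns `n_identity_per_type` planted genes whose
#' counts in that type's cells use `nb_mean_identity`.  The planted gene
#' sets are disjoint across types, emulating the type-selective markers a
#' digital-gene-expression matrix with cluster annotation would carry.
#'
#' @param cfg a [sim_config()].
#' @return list with
#'   \item{counts}{dgCMatrix, genes x cells, dimnames set}
#'   \item{labels}{character vector of cell-type labels, one per cell,
#'     named by cell barcode}
#'   \item{truth}{data.frame `(gene_id, cell_type)` of planted identity
#'     genes}
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 60, n_cell_types = 3,
#'   cells_per_type = 20, n_identity_per_type = 4, seed = 7))
#' dim(sim$counts)
#' @export
simulate_expression <- function(cfg) {
  validate_sim_config(cfg)
  n_cells <- cfg$n_cell_types * cfg$cells_per_type
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  types <- sprintf("type%02d", seq_len(cfg$n_cell_types))
  cells <- sprintf("cell%05d", seq_len(n_cells))
  labels <- rep(types, each = cfg$cells_per_type)
  names(labels) <- cells

  with_seed(substream_seed(cfg$seed, "expression"), {
    m <- matrix(
      rnbinom(cfg$n_genes * n_cells, mu = cfg$nb_mean_background,
              size = cfg$nb_dispersion),
      nrow = cfg$n_genes, ncol = n_cells,
      dimnames = list(genes, cells)
    )
    truth <- data.frame(gene_id = character(), cell_type = character(),
                        stringsAsFactors = FALSE)
    if (cfg$n_identity_per_type > 0) {
      planted <- split(
        genes[seq_len(cfg$n_identity_per_type * cfg$n_cell_types)],
        rep(types, each = cfg$n_identity_per_type)
      )
      for (t in types) {
        idx <- which(labels == t)
        m[planted[[t]], idx] <- rnbinom(
          length(planted[[t]]) * length(idx),
          mu = cfg$nb_mean_identity, size = cfg$nb_dispersion
        )
      }
      truth <- data.frame(
        gene_id = unlist(planted, use.names = FALSE),
        cell_type = rep(types, each = cfg$n_identity_per_type),
        stringsAsFactors = FALSE
      )
    }
  })
  list(counts = methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                        "generalMatrix"), "CsparseMatrix"),
       labels = labels, truth = truth)
}

#' Simulate a gene annotation table
#'
#' Places `n_genes` gene bodies on the configured chromosomes with a
#' minimum TSS spacing, random strand, and gene lengths drawn uniformly.
#' Genes are allocated to chromosomes proportionally to length.
#'
#' @param cfg a [sim_config()].
#' @param min_spacing minimum distance in bp between neighboring TSSs.
#' @param gene_length_range uniform range of gene body lengths (bp).
#' @return data.frame `(gene_id, chrom, start, end, strand, tss)`;
#'   `start`/`end` are the 0-based half-open gene body, `tss` the 0-based
#'   position of the transcription start (= `start` on `+`, `end - 1` on
#'   `-`).
#' @export
simulate_genome_annotation <- function(cfg, min_spacing = 20000L,
                                       gene_length_range = c(2000L, 15000L)) {
  validate_sim_config(cfg)
  lens <- cfg$genome
  n_per <- pmax(0L, as.integer(round(cfg$n_genes * lens / sum(lens))))
  # fix rounding so totals match
  while (sum(n_per) != cfg$n_genes) {
    i <- which.max(lens / (n_per + 1))
    n_per[i] <- n_per[i] + sign(cfg$n_genes - sum(n_per))
  }
  out <- vector("list", length(lens))
  with_seed(substream_seed(cfg$seed, "annotation"), {
    for (ci in seq_along(lens)) {
      n <- n_per[ci]
      if (n == 0L) { out[[ci]] <- NULL; next }
      len <- lens[ci]
      margin <- max(gene_length_range) + min_spacing
      avail <- len - n * min_spacing - margin
      if (avail <= 0)
        stop(sprintf("chromosome %s (%d bp) too small for %d genes at spacing %d",
                     names(lens)[ci], len, n, min_spacing))
      # order statistics of uniform draws + mandatory spacing
      tss <- floor(sort(runif(n, 0, avail))) + min_spacing * (seq_len(n) - 1L) +
        as.integer(min_spacing / 2)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      glen <- floor(runif(n, gene_length_range[1], gene_length_range[2] + 1))
      start <- ifelse(strand == "+", tss, pmax(0, tss - glen + 1))
      end <- ifelse(strand == "+", pmin(len, tss + glen), tss + 1)
      out[[ci]] <- data.frame(chrom = names(lens)[ci], start = as.integer(start),
                              end = as.integer(end), strand = strand,
                              tss = as.integer(tss), stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, out)
  tab <- data.frame(gene_id = sprintf("gene%04d", seq_len(nrow(tab))), tab,
                    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(tab$gene_id), all(tab$tss >= 0),
            all(tab$tss < cfg$genome[tab$chrom]))
  rownames(tab) <- NULL
  tab
}
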