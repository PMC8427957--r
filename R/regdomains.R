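#' Parameters of basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-aware basal region around its TSS
#' (`basal_up` bp upstream, `basal_down` bp downstream; the GREAT defaults
#' 5 kb / 1 kb) which is then extended on both sides by up to
#' `max_extension` bp (100 kb) but stops at the nearest neighboring gene's
#' basal-region boundary, and is clipped to the chromosome.
#'
#' @param basal_up bp upstream of the TSS in the basal region.
#' @param basal_down bp downstream of the TSS.
#' @param max_extension maximum extension beyond each basal edge (bp).
#' @return list of class `domain_params`.
#' @export
domain_params <- function(basal_up = 5000L, basal_down = 1000L,
                          max_extension = 100000L) {
  p <- list(basal_up = as.integer(basal_up),
            basal_down = as.integer(basal_down),
            max_extension = as.integer(max_extension))
  if (any(unlist(p) < 0)) stop("domain parameters must be >= 0")
  p$basal_width <- p$basal_up + p$basal_down
  if (p$basal_width <= 0) stop("basal region must have positive width")
  structure(p, class = "domain_params")
}

#' Build per-gene regulatory domains (basal region +/- extension)
#'
#' All arithmetic is in 0-based half-open coordinates.  On the `+` strand
#' the basal region is `[tss - basal_up, tss + basal_down)`; mirrored on
#' `-`.  Each basal edge is extended outward by `max_extension`, truncating
#' at the nearest other gene's basal boundary that lies fully outside this
#' gene's basal region (a domain always contains its own basal region, so
#' basal regions that overlap it — e.g. genes sharing a TSS — never truncate
#' it).  Domains are clipped to `[0, chrom length)`.
#'
#' @param gene_table data.frame with `gene_id`, `chrom`, `tss`, `strand`
#'   (`tss` 0-based).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param params a [domain_params()].
#' @return GRanges of domains with metadata `name` (gene id); order follows
#'   `gene_table`.
#' @examples
#' gt <- data.frame(gene_id = "g1", chrom = "chr1", tss = 150000,
#'                  strand = "+")
#' build_regulatory_domains(gt, c(chr1 = 1e6))
#' @export
build_regulatory_domains <- function(gene_table, chrom_sizes,
                                     params = domain_params()) {
  stopifnot(inherits(params, "domain_params"),
            all(c("gene_id", "chrom", "tss", "strand") %in%
                  names(gene_table)))
  unknown <- setdiff(unique(gene_table$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  bad <- gene_table$tss < 0 | gene_table$tss >= chrom_sizes[gene_table$chrom]
  if (any(bad))
    stop("TSS outside chromosome bounds for gene(s): ",
         paste(gene_table$gene_id[bad], collapse = ", "))

  plus <- gene_table$strand == "+"
  b_start <- ifelse(plus, gene_table$tss - params$basal_up,
                    gene_table$tss - params$basal_down + 1L)
  b_end <- ifelse(plus, gene_table$tss + params$basal_down,
                  gene_table$tss + params$basal_up + 1L)
  b_start <- pmax(0, b_start)
  b_end <- pmin(as.numeric(chrom_sizes[gene_table$chrom]), b_end)

  n <- nrow(gene_table)
  d_start <- numeric(n)
  d_end <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(gene_table$chrom == gene_table$chrom[i])
    same <- same[same != i]
    left_lim <- c(0, b_end[same][b_end[same] <= b_start[i]])
    right_lim <- c(chrom_sizes[[gene_table$chrom[i]]],
                   b_start[same][b_start[same] >= b_end[i]])
    d_start[i] <- max(b_start[i] - params$max_extension, max(left_lim))
    d_end[i] <- min(b_end[i] + params$max_extension, min(right_lim))
  }
  GenomicRanges::GRanges(
    seqnames = gene_table$chrom,
    ranges = IRanges::IRanges(start = d_start + 1L, end = d_end),
    strand = gene_table$strand,
    name = gene_table$gene_id
  )
}

#' Associate intervals with gene regulatory domains
#'
#' Emits one `(interval, gene)` pair per >= 1 bp overlap between an interval
#' and a gene's regulatory domain (half-open semantics: abutting intervals
#' do not overlap).  An interval may map to several genes.
#'
#' @param intervals GRanges (or BED-style data.frame) of peaks / variants.
#' @param domains GRanges from [build_regulatory_domains()].
#' @return list:
#'   \item{pairs}{data.frame `(interval_idx, interval_name, gene_id)`}
#'   \item{unmapped}{integer indices of intervals overlapping no domain}
#' @export
associate_intervals_to_genes <- function(intervals, domains) {
  intervals <- as_intervals(intervals)
  hits <- GenomicRanges::findOverlaps(intervals, domains,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  nm <- S4Vectors::mcols(intervals)$name
  pairs <- data.frame(
    interval_idx = qi,
    interval_name = if (!is.null(nm)) as.character(nm[qi])
      else sprintf("interval%d", qi),
    gene_id = as.character(
      S4Vectors::mcols(domains)$name[S4Vectors::subjectHits(hits)]),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       unmapped = setdiff(seq_along(intervals), unique(qi)))
}

#' Select cell-type-identity peaks
#'
#' The identity peaks of a cell type are its peaks overlapping the
#' regulatory domain of at least one of that type's identity genes.
#'
#' @param peaks_by_type named list (cell type -> GRanges) of per-type peak
#'   sets; a single GRanges shared by all types is also accepted.
#' @param identity_genes named list (cell type -> character vector of gene
#'   ids), e.g. the `genes` element of [call_identity_genes()].
#' @param domains GRanges from [build_regulatory_domains()]; must contain
#'   every identity gene.
#' @return named list (cell type -> GRanges of identity peaks).
#' @export
select_identity_peaks <- function(peaks_by_type, identity_genes, domains) {
  dom_ids <- as.character(S4Vectors::mcols(domains)$name)
  missing <- setdiff(unlist(identity_genes, use.names = FALSE), dom_ids)
  if (length(missing))
    stop("identity gene(s) missing from the domain map: ",
         paste(head(missing, 5), collapse = ", "))
  shared <- methods::is(peaks_by_type, "GRanges")
  out <- lapply(names(identity_genes), function(t) {
    pk <- as_intervals(if (shared) peaks_by_type else peaks_by_type[[t]])
    ids <- identity_genes[[t]]
    if (length(ids) == 0) {
      warning(sprintf("cell type '%s' has no identity genes", t))
      return(pk[0])
    }
    dom <- domains[dom_ids %in% ids]
    pk[GenomicRanges::countOverlaps(pk, dom, ignore.strand = TRUE) > 0]
  })
  names(out) <- names(identity_genes)
  out
}
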