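#' Read / write the pipeline's on-disk formats
#'
#' Plain-text interchange only: MatrixMarket + TSVs for matrices, 6-column
#' BED (0-based half-open) for intervals, sites-only VCF v4.2 (1-based) for
#' variants, TSV for gene tables and results.  Writers are byte-deterministic
#' for a fixed input so that reruns with the same seed reproduce files
#' exactly.
#'
#' @name snapvar-io
NULL

#' @rdname snapvar-io
#' @param gr intervals as GRanges or BED-style data.frame.
#' @param path output file.
#' @export
write_bed <- function(gr, path) {
  df <- if (is.data.frame(gr)) gr else granges_to_bed(gr)
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0L
  if (!"strand" %in% names(df)) df$strand <- "."
  write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname snapvar-io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::GRanges(gr)
}

#' @rdname snapvar-io
#' @param variants data.frame with `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt` (extra columns ignored).
#' @export
write_sites_vcf <- function(variants, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  id <- if ("id" %in% names(variants)) variants$id else "."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0)
    writeLines(paste(variants$chrom, variants$pos, id, variants$ref,
                     variants$alt, ".", "PASS", ".", sep = "\t"), con)
  invisible(path)
}

#' @rdname snapvar-io
#' @export
read_sites_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = ifelse(length(fx) > 0, 1, 0),
                                     dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0)
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
             id = fx[, "ID"], ref = fx[, "REF"], alt = fx[, "ALT"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname snapvar-io
#' @param mat genes-by-cells (or peaks-by-cells) sparse/dense matrix with
#'   dimnames.
#' @param prefix file prefix; writes `<prefix>.mtx`, `<prefix>.rows.tsv`,
#'   `<prefix>.cols.tsv`.
#' @export
write_mtx <- function(mat, prefix) {
  m <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  writeLines(rownames(mat), paste0(prefix, ".rows.tsv"))
  writeLines(colnames(mat), paste0(prefix, ".cols.tsv"))
  invisible(prefix)
}

#' @rdname snapvar-io
#' @export
read_mtx <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  dimnames(m) <- list(readLines(paste0(prefix, ".rows.tsv")),
                      readLines(paste0(prefix, ".cols.tsv")))
  methods::as(m, "CsparseMatrix")
}

#' @rdname snapvar-io
#' @param df any data.frame.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname snapvar-io
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
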