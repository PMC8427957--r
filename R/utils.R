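#' @importFrom methods is as
#' @importFrom stats rnbinom rbinom rpois runif quantile median p.adjust pnorm
#' @importFrom utils read.table write.table head combn
NULL

# Deterministic per-component seed derived from one global seed.
# Keeps component-level reproducibility: regenerating one input does not
# disturb the random stream of another.  Result always in [0, 2^31 - 2].
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) %% 2147480000 + 97003 * (h %% 21001)) %% 2147480000)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Convert a BED-style table (0-based half-open) to GRanges
#'
#' All interval files handled by the package are BED-convention 0-based
#' half-open; internally intervals live in `GRanges` (1-based closed).
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (BED column order is also accepted without
#'   names).
#' @return a [GenomicRanges::GRanges] with any extra columns as metadata.
#' @export
bed_to_granges <- function(df) {
  stopifnot(is.data.frame(df))
  if (is.null(names(df)) || !all(c("chrom", "start", "end") %in% names(df))) {
    nm <- c("chrom", "start", "end", "name", "score", "strand")
    names(df)[seq_len(min(ncol(df), 6L))] <- nm[seq_len(min(ncol(df), 6L))]
  }
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  for (cn in extra) S4Vectors::mcols(gr)[[cn]] <- df[[cn]]
  gr
}

#' Convert GRanges to a BED-style data.frame (0-based half-open)
#' @param gr a GRanges.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
granges_to_bed <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(mc)) as.character(mc$name)
      else rep(".", length(gr)),
    score = if ("score" %in% names(mc)) mc$score else rep(0L, length(gr)),
    strand = {
      s <- as.character(GenomicRanges::strand(gr)); s[s == "*"] <- "."; s
    },
    stringsAsFactors = FALSE
  )
}

# coerce peaks/footprints/enhancers input (GRanges or BED data.frame)
as_intervals <- function(x) {
  if (methods::is(x, "GRanges")) x else bed_to_granges(x)
}
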