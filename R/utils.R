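#' @importFrom stats approx lowess loess median prcomp cor dist hclust predict
#'   quantile model.matrix lm.fit lm.wfit rbinom rnbinom rnorm runif setNames
#'   ecdf complete.cases
#' @importFrom utils read.delim write.table head tail
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() wrapper that never truncates the offender list mid-word
.stop <- function(...) stop(..., call. = FALSE)

.assert_matrix_like <- function(x, what = "counts") {
  if (!is.matrix(x)) .stop(what, " must be a matrix with row and column names")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stop(what, " must carry rownames (features) and colnames (samples)")
  invisible(x)
}

## seqlengths-aware GRanges from a plain 1-based inclusive table
.df_to_granges <- function(df, chrom_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if ("strand" %in% names(df)) sub("^\\.$", "*", df$strand) else "*"
  )
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths
  }
  gr
}
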