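## Contamination diagnostics: read-distribution percentages (incl. IR%),
## expression normalisation/transforms, percent-expressed, and sample
## similarity summaries. All diagnostics return plain tables/matrices so they
## can be inspected, tested and rendered with any plotting front end.

#' Read-distribution percentages and the intergenic read fraction (IR%)
#'
#' For each sample, the percentage of fragments assigned to each exclusive
#' category (exon, intron, intergenic) out of all fragments assigned to their
#' union, so the three percentages sum to 100; IR% is the intergenic entry.
#' rRNA and organellar fractions are reported against the same denominator but
#' sit outside the 100% budget (they are tallied non-exclusively), as is the
#' gene-assigned fraction.
#'
#' @param assignments A `fragment_assignment` or list of them.
#' @return Data frame with one row per sample: `sample_id`, `exon_pct`,
#'   `intron_pct`, `intergenic_pct` (= `ir_percent`), `rRNA_pct`,
#'   `organellar_pct`, `gene_pct`, `ir_percent`.
#' @export
read_distribution <- function(assignments) {
  if (is(assignments, "fragment_assignment")) assignments <- list(assignments)
  rows <- lapply(assignments, function(a) {
    ac <- a$totals$assigned_per_category
    denom <- sum(ac[.CATEGORY_PRECEDENCE])
    if (denom == 0)
      .stop("sample '", a$sample_id,
            "' has zero fragments assigned to exon/intron/intergenic")
    data.frame(
      sample_id = a$sample_id,
      exon_pct = 100 * ac[["collapsed_exon"]] / denom,
      intron_pct = 100 * ac[["intron"]] / denom,
      intergenic_pct = 100 * ac[["intergenic"]] / denom,
      rRNA_pct = 100 * ac[["rRNA_exon"]] / denom,
      organellar_pct = 100 * ac[["organellar"]] / denom,
      gene_pct = 100 * sum(a$per_gene_counts) / denom,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$ir_percent <- out$intergenic_pct
  rownames(out) <- NULL
  out
}

#' Counts per million
#'
#' @param counts Gene-by-sample count matrix.
#' @return Matrix of `counts / column sum * 1e6`.
#' @export
cpm <- function(counts) {
  .assert_matrix_like(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0))
    .stop("zero library size for sample(s): ",
          paste(colnames(counts)[libsize == 0], collapse = ", "))
  sweep(counts, 2L, libsize, "/") * 1e6
}

#' Transcripts per million from counts and lengths
#'
#' `TPM_gs = (counts_gs / lengths_gs) / sum_g(counts_gs / lengths_gs) * 1e6`;
#' every column sums to 1e6.
#'
#' @param counts Gene-by-sample count matrix.
#' @param lengths Gene-by-sample length matrix (or per-gene vector), bp.
#' @return TPM matrix.
#' @export
tpm_from <- function(counts, lengths) {
  .assert_matrix_like(counts)
  if (!is.matrix(lengths))
    lengths <- matrix(lengths, nrow = nrow(counts), ncol = ncol(counts),
                      dimnames = dimnames(counts))
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0))
    .stop("zero total length-normalised count for sample(s): ",
          paste(colnames(counts)[denom == 0], collapse = ", "))
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' Per-sample size factor: the median, over genes with a positive geometric
#' mean across samples, of `counts_gs / geometric_mean_g`.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors_median_ratio <- function(counts) {
  .assert_matrix_like(counts)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    .stop("no gene has a nonzero count in every sample; cannot compute size factors")
  ratios <- sweep(log(counts[use, , drop = FALSE]), 1L, loggeo[use], "-")
  setNames(exp(apply(ratios, 2L, median)), colnames(counts))
}

#' Per-sample expression distribution summaries
#'
#' Two transform modes:
#' \describe{
#'   \item{log2_norm_p1}{median-of-ratios normalisation, then
#'     `log2(normalised + 1)`;}
#'   \item{log2_cpm_ecdf}{CPM plus a pseudocount of one tenth of the minimal
#'     positive CPM in the matrix, then `log2`.}
#' }
#' Returns per-sample quantiles at probabilities 0/0.25/0.5/0.75/1 and the
#' ECDF of each sample evaluated on a common grid.
#'
#' @param counts Gene-by-sample count matrix.
#' @param mode Transform mode, see above.
#' @param grid_n Number of ECDF evaluation points.
#' @return List with `transformed` (matrix), `quantiles`
#'   (sample x probability), `ecdf_grid`, `ecdf` (sample x grid).
#' @export
expression_summaries <- function(counts,
                                 mode = c("log2_norm_p1", "log2_cpm_ecdf"),
                                 grid_n = 101L) {
  mode <- match.arg(mode)
  .assert_matrix_like(counts)
  if (all(counts == 0)) .stop("all-zero count matrix")
  if (mode == "log2_norm_p1") {
    sf <- size_factors_median_ratio(counts)
    y <- log2(sweep(counts, 2L, sf, "/") + 1)
  } else {
    cc <- cpm(counts)
    minpos <- min(cc[cc > 0])
    y <- log2(cc + minpos / 10)
  }
  probs <- c(0, 0.25, 0.5, 0.75, 1)
  q <- t(apply(y, 2L, quantile, probs = probs))
  colnames(q) <- paste0("q", probs)
  grid <- seq(min(y), max(y), length.out = grid_n)
  ec <- t(apply(y, 2L, function(col) ecdf(col)(grid)))
  colnames(ec) <- NULL
  list(transformed = y, quantiles = q, ecdf_grid = grid, ecdf = ec)
}

#' Percentage of expressed genes per sample
#'
#' `100 * #\{genes with value > cutoff\} / #genes` (strict comparison).
#'
#' @param expr_matrix Gene-by-sample CPM or TPM matrix.
#' @param cutoff Positive expression cutoff (same unit as the matrix).
#' @return Named numeric vector of percentages.
#' @export
percent_expressed <- function(expr_matrix, cutoff = 1) {
  .assert_matrix_like(expr_matrix, "expr_matrix")
  if (cutoff <= 0) .stop("cutoff must be > 0")
  100 * colMeans(expr_matrix > cutoff)
}

#' Sample similarity: correlations, distances, PCA, clustering order
#'
#' On a transformed (e.g. log-scale) gene-by-sample matrix, computes pairwise
#' Pearson correlations, Euclidean distances between sample columns, PCA on
#' the gene-wise centred and scaled matrix (zero-variance genes dropped) with
#' variance-explained fractions, and the complete-linkage dendrogram order.
#'
#' @param log_matrix Transformed gene-by-sample matrix.
#' @return List with `correlation`, `distances`, `pca_scores`,
#'   `variance_explained`, `hclust_order`.
#' @export
sample_similarity <- function(log_matrix) {
  .assert_matrix_like(log_matrix, "log_matrix")
  if (ncol(log_matrix) < 2L) .stop("need at least 2 samples")
  corr <- cor(log_matrix, method = "pearson")
  dmat <- as.matrix(dist(t(log_matrix), method = "euclidean"))
  v <- apply(log_matrix, 1L, stats::var)
  keep <- v > 0 & is.finite(v)
  pca <- prcomp(t(log_matrix[keep, , drop = FALSE]), center = TRUE, scale. = TRUE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  hc <- hclust(dist(t(log_matrix)), method = "complete")
  list(correlation = corr, distances = dmat, pca_scores = pca$x,
       variance_explained = ve, hclust_order = colnames(log_matrix)[hc$order])
}

#' Full diagnostics report
#'
#' Convenience wrapper assembling the diagnostic battery: read-distribution
#' percentages with IR%, percent expressed genes at CPM/TPM cutoffs,
#' expression summaries, and sample similarity on the normalised log scale.
#'
#' @param assignments List of `fragment_assignment` objects.
#' @param expr A `gene_expr` (counts and lengths).
#' @param cpm_cutoff,tpm_cutoff Expressed-gene cutoffs.
#' @return A list of class `gdna_diagnostics`.
#' @export
diagnose_contamination <- function(assignments, expr, cpm_cutoff = 1,
                                   tpm_cutoff = 1) {
  rd <- read_distribution(assignments)
  cc <- cpm(expr$counts)
  pe_cpm <- percent_expressed(cc, cpm_cutoff)
  pe_tpm <- if (!is.null(expr$lengths))
    percent_expressed(
      if (!is.null(expr$tpm)) expr$tpm else tpm_from(expr$counts, expr$lengths),
      tpm_cutoff)
  else NULL
  es <- expression_summaries(expr$counts, "log2_norm_p1")
  sim <- if (ncol(expr$counts) >= 2L) sample_similarity(es$transformed) else NULL
  structure(list(read_distribution = rd, ir_percent = setNames(rd$ir_percent, rd$sample_id),
                 pct_expressed_cpm = pe_cpm, pct_expressed_tpm = pe_tpm,
                 expression_summaries = es, similarity = sim),
            class = "gdna_diagnostics")
}

#' @export
print.gdna_diagnostics <- function(x, ...) {
  cat("gDNA contamination diagnostics (", nrow(x$read_distribution),
      " samples)\n", sep = "")
  cat("IR% per sample:\n")
  print(round(x$ir_percent, 3))
  cat("% genes > cutoff (CPM):\n")
  print(round(x$pct_expressed_cpm, 2))
  invisible(x)
}
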