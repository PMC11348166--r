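## The contamination estimator: per-sample genomic-DNA contamination level as
## fragments-per-base (FPB) coverage of intergenic regions, either as a single
## global scalar (median FPB over non-zero intergenic regions) or stratified
## into 20 equal-width GC bins through a loess fit of FPB on GC content.

.N_GC_BINS <- 20L

#' GC bin index
#'
#' Maps GC fractions to 20 equal-width bins: bin `b` (1-based) covers
#' `[(b-1)/20, b/20)`; the last bin is closed so GC = 1 falls in bin 20.
#'
#' @param gc Numeric vector of GC fractions in `[0, 1]`.
#' @return Integer bin index in `1..20` (`NA` for `NA` input).
#' @export
gc_bin <- function(gc) {
  b <- floor(gc * .N_GC_BINS) + 1L
  b[!is.na(gc) & gc >= 1] <- .N_GC_BINS
  as.integer(b)
}

.align_regions <- function(counts, region_lengths) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = 1L,
                     dimnames = list(names(counts), "sample"))
  if (!is.null(names(region_lengths)) && !is.null(rownames(counts))) {
    miss <- setdiff(rownames(counts), names(region_lengths))
    if (length(miss))
      .stop("region(s) without a length: ", paste(head(miss, 5L), collapse = ", "))
    region_lengths <- region_lengths[rownames(counts)]
  }
  if (length(region_lengths) != nrow(counts))
    .stop("region_lengths must match the rows of the count matrix")
  list(counts = counts, lengths = as.numeric(region_lengths))
}

#' Global contamination level: median intergenic FPB
#'
#' For each sample, divides intergenic fragment counts by region lengths and
#' returns the median FPB over regions with a non-zero count — the global
#' gDNA contamination estimate.
#'
#' @param intergenic_counts Region-by-sample count matrix (or a vector for one
#'   sample), rows named by region id.
#' @param region_lengths Region lengths in bp, named by region id.
#' @return Named numeric vector: one global FPB per sample.
#' @export
estimate_global_fpb <- function(intergenic_counts, region_lengths) {
  al <- .align_regions(intergenic_counts, region_lengths)
  out <- vapply(seq_len(ncol(al$counts)), function(s) {
    cnt <- al$counts[, s]
    nz <- cnt > 0
    if (!any(nz))
      .stop("sample '", colnames(al$counts)[s],
            "': all intergenic counts are zero — no evidence of contamination; ",
            "correction unnecessary")
    median(cnt[nz] / al$lengths[nz])
  }, 0)
  setNames(out, colnames(al$counts))
}

#' GC-stratified contamination levels via loess
#'
#' For each sample, fits a loess regression of intergenic FPB (non-zero
#' regions) on GC content, predicts FPB at the GC of every member region, and
#' takes the median of predictions within each of 20 equal-width GC bins as
#' that bin's contamination estimate. Bins without member regions inherit the
#' nearest populated bin's estimate; estimates are clamped at zero. With fewer
#' than `min_regions` usable regions or fewer than `min_bins` distinct GC
#' bins, all bins fall back to the global estimate with a warning.
#'
#' @param intergenic_counts Region-by-sample count matrix (or vector).
#' @param region_lengths Region lengths in bp, named by region id.
#' @param region_gc A `gc_profile` (or named numeric vector) of region GC.
#' @param span Loess span (default 0.75, degree 2).
#' @param min_regions,min_bins Minimum data requirements for the loess route.
#' @return 20-by-sample matrix of per-bin FPB estimates.
#' @export
fit_gc_model <- function(intergenic_counts, region_lengths, region_gc,
                         span = 0.75, min_regions = 20L, min_bins = 3L) {
  al <- .align_regions(intergenic_counts, region_lengths)
  if (is.data.frame(region_gc)) region_gc <- setNames(region_gc$gc, region_gc$id)
  if (!is.null(rownames(al$counts))) {
    miss <- setdiff(rownames(al$counts), names(region_gc))
    if (length(miss))
      .stop("region(s) without GC: ", paste(head(miss, 5L), collapse = ", "))
    region_gc <- region_gc[rownames(al$counts)]
  }
  globals <- estimate_global_fpb(al$counts, al$lengths)
  out <- matrix(NA_real_, .N_GC_BINS, ncol(al$counts),
                dimnames = list(paste0("gc_bin_", seq_len(.N_GC_BINS)),
                                colnames(al$counts)))
  for (s in seq_len(ncol(al$counts))) {
    cnt <- al$counts[, s]
    use <- cnt > 0 & !is.na(region_gc)
    gc <- region_gc[use]
    fpb <- cnt[use] / al$lengths[use]
    bins <- gc_bin(gc)
    if (sum(use) < min_regions || length(unique(bins)) < min_bins) {
      warning("sample '", colnames(al$counts)[s], "': too few regions/bins (",
              sum(use), " regions, ", length(unique(bins)),
              " bins); falling back to the global FPB for all GC bins")
      out[, s] <- globals[s]
      next
    }
    fit <- loess(fpb ~ gc, span = span, degree = 2,
                 control = stats::loess.control(surface = "direct"))
    pred <- predict(fit, newdata = data.frame(gc = gc))
    est <- rep(NA_real_, .N_GC_BINS)
    med <- tapply(pred, bins, median)
    est[as.integer(names(med))] <- as.numeric(med)
    pop <- which(!is.na(est))
    for (b in which(is.na(est)))
      est[b] <- est[pop[which.min(abs(pop - b))]]
    out[, s] <- pmax(est, 0)
  }
  out
}

#' Fit a gDNA contamination model from intergenic coverage
#'
#' The central estimator. Computes, per sample, the global contamination level
#' (median FPB over non-zero intergenic regions) and, when
#' `method = "gc"`, the 20 GC-bin FPB estimates from a loess fit of FPB on GC.
#'
#' @param intergenic_counts Region-by-sample count matrix of intergenic
#'   fragment counts (rows named by region id), or a vector for one sample.
#' @param region_lengths Region lengths in bp, named by region id.
#' @param region_gc Region GC content (`gc_profile` or named vector); required
#'   for `method = "gc"`.
#' @param method `"global"` or `"gc"`.
#' @param span Loess span for the GC route.
#' @return An object of class `contamination_fit` with components
#'   `global_fpb`, `gc_bin_fpb` (20 x samples, or `NULL`), `method`, `span`
#'   and `n_regions_used`.
#' @seealso [global_correction()], [gc_correction()],
#'   [predict.contamination_fit()]
#' @export
contamination_fit <- function(intergenic_counts, region_lengths,
                              region_gc = NULL,
                              method = c("global", "gc"), span = 0.75) {
  method <- match.arg(method)
  al <- .align_regions(intergenic_counts, region_lengths)
  global_fpb <- estimate_global_fpb(al$counts, al$lengths)
  gc_bin_fpb <- NULL
  if (method == "gc") {
    if (is.null(region_gc)) .stop("method 'gc' requires region_gc")
    gc_bin_fpb <- fit_gc_model(al$counts, al$lengths, region_gc, span = span)
  }
  structure(list(
    method = method,
    global_fpb = global_fpb,
    gc_bin_fpb = gc_bin_fpb,
    span = span,
    n_regions_used = colSums(al$counts > 0)
  ), class = "contamination_fit")
}

#' @export
print.contamination_fit <- function(x, ...) {
  cat("gDNA contamination fit (method: ", x$method, ")\n", sep = "")
  cat("Global FPB (median over non-zero intergenic regions):\n")
  print(signif(x$global_fpb, 4))
  if (!is.null(x$gc_bin_fpb)) {
    cat("GC-bin FPB range per sample:\n")
    print(t(apply(x$gc_bin_fpb, 2L, range)))
  }
  invisible(x)
}

#' @export
summary.contamination_fit <- function(object, ...) {
  data.frame(
    sample_id = names(object$global_fpb),
    global_fpb = as.numeric(object$global_fpb),
    n_regions_used = as.integer(object$n_regions_used),
    method = object$method,
    row.names = NULL
  )
}

#' Extract contamination-level coefficients
#'
#' @param object A `contamination_fit`.
#' @param ... Unused.
#' @return The global FPB vector (method `"global"`) or the 20 x sample
#'   GC-bin FPB matrix (method `"gc"`).
#' @export
coef.contamination_fit <- function(object, ...) {
  if (object$method == "gc") object$gc_bin_fpb else object$global_fpb
}

#' Predict per-gene contamination counts
#'
#' Expected gDNA-derived fragment counts per gene and sample: the sample's
#' contamination FPB (global, or the GC bin matching the gene's GC) times the
#' gene length. Genes with undefined GC fall back to the global estimate.
#'
#' @param object A `contamination_fit`.
#' @param gene_lengths Gene-by-sample length matrix or per-gene vector (bp).
#' @param gene_gc Gene GC (`gc_profile` or named vector); required for the
#'   GC route.
#' @param ... Unused.
#' @return Gene-by-sample matrix of expected contamination counts.
#' @export
predict.contamination_fit <- function(object, gene_lengths, gene_gc = NULL, ...) {
  samples <- names(object$global_fpb)
  if (!is.matrix(gene_lengths)) {
    if (is.null(names(gene_lengths))) .stop("gene_lengths must be named")
    gene_lengths <- matrix(gene_lengths, nrow = length(gene_lengths),
                           ncol = length(samples),
                           dimnames = list(names(gene_lengths), samples))
  }
  if (anyNA(match(samples, colnames(gene_lengths))))
    .stop("gene_lengths columns must cover the fitted samples")
  gene_lengths <- gene_lengths[, samples, drop = FALSE]
  if (object$method == "global") {
    contam <- sweep(gene_lengths, 2L, object$global_fpb, "*")
  } else {
    if (is.null(gene_gc)) .stop("method 'gc' requires gene_gc")
    if (is.data.frame(gene_gc)) gene_gc <- setNames(gene_gc$gc, gene_gc$id)
    miss <- setdiff(rownames(gene_lengths), names(gene_gc))
    if (length(miss))
      .stop("gene(s) without GC: ", paste(head(miss, 5L), collapse = ", "))
    gc <- gene_gc[rownames(gene_lengths)]
    bins <- gc_bin(gc)
    fpb <- matrix(NA_real_, nrow(gene_lengths), length(samples),
                  dimnames = dimnames(gene_lengths))
    ok <- !is.na(bins)
    fpb[ok, ] <- object$gc_bin_fpb[bins[ok], , drop = FALSE]
    if (any(!ok))
      fpb[!ok, ] <- matrix(object$global_fpb, sum(!ok), length(samples),
                           byrow = TRUE)
    contam <- fpb * gene_lengths
  }
  contam
}
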