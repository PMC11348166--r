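## The four correction algorithms and the two optional post-correction gene
## filters. Count-scale corrections (global, GC, stranded) subtract expected
## contamination, clamp at zero and round to the nearest integer so the output
## remains valid input for count-based differential-expression tools. The IR%
## method instead returns an adjusted log2-CPM matrix from a precision-weighted
## linear model with the intergenic read fraction as a covariate.

.new_corrected <- function(method, mat, covariates = NULL, params = list()) {
  structure(list(method = method, matrix = mat, covariates = covariates,
                 params = params),
            class = "corrected_expr")
}

#' @export
print.corrected_expr <- function(x, ...) {
  cat("gDNA-corrected expression [method: ", x$method, "]: ",
      nrow(x$matrix), " genes x ", ncol(x$matrix), " samples (",
      if (x$method == "ir_percent") "log2-CPM scale" else "count scale",
      ")\n", sep = "")
  invisible(x)
}

.expr_pieces <- function(expr) {
  if (is(expr, "gene_expr")) {
    if (is.null(expr$lengths)) .stop("expression set carries no gene lengths")
    list(counts = expr$counts, lengths = expr$lengths)
  } else {
    .stop("expr must be a gene_expr (see new_gene_expr / expr_from_assignments)")
  }
}

.subtract_contam <- function(counts, contam) {
  round(pmax(counts - contam, 0))
}

#' Global gDNA contamination correction
#'
#' Per-gene contamination is the sample's global FPB estimate times the gene
#' length; it is subtracted from the raw counts, clamped at zero and rounded.
#'
#' @param expr A `gene_expr` with counts and lengths.
#' @param fit A `contamination_fit`, or a named per-sample FPB vector.
#' @return A `corrected_expr` (count scale).
#' @export
global_correction <- function(expr, fit) {
  ep <- .expr_pieces(expr)
  fpb <- if (is(fit, "contamination_fit")) fit$global_fpb else fit
  miss <- setdiff(colnames(ep$counts), names(fpb))
  if (length(miss))
    .stop("no contamination estimate for sample(s): ",
          paste(miss, collapse = ", "))
  if (anyNA(ep$lengths))
    .stop("missing gene length(s) for: ",
          paste(head(rownames(ep$counts)[apply(is.na(ep$lengths), 1L, any)], 5L),
                collapse = ", "))
  contam <- sweep(ep$lengths, 2L, fpb[colnames(ep$counts)], "*")
  .new_corrected("global", .subtract_contam(ep$counts, contam),
                 params = list(global_fpb = fpb[colnames(ep$counts)]))
}

#' GC-stratified gDNA contamination correction
#'
#' Per-gene contamination is the FPB estimate of the GC bin containing the
#' gene's GC content times the gene length. Genes with undefined GC fall back
#' to the global estimate. With all bins set to the global FPB this reduces
#' exactly to [global_correction()].
#'
#' @param expr A `gene_expr` with counts and lengths.
#' @param fit A `contamination_fit` with `method = "gc"` (or a 20 x sample
#'   bin-FPB matrix, in which case `global_fallback` supplies the per-sample
#'   global FPB for genes without GC).
#' @param gene_gc Gene GC content (`gc_profile` or named vector).
#' @param global_fallback Optional named per-sample FPB vector used only when
#'   `fit` is a bare matrix.
#' @return A `corrected_expr` (count scale).
#' @export
gc_correction <- function(expr, fit, gene_gc, global_fallback = NULL) {
  ep <- .expr_pieces(expr)
  if (!is(fit, "contamination_fit")) {
    fit <- structure(list(method = "gc", gc_bin_fpb = fit,
                          global_fpb = global_fallback %||%
                            setNames(colMeans(fit), colnames(fit)),
                          span = NA_real_,
                          n_regions_used = NA_integer_),
                     class = "contamination_fit")
  }
  if (is.null(fit$gc_bin_fpb)) .stop("fit carries no GC-bin estimates")
  contam <- predict(fit, gene_lengths = ep$lengths, gene_gc = gene_gc)
  contam <- contam[rownames(ep$counts), colnames(ep$counts), drop = FALSE]
  .new_corrected("gc", .subtract_contam(ep$counts, contam),
                 params = list(gc_bin_fpb = fit$gc_bin_fpb, span = fit$span))
}

## ----------------------------------------------------------- IR% model ----

## Precision-weighted log2-CPM pipeline: log2 CPM with a 0.5 pseudocount,
## gene-wise mean-variance trend by lowess of sqrt residual SD on mean
## log2 count, observation weights 1 / trend^4, then weighted least squares
## per gene on [intercept | group dummies | centred IR%].
.voom_weights <- function(y, design, libsize, lowess_span = 0.5) {
  qrX <- qr(design)
  eff <- qr.qty(qrX, t(y))
  resid_df <- nrow(design) - qrX$rank
  sigma <- sqrt(colSums(eff[-seq_len(qrX$rank), , drop = FALSE]^2) / resid_df)
  fitted <- t(qr.fitted(qrX, t(y)))
  sx <- rowMeans(y) + mean(log2(libsize + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  lo <- lowess(sx, sy, f = lowess_span)
  lof <- stats::approxfun(lo, rule = 2, ties = list("ordered", mean))
  fitted_logcount <- fitted + matrix(log2(libsize + 1), nrow(y), ncol(y),
                                     byrow = TRUE) - log2(1e6)
  w <- 1 / pmax(lof(fitted_logcount), 1e-6)^4
  dim(w) <- dim(y)
  w
}

#' IR%-covariate contamination correction (precision-weighted linear model)
#'
#' Transforms counts to `log2((count + 0.5) / (libsize + 1) * 1e6)`, estimates
#' observation precision weights from the gene-wise mean-variance trend
#' (lowess of the square-root residual standard deviation on mean log2 count),
#' then fits, per gene, a weighted least-squares model on
#' `[intercept | group dummies | centred IR%]`. The adjusted matrix removes
#' only the IR% term: `adjusted = y - beta_IR * (IR% - mean IR%)`, so the
#' intercept stays on the clean-sample baseline.
#'
#' @param counts Gene-by-sample count matrix (raw counts).
#' @param group Per-sample condition labels (factor or character). A single
#'   level yields an intercept-plus-IR% design.
#' @param ir_percent Per-sample intergenic read fraction, in percent
#'   (named by sample or in column order).
#' @param lowess_span Span of the mean-variance trend smoother.
#' @return A `corrected_expr` on the log2-CPM scale, with per-gene `beta_ir`
#'   in `$params` and a covariate table (sample, IR%, group) in `$covariates`.
#' @export
ir_percent_correction <- function(counts, group, ir_percent,
                                  lowess_span = 0.5) {
  if (is(counts, "gene_expr")) counts <- counts$counts
  .assert_matrix_like(counts)
  n <- ncol(counts)
  if (n < 2L) .stop("need at least 2 samples")
  if (!is.null(names(ir_percent))) {
    miss <- setdiff(colnames(counts), names(ir_percent))
    if (length(miss)) .stop("no IR% for sample(s): ", paste(miss, collapse = ", "))
    ir_percent <- ir_percent[colnames(counts)]
  }
  if (length(ir_percent) != n) .stop("ir_percent must have one value per sample")
  if (diff(range(ir_percent)) == 0)
    .stop("IR% is constant across samples: covariate uninformative")
  group <- factor(group)
  if (length(group) != n) .stop("group must have one label per sample")

  ir_c <- ir_percent - mean(ir_percent)
  design <- if (nlevels(group) >= 2L)
    model.matrix(~ group + ir_c) else model.matrix(~ ir_c)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1L):ncol(design)]]
    .stop("design matrix is rank deficient; collinear column(s): ",
          paste(dropped, collapse = ", "))
  }

  libsize <- colSums(counts)
  y <- log2(sweep(counts + 0.5, 2L, libsize + 1, "/") * 1e6)
  w <- .voom_weights(y, design, libsize, lowess_span)

  ir_col <- which(colnames(design) == "ir_c")
  beta_ir <- numeric(nrow(y))
  for (g in seq_len(nrow(y))) {
    fit_g <- lm.wfit(design, y[g, ], w[g, ])
    beta_ir[g] <- fit_g$coefficients[ir_col]
  }
  names(beta_ir) <- rownames(y)
  adjusted <- y - outer(beta_ir, ir_c)
  dimnames(adjusted) <- dimnames(y)
  covar <- data.frame(sample_id = colnames(counts), ir_percent = ir_percent,
                      group = as.character(group), row.names = NULL)
  .new_corrected("ir_percent", adjusted, covariates = covar,
                 params = list(beta_ir = beta_ir, lowess_span = lowess_span,
                               design = design, weights = w, log2cpm = y))
}

#' Stranded sense-minus-antisense correction
#'
#' For stranded libraries (stranded-read proportion above 0.9), fragments from
#' double-stranded gDNA fall on both strands in equal expectation while RNA
#' fragments keep the transcript orientation. Quantifying each sample twice —
#' once with the correct library strandedness, once with the opposite — and
#' subtracting the antisense matrix from the sense matrix removes the gDNA
#' component: `corrected = max(0, sense - antisense)`.
#'
#' @param sense Gene-by-sample counts quantified with the correct
#'   strandedness (`gene_expr` or matrix).
#' @param antisense Same samples quantified with the opposite strandedness.
#' @return A `corrected_expr` (count scale).
#' @export
stranded_correction <- function(sense, antisense) {
  s <- if (is(sense, "gene_expr")) sense$counts else sense
  a <- if (is(antisense, "gene_expr")) antisense$counts else antisense
  .assert_matrix_like(s, "sense"); .assert_matrix_like(a, "antisense")
  if (!identical(dimnames(s), dimnames(a)))
    .stop("sense and antisense matrices must share genes and samples")
  .new_corrected("stranded", pmax(s - a, 0))
}

## -------------------------------------------------------------- filters ----

#' Filter multi-exonic genes lacking splicing-junction support
#'
#' Drops genes with two or more exons whose junction support (counted
#' fragments with a spliced CIGAR) is below `min_junction_fragments` in every
#' sample; mono-exonic genes are always retained.
#'
#' @param corrected A `corrected_expr` (count scale) or count matrix.
#' @param n_exons Per-gene exon counts (named vector, e.g.
#'   `setNames(models$genes$n_exons, models$genes$gene_id)`).
#' @param junction_support Gene-by-sample junction-support matrix, or a list
#'   of `fragment_assignment` objects.
#' @param min_junction_fragments Minimum spliced fragments (default 1).
#' @return The input with unsupported multi-exonic genes removed.
#' @export
filter_unsupported_multiexonic <- function(corrected, n_exons,
                                           junction_support,
                                           min_junction_fragments = 1) {
  mat <- if (is(corrected, "corrected_expr")) corrected$matrix else corrected
  if (is.list(junction_support) && !is.matrix(junction_support) &&
      !is.data.frame(junction_support)) {
    junction_support <- vapply(junction_support, function(a) a$junction_support,
                               numeric(length(junction_support[[1L]]$junction_support)))
    if (is.null(dim(junction_support)))
      junction_support <- matrix(junction_support, ncol = 1L)
  }
  genes <- rownames(mat)
  miss <- setdiff(genes, names(n_exons))
  if (length(miss))
    .stop("no exon count for gene(s): ", paste(head(miss, 5L), collapse = ", "))
  miss2 <- setdiff(genes, rownames(junction_support))
  if (length(miss2))
    .stop("no junction support for gene(s): ",
          paste(head(miss2, 5L), collapse = ", "))
  js <- junction_support[genes, , drop = FALSE]
  multi <- n_exons[genes] >= 2L
  unsupported <- multi & apply(js < min_junction_fragments, 1L, all)
  keep <- genes[!unsupported]
  if (is(corrected, "corrected_expr")) {
    corrected$matrix <- corrected$matrix[keep, , drop = FALSE]
    corrected$params$dropped_unsupported <- setdiff(genes, keep)
    corrected
  } else mat[keep, , drop = FALSE]
}

#' Filter genes lowly expressed in uncontaminated samples
#'
#' Drops genes whose CPM is at or below `cpm_cutoff` in all uncontaminated
#' samples of every condition: genuine expression should be visible in at
#' least one clean sample of some condition.
#'
#' @param corrected A `corrected_expr` (count scale) or count matrix.
#' @param condition_labels Per-sample condition labels.
#' @param contaminated_flags Logical per sample, `TRUE` for contaminated.
#' @param cpm_cutoff CPM threshold (default 1).
#' @return The input with low-in-clean genes removed.
#' @export
filter_low_in_clean <- function(corrected, condition_labels,
                                contaminated_flags, cpm_cutoff = 1) {
  mat <- if (is(corrected, "corrected_expr")) corrected$matrix else corrected
  .assert_matrix_like(mat, "corrected counts")
  condition_labels <- as.character(condition_labels)
  if (length(condition_labels) != ncol(mat) ||
      length(contaminated_flags) != ncol(mat))
    .stop("condition_labels and contaminated_flags must match the samples")
  for (cond in unique(condition_labels)) {
    clean <- condition_labels == cond & !contaminated_flags
    if (!any(clean))
      .stop("condition '", cond, "' has no uncontaminated sample")
  }
  cc <- cpm(mat)
  clean_cols <- !contaminated_flags
  expressed_somewhere <- apply(cc[, clean_cols, drop = FALSE] > cpm_cutoff,
                               1L, any)
  keep <- rownames(mat)[expressed_somewhere]
  if (is(corrected, "corrected_expr")) {
    corrected$matrix <- corrected$matrix[keep, , drop = FALSE]
    corrected$params$dropped_low_in_clean <- setdiff(rownames(mat), keep)
    corrected
  } else mat[keep, , drop = FALSE]
}
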