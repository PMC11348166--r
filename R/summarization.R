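## Fragment-to-feature assignment, strandedness inference, quantifier import.
##
## A "fragment" is the sequenced template: a properly-oriented read pair counted
## once, or a single-end read. Assignment is strictly fragment-based because the
## downstream coverage unit (fragments per base, FPB) and the intergenic read
## fraction (IR%) are fragment-based quantities.

.CATEGORY_PRECEDENCE <- c("collapsed_exon", "intron", "intergenic")

## Max-overlap assignment of fragments (GRangesList of blocks) to regions of a
## single category. Ties break to the leftmost region start, then region order.
## Returns integer region index per fragment (NA if no overlap).
.max_overlap_region <- function(blocks, regions_gr) {
  flat <- unlist(blocks, use.names = FALSE)
  frag_of <- rep(seq_along(blocks), S4Vectors::elementNROWS(blocks))
  hits <- GenomicRanges::findOverlaps(flat, regions_gr, ignore.strand = TRUE)
  if (length(hits) == 0L) return(rep(NA_integer_, length(blocks)))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(flat)[qh],
                                          IRanges::ranges(regions_gr)[sh]))
  key <- paste(frag_of[qh], sh)
  agg <- rowsum(w, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  fr <- as.integer(vapply(parts, `[`, "", 1L))
  rg <- as.integer(vapply(parts, `[`, "", 2L))
  ww <- as.numeric(agg[, 1L])
  ord <- order(fr, -ww, GenomicRanges::start(regions_gr)[rg], rg)
  fr <- fr[ord]; rg <- rg[ord]
  keep <- !duplicated(fr)
  out <- rep(NA_integer_, length(blocks))
  out[fr[keep]] <- rg[keep]
  out
}

## Core assignment shared by the BAM reader and the fragment-table path.
## blocks: GRangesList (one element per fragment, genomic alignment blocks);
## frag_strand: "+", "-" or "*" per fragment; njunc: spliced-gap count.
.assign_core <- function(blocks, frag_strand, njunc, catalog, models,
                         strand_mode = c("unstranded", "forward", "reverse"),
                         sample_id = "sample") {
  strand_mode <- match.arg(strand_mode)
  n <- length(blocks)
  cat_gr <- lapply(catalog, .df_to_granges)

  in_cat <- vapply(.CATEGORY_PRECEDENCE, function(cn)
    IRanges::overlapsAny(blocks, cat_gr[[cn]], ignore.strand = TRUE),
    logical(n))
  if (n == 1L) in_cat <- matrix(in_cat, nrow = 1L,
                                dimnames = list(NULL, .CATEGORY_PRECEDENCE))
  assigned_cat <- rep(NA_character_, n)
  free <- rep(TRUE, n)
  for (cn in .CATEGORY_PRECEDENCE) {
    take <- free & in_cat[, cn]
    assigned_cat[take] <- cn
    free <- free & !take
  }

  per_region <- list()
  for (cn in .CATEGORY_PRECEDENCE) {
    idx <- which(assigned_cat == cn)
    counts <- setNames(numeric(nrow(catalog[[cn]])), catalog[[cn]]$region_id)
    if (length(idx)) {
      ri <- .max_overlap_region(blocks[idx], cat_gr[[cn]])
      tab <- table(ri)
      counts[as.integer(names(tab))] <- as.numeric(tab)
    }
    per_region[[cn]] <- counts
  }
  ## rRNA and organellar are tallied independently (non-exclusive)
  for (cn in c("rRNA_exon", "organellar")) {
    counts <- setNames(numeric(nrow(catalog[[cn]])), catalog[[cn]]$region_id)
    if (nrow(catalog[[cn]])) {
      idx <- which(IRanges::overlapsAny(blocks, cat_gr[[cn]], ignore.strand = TRUE))
      if (length(idx)) {
        ri <- .max_overlap_region(blocks[idx], cat_gr[[cn]])
        tab <- table(ri)
        counts[as.integer(names(tab))] <- as.numeric(tab)
      }
    }
    per_region[[cn]] <- counts
  }

  ## gene-level union-exon counting honoring the strand mode; fragments
  ## compatible with >1 gene are ambiguous and dropped (featureCounts default)
  ue <- .union_exons(models)
  gene_ids <- names(ue)
  gene_strand <- setNames(models$genes$strand, models$genes$gene_id)[gene_ids]
  hits <- GenomicRanges::findOverlaps(blocks, ue, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (strand_mode != "unstranded") {
    fs <- frag_strand[qh]; gs <- gene_strand[sh]
    ok <- if (strand_mode == "forward") fs == gs
          else (fs == "+" & gs == "-") | (fs == "-" & gs == "+")
    ok[fs == "*"] <- FALSE
    qh <- qh[ok]; sh <- sh[ok]
  }
  ngene <- tabulate(qh, nbins = length(blocks))
  uniq <- ngene[qh] == 1L
  gcounts <- setNames(numeric(length(gene_ids)), gene_ids)
  tab <- table(sh[uniq])
  gcounts[as.integer(names(tab))] <- as.numeric(tab)

  jsupp <- setNames(numeric(length(gene_ids)), gene_ids)
  jsel <- uniq & njunc[qh] > 0
  if (any(jsel)) {
    jt <- table(sh[jsel])
    jsupp[as.integer(names(jt))] <- as.numeric(jt)
  }

  assigned_per_category <- vapply(per_region, sum, 0)
  structure(list(
    sample_id = sample_id,
    per_region_counts = per_region,
    per_gene_counts = gcounts,
    junction_support = jsupp,
    totals = list(
      total_fragments = n,
      assigned_per_category = assigned_per_category,
      unassigned = n - sum(assigned_per_category[.CATEGORY_PRECEDENCE])
    ),
    strand_mode = strand_mode
  ), class = "fragment_assignment")
}

#' @export
print.fragment_assignment <- function(x, ...) {
  cat("Fragment assignment for sample '", x$sample_id, "' (",
      x$totals$total_fragments, " fragments, strand mode: ", x$strand_mode,
      ")\n", sep = "")
  print(x$totals$assigned_per_category)
  cat("unassigned:", x$totals$unassigned, "\n")
  invisible(x)
}

#' Assign aligned fragments in a BAM file to feature catalogs and genes
#'
#' Native fragment counter. Each fragment is assigned to at most one of the
#' exclusive categories by precedence exon > intron > intergenic (a fragment
#' overlapping any region of a category, with either mate, belongs to that
#' category); within a category it is attributed to the region of maximal
#' overlap. rRNA and organellar features are tallied independently. Gene counts
#' use union-exon overlap honoring the strand mode; fragments compatible with
#' more than one gene are dropped as ambiguous. Secondary, supplementary,
#' unmapped and QC-fail alignments are ignored. Junction support per gene is
#' the number of counted fragments bearing a spliced (N) CIGAR operation.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param catalog Feature catalog from [build_feature_catalog()].
#' @param models A `gene_models` object.
#' @param strand_mode `"unstranded"`, `"forward"` (fragment strand equals gene
#'   strand) or `"reverse"` (mate 1 antisense to the transcript).
#' @param sample_id Sample label; defaults to the BAM basename.
#' @param count_duplicates Count duplicate-marked reads (default `TRUE`).
#' @return A `fragment_assignment` object.
#' @export
assign_fragments <- function(bam, catalog, models,
                             strand_mode = c("unstranded", "forward", "reverse"),
                             sample_id = sub("\\.bam$", "", basename(bam)),
                             count_duplicates = TRUE) {
  strand_mode <- match.arg(strand_mode)
  if (!file.exists(bam)) .stop("BAM not found: ", bam)
  bai <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(bai)))
    .stop("BAM is not indexed (no .bai next to ", bam, ")")

  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  extra <- setdiff(names(hdr), names(models$chrom_lengths))
  if (length(extra))
    .stop("BAM chromosome(s) absent from the annotation: ",
          paste(extra, collapse = ", "))

  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isUnmappedQuery = FALSE, isNotPassingQualityControls = FALSE,
    isDuplicate = if (count_duplicates) NA else FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag)

  paired <- suppressMessages(Rsamtools::testPairedEndBam(bam))
  if (paired) {
    gap <- GenomicAlignments::readGAlignmentPairs(bam, param = param,
                                                  strandMode = 1L)
    blocks <- GenomicAlignments::grglist(gap)
    frag_strand <- as.character(GenomicAlignments::strand(gap))
    njunc <- GenomicAlignments::njunc(gap)
  } else {
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    blocks <- GenomicAlignments::grglist(ga)
    frag_strand <- as.character(GenomicAlignments::strand(ga))
    njunc <- GenomicAlignments::njunc(ga)
  }
  .assign_core(blocks, frag_strand, njunc, catalog, models, strand_mode,
               sample_id = sample_id)
}

## ---------------------------------------------------- strandedness ----

.detect_core <- function(blocks, frag_strand, models, max_fragments = 200000L,
                         min_fragments = 100L, sample_id = "sample") {
  spans <- .gene_spans(models)
  self_only <- GenomicRanges::countOverlaps(spans, spans,
                                            ignore.strand = TRUE) == 1L
  solo <- names(spans)[self_only]
  ue <- .union_exons(models)[solo]
  gene_strand <- setNames(models$genes$strand, models$genes$gene_id)[solo]

  hits <- GenomicRanges::findOverlaps(blocks, ue, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  uniq <- tabulate(qh, nbins = length(blocks))[qh] == 1L
  qh <- qh[uniq]; sh <- sh[uniq]
  fs <- frag_strand[qh]; gs <- gene_strand[sh]
  keep <- fs %in% c("+", "-")
  fs <- fs[keep]; gs <- gs[keep]
  if (length(fs) > max_fragments) {
    fs <- fs[seq_len(max_fragments)]; gs <- gs[seq_len(max_fragments)]
  }
  n <- length(fs)
  if (n < min_fragments)
    return(structure(list(sample_id = sample_id, proportion = NA_real_,
                          n_evaluable = n, status = "inconclusive",
                          threshold = 0.9),
                     class = "strandedness_call"))
  ## reverse convention: mate 1 antisense to the transcript
  p <- mean(fs != gs)
  status <- if (p > 0.9) "stranded (reverse)"
            else if (1 - p > 0.9) "stranded (forward)"
            else "unstranded"
  structure(list(sample_id = sample_id, proportion = p, n_evaluable = n,
                 status = status, threshold = 0.9),
            class = "strandedness_call")
}

#' Infer library strandedness from alignments
#'
#' Evaluates fragments overlapping unambiguous single-gene loci and returns the
#' proportion matching the annotated gene strand under the reverse convention
#' (mate 1 antisense to the transcript). The library is called stranded when
#' `max(p, 1 - p) > 0.9`, with the direction inferred from which side exceeds
#' the threshold; with fewer than `min_fragments` evaluable fragments the call
#' is `"inconclusive"` rather than a silent number.
#'
#' @param x A BAM path or a `sim_fragments` table from [simulate_sample()].
#' @param models A `gene_models` object.
#' @param max_fragments Maximum number of evaluable fragments used.
#' @param min_fragments Minimum evaluable fragments for a conclusive call.
#' @param ... Passed to methods.
#' @return A `strandedness_call` with `proportion`, `n_evaluable`, `status`.
#' @export
detect_strandedness <- function(x, models, max_fragments = 200000L,
                                min_fragments = 100L, ...) {
  UseMethod("detect_strandedness")
}

#' @export
detect_strandedness.character <- function(x, models, max_fragments = 200000L,
                                          min_fragments = 100L, ...) {
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isUnmappedQuery = FALSE, isNotPassingQualityControls = FALSE)
  paired <- suppressMessages(Rsamtools::testPairedEndBam(x))
  param <- Rsamtools::ScanBamParam(flag = flag)
  if (paired) {
    gap <- GenomicAlignments::readGAlignmentPairs(x, param = param, strandMode = 1L)
    blocks <- GenomicAlignments::grglist(gap)
    fs <- as.character(GenomicAlignments::strand(gap))
  } else {
    ga <- GenomicAlignments::readGAlignments(x, param = param)
    blocks <- GenomicAlignments::grglist(ga)
    fs <- as.character(GenomicAlignments::strand(ga))
  }
  .detect_core(blocks, fs, models, max_fragments, min_fragments,
               sample_id = sub("\\.bam$", "", basename(x)))
}

#' @export
detect_strandedness.sim_fragments <- function(x, models,
                                              max_fragments = 200000L,
                                              min_fragments = 100L, ...) {
  rep_ <- .fragments_to_blocks(x, models$chrom_lengths)
  .detect_core(rep_$blocks, rep_$strand, models, max_fragments, min_fragments,
               sample_id = attr(x, "sample_id") %||% "sample")
}

#' @export
print.strandedness_call <- function(x, ...) {
  cat("Strandedness [", x$sample_id, "]: ", x$status, "\n", sep = "")
  cat(sprintf("  proportion (reverse convention): %s over %d evaluable fragments\n",
              ifelse(is.na(x$proportion), "NA", sprintf("%.3f", x$proportion)),
              x$n_evaluable))
  invisible(x)
}

## ------------------------------------------------ expression container ----

#' Construct a gene expression container
#'
#' Bundles a gene-by-sample count matrix with matching per-sample gene lengths
#' (bp) and, optionally, a TPM abundance matrix. All matrices share dimensions
#' and dimnames; a length vector is recycled across samples.
#'
#' @param counts Gene-by-sample non-negative count matrix.
#' @param lengths Gene-by-sample length matrix, or a per-gene vector.
#' @param tpm Optional gene-by-sample TPM matrix.
#' @return An object of class `gene_expr`.
#' @export
new_gene_expr <- function(counts, lengths = NULL, tpm = NULL) {
  .assert_matrix_like(counts, "counts")
  if (any(counts < 0)) .stop("counts must be non-negative")
  if (!is.null(lengths)) {
    if (!is.matrix(lengths)) {
      if (is.null(names(lengths))) names(lengths) <- rownames(counts)
      lengths <- matrix(lengths[rownames(counts)], nrow = nrow(counts),
                        ncol = ncol(counts), dimnames = dimnames(counts))
    }
    if (!identical(dimnames(lengths), dimnames(counts)))
      .stop("lengths must share dimnames with counts")
    if (any(counts > 0 & !(lengths > 0), na.rm = TRUE))
      .stop("genes with counts > 0 must have positive lengths")
  }
  if (!is.null(tpm) && !identical(dimnames(tpm), dimnames(counts)))
    .stop("tpm must share dimnames with counts")
  structure(list(counts = counts, lengths = lengths, tpm = tpm),
            class = "gene_expr")
}

#' @export
print.gene_expr <- function(x, ...) {
  cat("Gene expression set:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; lengths:", ifelse(is.null(x$lengths), "absent", "present"),
      "; TPM:", ifelse(is.null(x$tpm), "absent", "present"), "\n")
  invisible(x)
}

#' @export
dim.gene_expr <- function(x) dim(x$counts)

#' Assemble a gene expression set from fragment assignments
#'
#' @param assignments A list of `fragment_assignment` objects (one per sample).
#' @param models A `gene_models` object providing union-exon gene lengths.
#' @return A `gene_expr` with counts and union-exon lengths.
#' @export
expr_from_assignments <- function(assignments, models) {
  if (is(assignments, "fragment_assignment")) assignments <- list(assignments)
  counts <- vapply(assignments, function(a) a$per_gene_counts,
                   numeric(length(assignments[[1L]]$per_gene_counts)))
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(assignments))
  colnames(counts) <- vapply(assignments, function(a) a$sample_id, "")
  rownames(counts) <- names(assignments[[1L]]$per_gene_counts)
  len <- setNames(models$genes$union_exon_length, models$genes$gene_id)
  new_gene_expr(counts, lengths = len[rownames(counts)])
}

#' Import a transcript-quantifier gene-level triplet
#'
#' Reads the count / effective-length / TPM tables written by a
#' transcript quantifier import (genes as rows, header = sample IDs) and aligns
#' them by gene and sample ID. Genes missing a length fall back to the
#' union-exon length from the annotation.
#'
#' @param count_tsv Path to the gene-by-sample count TSV.
#' @param length_tsv Optional path to the effective-length TSV.
#' @param tpm_tsv Optional path to the TPM TSV.
#' @param models Optional `gene_models` for the union-exon length fallback.
#' @return A `gene_expr`.
#' @export
import_quant <- function(count_tsv, length_tsv = NULL, tpm_tsv = NULL,
                         models = NULL) {
  read_m <- function(p) as.matrix(read.delim(p, row.names = 1L, check.names = FALSE))
  counts <- read_m(count_tsv)
  align <- function(m, what) {
    extra <- setdiff(colnames(m), colnames(counts))
    miss <- setdiff(colnames(counts), colnames(m))
    if (length(extra) || length(miss))
      .stop("sample mismatch between count and ", what, " tables: ",
            paste(c(extra, miss), collapse = ", "))
    m[, colnames(counts), drop = FALSE]
  }
  lengths <- NULL
  if (!is.null(length_tsv)) {
    lm <- align(read_m(length_tsv), "length")
    common <- intersect(rownames(counts), rownames(lm))
    lengths <- matrix(NA_real_, nrow(counts), ncol(counts),
                      dimnames = dimnames(counts))
    lengths[common, ] <- lm[common, ]
  } else {
    lengths <- matrix(NA_real_, nrow(counts), ncol(counts),
                      dimnames = dimnames(counts))
  }
  if (anyNA(lengths)) {
    if (is.null(models))
      .stop("genes without a length and no gene models for the union-exon fallback: ",
            paste(head(rownames(counts)[apply(is.na(lengths), 1L, any)], 5L),
                  collapse = ", "))
    fallback <- setNames(models$genes$union_exon_length, models$genes$gene_id)
    for (g in rownames(counts)[apply(is.na(lengths), 1L, any)]) {
      if (is.na(fallback[g]))
        .stop("no length available for gene ", g)
      lengths[g, is.na(lengths[g, ])] <- fallback[g]
    }
  }
  tpm <- if (!is.null(tpm_tsv)) {
    tm <- align(read_m(tpm_tsv), "tpm")
    tm[rownames(counts), , drop = FALSE]
  } else NULL
  new_gene_expr(counts, lengths = lengths, tpm = tpm)
}
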