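# Shared fixtures: tiny hand-written annotations, a cached small synthetic
# reference, and a brute-force fragment-assignment oracle written in plain
# loops/arithmetic, independent of the package's interval machinery.

.fixture_env <- new.env(parent = emptyenv())

# memoised small synthetic reference (fast enough for most tests)
small_ref <- function(seed = 7) {
  key <- paste0("ref", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_reference(seed, n_chroms = 1L,
                                          chrom_length = 8e4, n_genes = 10L,
                                          organellar_length = 8000L)
  .fixture_env[[key]]
}

small_catalog <- function(seed = 7) {
  key <- paste0("cat", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_feature_catalog(small_ref(seed)$models)
  .fixture_env[[key]]
}

# write a minimal Ensembl-dialect GTF from an exon table and load it
toy_models <- function(exons, chrom_lengths, biotypes = NULL) {
  # exons: data.frame(gene_id, chrom, start, end, strand)
  gtf <- vapply(seq_len(nrow(exons)), function(i) {
    g <- exons$gene_id[i]
    bt <- if (!is.null(biotypes)) biotypes[[g]] else "protein_coding"
    attr_part <- if (is.na(bt)) sprintf('gene_id "%s"; transcript_id "%s.t1";', g, g)
      else sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";', g, g, bt)
    paste(exons$chrom[i], "test", "exon", exons$start[i], exons$end[i], ".",
          exons$strand[i], ".", attr_part, sep = "\t")
  }, "")
  path <- tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  load_gene_models(path, chrom_lengths)
}

# write a tiny FASTA (one sequence per element) and return its path
toy_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

# ---------------------------------------------------------------- oracle ----

# plain-arithmetic overlap of one block set with one region
.ov_bp <- function(b, chrom, start, end) {
  sel <- b$chrom == chrom
  if (!any(sel)) return(0)
  sum(pmax(0, pmin(b$end[sel], end) - pmax(b$start[sel], start) + 1))
}

# Brute-force re-implementation of the documented assignment rule:
# category precedence exon > intron > intergenic, within-category attribution
# to the region of maximal overlap (ties: leftmost start, then region order);
# rRNA/organellar tallied non-exclusively; gene counts by union-exon overlap
# honoring the strand mode, ambiguous fragments dropped.
oracle_assign <- function(frags, catalog, models, strand_mode = "unstranded") {
  blocks <- attr(frags, "blocks")
  cats <- c("collapsed_exon", "intron", "intergenic")
  side <- c("rRNA_exon", "organellar")
  per_region <- lapply(catalog[c(cats, side)], function(rs)
    stats::setNames(numeric(nrow(rs)), rs$region_id))
  ex <- data.frame(chrom = as.character(GenomicRanges::seqnames(models$exons)),
                   start = GenomicRanges::start(models$exons),
                   end = GenomicRanges::end(models$exons),
                   gene_id = models$exons$gene_id, stringsAsFactors = FALSE)
  gene_ids <- sort(unique(ex$gene_id))
  gene_strand <- stats::setNames(models$genes$strand, models$genes$gene_id)
  gcounts <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  jsupp <- gcounts
  assigned_cat <- integer(0)

  for (f in seq_len(nrow(frags))) {
    b <- blocks[blocks$frag_id == frags$frag_id[f], , drop = FALSE]
    for (cn in cats) {
      rs <- catalog[[cn]]
      w <- vapply(seq_len(nrow(rs)), function(r)
        .ov_bp(b, rs$chrom[r], rs$start[r], rs$end[r]), 0)
      if (length(w) && any(w > 0)) {
        best <- which(w == max(w))
        best <- best[order(rs$start[best], best)][1L]
        per_region[[cn]][best] <- per_region[[cn]][best] + 1
        break
      }
    }
    for (cn in side) {
      rs <- catalog[[cn]]
      if (!nrow(rs)) next
      w <- vapply(seq_len(nrow(rs)), function(r)
        .ov_bp(b, rs$chrom[r], rs$start[r], rs$end[r]), 0)
      if (any(w > 0)) {
        best <- which(w == max(w))
        best <- best[order(rs$start[best], best)][1L]
        per_region[[cn]][best] <- per_region[[cn]][best] + 1
      }
    }
    hits <- character(0)
    for (g in gene_ids) {
      eg <- ex[ex$gene_id == g, , drop = FALSE]
      w <- sum(vapply(seq_len(nrow(eg)), function(r)
        .ov_bp(b, eg$chrom[r], eg$start[r], eg$end[r]), 0))
      if (w > 0) {
        ok <- switch(strand_mode,
          unstranded = TRUE,
          forward = frags$strand[f] == gene_strand[[g]],
          reverse = frags$strand[f] %in% c("+", "-") &&
            frags$strand[f] != gene_strand[[g]])
        if (isTRUE(ok)) hits <- c(hits, g)
      }
    }
    if (length(hits) == 1L) {
      gcounts[hits] <- gcounts[hits] + 1
      if (frags$n_blocks[f] > 1L) jsupp[hits] <- jsupp[hits] + 1
    }
  }
  list(per_region_counts = per_region, per_gene_counts = gcounts,
       junction_support = jsupp)
}

# brute-force per-base GC of a string
oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  acgt <- ch[ch %in% c("A", "C", "G", "T")]
  if (!length(acgt)) return(NA_real_)
  sum(acgt %in% c("G", "C")) / length(acgt)
}
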