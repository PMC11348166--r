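## Gene models, feature catalogs, GC content and SAF I/O.
##
## Coordinates: GTF and SAF are 1-based inclusive on disk; internally intervals
## live in GRanges (1-based inclusive as well), and all arithmetic goes through
## IRanges so off-by-one risk is confined to the parsers/writers.

#' Read chromosome lengths from a FASTA index
#'
#' Reads (creating if necessary) the `.fai` index of a genome FASTA and returns
#' the chromosome lengths. Used to bound annotation intervals and to define the
#' intergenic complement.
#'
#' @param fasta_path Path to a genome FASTA file.
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
fasta_chrom_lengths <- function(fasta_path) {
  if (!file.exists(fasta_path)) .stop("FASTA not found: ", fasta_path)
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  sl <- Rsamtools::seqinfo(fa)
  setNames(as.numeric(GenomeInfoDb::seqlengths(sl)), GenomeInfoDb::seqnames(sl))
}

#' Load gene models from an Ensembl-dialect GTF
#'
#' Parses the exon features of a GTF file into a `gene_models` object: one gene
#' per `gene_id` with all of its exons, the gene biotype
#' (`gene_biotype`/`gene_type` attribute, `"unknown"` if absent), and the
#' chromosome lengths of the accompanying genome.
#'
#' @param gtf_path Path to a GTF file (Ensembl attribute dialect).
#' @param chrom_lengths Either a named vector of chromosome lengths or a path
#'   to the genome FASTA (lengths are then read from its index).
#' @return An object of class `gene_models` with components `genes` (data frame
#'   with `gene_id`, `chrom`, `strand`, `biotype`, `n_exons`,
#'   `union_exon_length`), `exons` (a `GRanges` with a `gene_id` column) and
#'   `chrom_lengths`.
#' @export
load_gene_models <- function(gtf_path, chrom_lengths) {
  if (!file.exists(gtf_path)) .stop("GTF not found: ", gtf_path)
  if (is.character(chrom_lengths) && length(chrom_lengths) == 1L)
    chrom_lengths <- fasta_chrom_lengths(chrom_lengths)
  if (is.null(names(chrom_lengths))) .stop("chrom_lengths must be named")

  gtf <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  if (length(ex) == 0L) .stop("GTF contains no exon features: ", gtf_path)
  if (is.null(ex$gene_id) || anyNA(ex$gene_id)) {
    bad <- if (is.null(ex$gene_id)) seq_along(ex) else which(is.na(ex$gene_id))
    .stop("exon feature(s) without a gene_id attribute (exon record ",
          paste(head(bad, 5L), collapse = ", "),
          if (length(bad) > 5L) " ..." else "", ")")
  }
  chroms <- as.character(GenomeInfoDb::seqnames(ex))
  missing_chrom <- setdiff(unique(chroms), names(chrom_lengths))
  if (length(missing_chrom) > 0L)
    .stop("GTF chromosome(s) absent from the genome: ",
          paste(missing_chrom, collapse = ", "))
  too_far <- GenomicRanges::end(ex) > chrom_lengths[chroms] |
    GenomicRanges::start(ex) < 1L
  if (any(too_far))
    .stop("exon interval(s) outside chromosome bounds for gene(s): ",
          paste(unique(ex$gene_id[too_far]), collapse = ", "))

  biotype <- ex$gene_biotype %||% ex$gene_type %||% rep(NA_character_, length(ex))
  biotype[is.na(biotype)] <- "unknown"

  exons <- GenomicRanges::GRanges(
    seqnames = chroms,
    ranges = IRanges::IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex)),
    strand = GenomicRanges::strand(ex),
    gene_id = as.character(ex$gene_id)
  )
  GenomeInfoDb::seqlevels(exons) <- names(chrom_lengths)
  GenomeInfoDb::seqlengths(exons) <- chrom_lengths

  ord <- order(exons$gene_id, as.integer(GenomicRanges::seqnames(exons)),
               GenomicRanges::start(exons))
  exons <- exons[ord]
  biotype <- biotype[ord]

  first <- !duplicated(exons$gene_id)
  gene_chrom <- tapply(as.character(GenomicRanges::seqnames(exons)),
                       exons$gene_id, function(x) unique(x)[1L])
  per_gene <- split(exons, exons$gene_id)
  union_len <- vapply(per_gene, function(g)
    sum(IRanges::width(GenomicRanges::reduce(g, ignore.strand = TRUE))), 0)
  genes <- data.frame(
    gene_id = exons$gene_id[first],
    chrom = as.character(GenomicRanges::seqnames(exons))[first],
    strand = as.character(GenomicRanges::strand(exons))[first],
    biotype = biotype[first],
    n_exons = as.integer(table(exons$gene_id)[exons$gene_id[first]]),
    union_exon_length = as.numeric(union_len[exons$gene_id[first]]),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  structure(
    list(genes = genes, exons = exons, chrom_lengths = chrom_lengths),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", nrow(x$genes), "genes,", length(x$exons), "exons on",
      length(x$chrom_lengths), "chromosome(s)\n")
  bt <- sort(table(x$genes$biotype), decreasing = TRUE)
  cat("Biotypes:", paste(names(bt), bt, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

## union-exon structures per gene, as a GRangesList (strand kept)
.union_exons <- function(models) {
  GenomicRanges::reduce(S4Vectors::split(models$exons, models$exons$gene_id))
}

## per-gene genomic span (strand-agnostic)
.gene_spans <- function(models) {
  rng <- unlist(range(S4Vectors::split(models$exons, models$exons$gene_id),
                      ignore.strand = TRUE))
  rng
}

.new_region_set <- function(gr, category, prefix = category) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  n <- length(gr)
  df <- data.frame(
    region_id = if (n > 0 && !is.null(names(gr)) && !anyDuplicated(names(gr)))
      names(gr) else sprintf("%s_%05d", prefix, seq_len(max(n, 0L))),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = sub("^\\*$", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )[seq_len(n), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, category = category, class = c("region_set", "data.frame"))
}

#' Region lengths of a region set
#'
#' @param rs A `region_set`.
#' @return Named numeric vector of `end - start + 1` per region.
#' @export
region_lengths <- function(rs) {
  setNames(rs$end - rs$start + 1, rs$region_id)
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set [", attr(x, "category"), "]: ", nrow(x), " regions, ",
      sum(region_lengths(x)), " bp\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5L))
  invisible(x)
}

#' Derive the five feature catalogs from gene models
#'
#' Builds the coordinate-collapsed feature sets used for fragment assignment
#' and contamination diagnostics:
#' \describe{
#'   \item{collapsed_exon}{genome-wide union of all exons;}
#'   \item{intron}{per-gene span minus that gene's exon union, collapsed
#'     across genes, then with the global exon union subtracted;}
#'   \item{intergenic}{chromosome complement of all gene spans (each extended
#'     by `intergenic_flank` bp), excluding organellar chromosomes;}
#'   \item{rRNA_exon}{union of exons of genes whose biotype is in
#'     `rRNA_biotypes`;}
#'   \item{organellar}{one region spanning each listed organellar chromosome.}
#' }
#' With `intergenic_flank = 0`, collapsed_exon, intron and intergenic partition
#' every non-organellar chromosome exactly.
#'
#' @param models A `gene_models` object.
#' @param organellar_chroms Chromosome names treated as organellar
#'   (mitochondrial/chloroplast). Default `"MT"` (Ensembl naming).
#' @param rRNA_biotypes Gene biotypes counted as rRNA.
#' @param intergenic_flank Flank in bp added to each gene span before taking
#'   the intergenic complement (guards against incompletely annotated UTRs).
#' @return Named list of `region_set` objects, one per category.
#' @export
build_feature_catalog <- function(models,
                                  organellar_chroms = "MT",
                                  rRNA_biotypes = c("rRNA", "rRNA_pseudogene", "Mt_rRNA"),
                                  intergenic_flank = 0) {
  stopifnot(is(models, "gene_models"))
  if (nrow(models$genes) == 0L) .stop("gene models are empty")
  cl <- models$chrom_lengths
  missing_org <- setdiff(organellar_chroms, names(cl))
  if (length(missing_org))
    .stop("organellar chromosome(s) not in genome: ",
          paste(missing_org, collapse = ", "))

  exon_union <- GenomicRanges::reduce(models$exons, ignore.strand = TRUE)

  spans <- .gene_spans(models)
  per_gene_exons <- GenomicRanges::reduce(
    S4Vectors::split(models$exons, models$exons$gene_id), ignore.strand = TRUE)
  spans <- spans[names(per_gene_exons)]
  intron_per_gene <- GenomicRanges::setdiff(
    methods::as(spans, "GRangesList"), per_gene_exons, ignore.strand = TRUE)
  introns <- GenomicRanges::reduce(unlist(intron_per_gene), ignore.strand = TRUE)
  introns <- GenomicRanges::setdiff(introns, exon_union, ignore.strand = TRUE)

  spans_flank <- spans
  if (intergenic_flank > 0)
    spans_flank <- GenomicRanges::trim(spans_flank + intergenic_flank)
  genic <- GenomicRanges::reduce(unlist(methods::as(spans_flank, "GRangesList")),
                                 ignore.strand = TRUE)
  whole <- GenomicRanges::GRanges(
    seqnames = names(cl), ranges = IRanges::IRanges(1, cl))
  GenomeInfoDb::seqlevels(whole) <- names(cl)
  GenomeInfoDb::seqlengths(whole) <- cl
  intergenic <- GenomicRanges::setdiff(whole, genic, ignore.strand = TRUE)
  intergenic <- intergenic[
    !as.character(GenomicRanges::seqnames(intergenic)) %in% organellar_chroms]

  rrna_genes <- models$genes$gene_id[models$genes$biotype %in% rRNA_biotypes]
  rrna <- GenomicRanges::reduce(
    models$exons[models$exons$gene_id %in% rrna_genes], ignore.strand = TRUE)

  org <- GenomicRanges::GRanges(
    seqnames = organellar_chroms,
    ranges = IRanges::IRanges(1, cl[organellar_chroms]))
  if (length(organellar_chroms)) {
    GenomeInfoDb::seqlevels(org) <- names(cl)
    GenomeInfoDb::seqlengths(org) <- cl
    names(org) <- organellar_chroms
  }

  list(
    collapsed_exon = .new_region_set(exon_union, "collapsed_exon", "exon"),
    intron = .new_region_set(introns, "intron"),
    intergenic = .new_region_set(intergenic, "intergenic"),
    rRNA_exon = .new_region_set(rrna, "rRNA_exon", "rRNA"),
    organellar = .new_region_set(org, "organellar")
  )
}

#' Tile a region set into fixed-width windows
#'
#' Splits each region into consecutive windows of at most `width` bp. Used to
#' stabilise fragments-per-base estimates over long intergenic regions.
#'
#' @param rs A `region_set`.
#' @param width Maximum window width in bp.
#' @return A `region_set` of the same category with windowed regions.
#' @export
tile_regions <- function(rs, width = 1000) {
  stopifnot(is(rs, "region_set"), width >= 1)
  gr <- .df_to_granges(rs)
  tiles <- unlist(GenomicRanges::slidingWindows(gr, width = width, step = width))
  .new_region_set(tiles, attr(rs, "category"),
                  prefix = paste0(attr(rs, "category"), "_w"))
}

## ------------------------------------------------------------------ GC ----

.gc_of_seqs <- function(seqs) {
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  gc <- (freq[, "G"] + freq[, "C"]) / denom
  gc[denom == 0] <- NA_real_
  gc
}

#' GC content of regions
#'
#' Computes per-region GC fraction `(#G + #C) / (#A + #C + #G + #T)` from the
#' genome sequence. Bases outside ACGT (e.g. N) are excluded from both the
#' numerator and the denominator; regions with no ACGT base are flagged `NA`.
#'
#' @param rs A `region_set`.
#' @param fasta_path Genome FASTA (indexed on first use).
#' @return A data frame of class `gc_profile` with `id` and `gc` columns.
#' @export
calculate_region_gc <- function(rs, fasta_path) {
  stopifnot(is(rs, "region_set"))
  cl <- fasta_chrom_lengths(fasta_path)
  bad <- rs$end > cl[rs$chrom] | rs$start < 1
  if (any(bad))
    .stop("region(s) beyond sequence end: ",
          paste(head(rs$region_id[bad], 5L), collapse = ", "))
  fa <- Rsamtools::FaFile(fasta_path)
  seqs <- Rsamtools::scanFa(fa, .df_to_granges(rs))
  structure(
    data.frame(id = rs$region_id, gc = as.numeric(.gc_of_seqs(seqs)),
               stringsAsFactors = FALSE),
    class = c("gc_profile", "data.frame")
  )
}

#' GC content of genes over their union-exon sequence
#'
#' Concatenates each gene's collapsed exon sequences and computes the GC
#' fraction with the same ambiguous-base policy as [calculate_region_gc()].
#'
#' @param models A `gene_models` object.
#' @param fasta_path Genome FASTA.
#' @return A `gc_profile` data frame keyed by `gene_id`.
#' @export
calculate_gene_gc <- function(models, fasta_path) {
  stopifnot(is(models, "gene_models"))
  fa <- Rsamtools::FaFile(fasta_path)
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  ue <- .union_exons(models)
  flat <- unlist(ue)
  seqs <- Rsamtools::scanFa(fa, GenomicRanges::granges(flat))
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  gene <- rep(names(ue), S4Vectors::elementNROWS(ue))
  gcs <- rowsum(freq[, "G"] + freq[, "C"], gene)
  tot <- rowsum(rowSums(freq), gene)
  gc <- as.numeric(gcs / tot)
  gc[tot == 0] <- NA_real_
  structure(
    data.frame(id = rownames(gcs), gc = gc, stringsAsFactors = FALSE),
    class = c("gc_profile", "data.frame")
  )
}

## ----------------------------------------------------------------- SAF ----

#' Write a region set as a SAF file
#'
#' Simplified Annotation Format: 5 tab-separated columns
#' `GeneID/Chr/Start/End/Strand` with 1-based inclusive coordinates.
#'
#' @param rs A `region_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_saf <- function(rs, path) {
  stopifnot(is(rs, "region_set"))
  df <- data.frame(GeneID = rs$region_id, Chr = rs$chrom, Start = rs$start,
                   End = rs$end, Strand = rs$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SAF file into a region set
#'
#' @param path SAF file path.
#' @param category Category label to attach (default `"custom"`).
#' @return A `region_set`.
#' @export
read_saf <- function(path, category = "custom") {
  lines <- readLines(path)
  if (length(lines) < 1L) .stop("empty SAF file: ", path)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != 5L)
  if (length(bad))
    .stop("malformed SAF line ", bad[1L], " in ", path,
          " (expected 5 tab-separated columns, found ", nfield[bad[1L]], ")")
  df <- read.delim(text = lines, stringsAsFactors = FALSE)
  expected <- c("GeneID", "Chr", "Start", "End", "Strand")
  if (!identical(names(df)[1:5], expected))
    .stop("SAF header must be ", paste(expected, collapse = "/"))
  out <- data.frame(region_id = as.character(df$GeneID), chrom = as.character(df$Chr),
                    start = as.integer(df$Start), end = as.integer(df$End),
                    strand = as.character(df$Strand), stringsAsFactors = FALSE)
  if (any(out$start > out$end)) .stop("SAF contains start > end")
  if (anyDuplicated(out$region_id)) .stop("duplicated region ids in SAF")
  structure(out, category = category, class = c("region_set", "data.frame"))
}
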