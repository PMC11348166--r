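## Deterministic synthetic data with known contamination truth.
##
## The generator emulates the benchmark design of a contamination-spiking
## experiment: one shared expression truth, several groups differing only in
## the mass fraction of fragments of genomic-DNA origin. RNA fragments are
## drawn from union-exon transcripts honoring a strandedness purity; gDNA
## fragments are placed uniformly (or with a GC-linear density) over the whole
## genome with Bernoulli(0.5) strands, since both strands of double-stranded
## gDNA template equally.

#' Generate a toy reference genome and annotation
#'
#' Writes a FASTA (with controllable regional GC) and an Ensembl-dialect GTF
#' containing mono- and multi-exonic genes, an rRNA-biotype gene and an
#' organellar chromosome. Byte-identical output for identical seeds.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_chroms Number of main (nuclear) chromosomes.
#' @param chrom_length Length of each main chromosome in bp.
#' @param n_genes Total number of genes across main chromosomes.
#' @param gc_landscape Either a single GC fraction (constant landscape) or a
#'   range `c(lo, hi)`; each 10 kb block draws its GC uniformly from it.
#' @param organellar_length Length of the organellar chromosome `MT` in bp.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `sim_reference`: paths (`fasta`, `gtf`),
#'   `chrom_lengths`, loaded `models`, and `tiles` (1 kb genome tiles with GC,
#'   used for GC-biased fragment placement).
#' @export
make_reference <- function(seed, n_chroms = 2L, chrom_length = 1.6e6,
                           n_genes = 150L, gc_landscape = c(0.35, 0.65),
                           organellar_length = 20000L,
                           out_dir = tempfile("simref_")) {
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- c(as.character(seq_len(n_chroms)), "MT")
  chrom_lengths <- setNames(c(rep(chrom_length, n_chroms), organellar_length),
                            chroms)

  gc_range <- if (length(gc_landscape) == 1L) rep(gc_landscape, 2L) else gc_landscape
  block <- 10000L
  seqs <- lapply(chrom_lengths, function(len) {
    nb <- ceiling(len / block)
    gcb <- runif(nb, gc_range[1L], gc_range[2L])
    parts <- vapply(seq_len(nb), function(i) {
      size <- min(block, len - (i - 1L) * block)
      p <- c((1 - gcb[i]) / 2, gcb[i] / 2, gcb[i] / 2, (1 - gcb[i]) / 2)
      paste(sample(c("A", "C", "G", "T"), size, replace = TRUE, prob = p),
            collapse = "")
    }, "")
    paste(parts, collapse = "")
  })

  ## gene structures, then feasibility-checked placement with random gaps
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chroms + 1L)))
  gene_rows <- list(); gtf <- character(0)
  gid <- 0L
  for (ci in seq_len(n_chroms)) {
    ng <- per_chrom[ci]
    n_ex <- sample(1:4, ng, replace = TRUE, prob = c(0.25, 0.3, 0.25, 0.2))
    widths <- lapply(seq_len(ng), function(i) {
      ex <- sample(300:800, n_ex[i], replace = TRUE)
      intr <- if (n_ex[i] > 1L) sample(200:1500, n_ex[i] - 1L, replace = TRUE)
              else integer(0)
      list(ex = ex, intr = intr, span = sum(ex) + sum(intr))
    })
    spans <- vapply(widths, `[[`, 0, "span")
    free <- chrom_length - sum(spans)
    min_gap <- 400L
    if (free < min_gap * (ng + 1L))
      .stop("infeasible placement: chromosome ", ci, " too short for ", ng,
            " genes")
    gw <- runif(ng + 1L, 0.3, 1)
    gaps <- min_gap + floor((free - min_gap * (ng + 1L)) * gw / sum(gw))
    pos <- 0L
    for (i in seq_len(ng)) {
      gid <- gid + 1L
      start <- pos + gaps[i] + 1L
      w <- widths[[i]]
      ex_start <- start + cumsum(c(0L, head(w$ex, -1L) + w$intr))
      ex_end <- ex_start + w$ex - 1L
      pos <- ex_end[length(ex_end)]
      strand <- sample(c("+", "-"), 1L)
      biotype <- if (gid == 1L) "rRNA"
                 else if (gid %% 20L == 0L) "lincRNA" else "protein_coding"
      id <- sprintf("G%04d", gid)
      gene_rows[[gid]] <- data.frame(gene_id = id, chrom = chroms[ci],
                                     strand = strand, biotype = biotype)
      attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', id, biotype)
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";',
                        id, id, biotype)
      gtf <- c(gtf,
        paste(chroms[ci], "sim", "gene", start, pos, ".", strand, ".", attr_g,
              sep = "\t"),
        paste(chroms[ci], "sim", "transcript", start, pos, ".", strand, ".",
              attr_t, sep = "\t"),
        vapply(seq_along(ex_start), function(e)
          paste(chroms[ci], "sim", "exon", ex_start[e], ex_end[e], ".", strand,
                ".", sprintf('%s exon_number "%d";', attr_t, e), sep = "\t"),
          ""))
    }
  }
  ## one organellar rRNA gene on MT
  gid <- gid + 1L
  mt_start <- 2001L
  mt_end <- min(mt_start + 1499L, organellar_length - 100L)
  id <- sprintf("G%04d", gid)
  attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_biotype "Mt_rRNA";',
                    id, id)
  gtf <- c(gtf,
    paste("MT", "sim", "gene", mt_start, mt_end, ".", "+", ".",
          sprintf('gene_id "%s"; gene_biotype "Mt_rRNA";', id), sep = "\t"),
    paste("MT", "sim", "transcript", mt_start, mt_end, ".", "+", ".", attr_t,
          sep = "\t"),
    paste("MT", "sim", "exon", mt_start, mt_end, ".", "+", ".",
          sprintf('%s exon_number "1";', attr_t), sep = "\t"))

  fasta <- file.path(out_dir, "genome.fa")
  gtf_path <- file.path(out_dir, "annotation.gtf")
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- chroms
  Biostrings::writeXStringSet(dss, fasta, width = 60L)
  if (file.exists(paste0(fasta, ".fai"))) file.remove(paste0(fasta, ".fai"))
  Rsamtools::indexFa(fasta)
  writeLines(gtf, gtf_path)

  models <- load_gene_models(gtf_path, chrom_lengths)

  ## 1 kb genome tiles with GC, for GC-aware gDNA placement
  tile_w <- 1000L
  tiles <- do.call(rbind, lapply(chroms, function(ch) {
    st <- seq(1L, chrom_lengths[[ch]], by = tile_w)
    data.frame(chrom = ch, start = st,
               end = pmin(st + tile_w - 1L, chrom_lengths[[ch]]))
  }))
  tile_seq <- Biostrings::DNAStringSet(substring(
    unlist(seqs)[tiles$chrom], tiles$start, tiles$end))
  tiles$gc <- as.numeric(.gc_of_seqs(tile_seq))

  structure(list(fasta = fasta, gtf = gtf_path, chrom_lengths = chrom_lengths,
                 models = models, tiles = tiles, seed = seed),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("Synthetic reference (seed ", x$seed, "): ",
      length(x$chrom_lengths) - 1L, " chromosome(s) + MT, ",
      nrow(x$models$genes), " genes\n", sep = "")
  invisible(x)
}

## default shared expression truth: log-normal weights over genes with a
## union-exon transcript at least one fragment long; a quarter of them are
## silent, so contamination visibly inflates the percent-expressed diagnostic
default_expression_weights <- function(ref, seed, fragment_length = 200L,
                                       silent_fraction = 0.25) {
  set.seed(seed)
  g <- ref$models$genes
  ok <- g$union_exon_length >= fragment_length
  w <- setNames(rep(0, nrow(g)), g$gene_id)
  w[ok] <- stats::rlnorm(sum(ok), meanlog = 0, sdlog = 1.5)
  idx <- which(ok)
  silent <- sample(idx, floor(length(idx) * silent_fraction))
  w[silent] <- 0
  w / sum(w)
}

#' Simulate one RNA-seq sample with known contamination truth
#'
#' Draws `n_fragments` single-end fragments: RNA fragments from the union-exon
#' transcripts of expressed genes (multinomial across genes, uniform within
#' the transcript, spliced blocks mapped back to the genome, read strand
#' honoring `strandedness_purity` under the reverse convention) and gDNA
#' fragments placed over the whole genome, uniformly or with a per-kilobase
#' density proportional to `a + b * GC`, with strand drawn Bernoulli(0.5) (or
#' exactly strand-symmetric pairs when `gdna_strand = "symmetric"`).
#'
#' @param ref A `sim_reference`.
#' @param sample_id Sample label.
#' @param n_fragments Total fragments.
#' @param contamination Mass fraction of fragments of gDNA origin in `[0, 1]`.
#' @param expression Named per-gene weight vector (normalised internally);
#'   default drawn from the reference seed so samples share one truth.
#' @param strandedness_purity Probability that an RNA read takes the library
#'   orientation (0.5 = unstranded library, 1 = perfectly stranded).
#' @param gc_bias `NULL` for uniform gDNA placement, or coefficients
#'   `c(a, b)` of the linear GC density.
#' @param gdna_strand `"random"` or `"symmetric"` (each gDNA position emitted
#'   once per strand; used for noiseless stranded-correction truth).
#' @param fragment_length Fragment length in bp (fixed).
#' @param seed Integer seed for this sample.
#' @return A `sim_fragments` data frame (one row per fragment: `frag_id`,
#'   `chrom`, `start`, `end`, `strand`, `origin`, `gene_id`, `n_blocks`) with
#'   attributes `blocks` (per-block long table) and `truth` (true per-gene
#'   counts, `true_intergenic_fpb = n_gdna / genome bp`, parameters).
#' @export
simulate_sample <- function(ref, sample_id, n_fragments = 200000L,
                            contamination = 0, expression = NULL,
                            strandedness_purity = 0.5, gc_bias = NULL,
                            gdna_strand = c("random", "symmetric"),
                            fragment_length = 200L, seed = 1L) {
  stopifnot(is(ref, "sim_reference"),
            contamination >= 0, contamination <= 1,
            strandedness_purity >= 0, strandedness_purity <= 1)
  gdna_strand <- match.arg(gdna_strand)
  set.seed(seed)
  flen <- as.integer(fragment_length)
  n_gdna <- round(contamination * n_fragments)
  if (gdna_strand == "symmetric") n_gdna <- 2L * (n_gdna %/% 2L)
  n_rna <- n_fragments - n_gdna

  if (is.null(expression))
    expression <- default_expression_weights(ref, ref$seed + 7L, flen)
  expression <- expression / sum(expression)

  models <- ref$models
  ue <- .union_exons(models)
  gene_ids <- names(ue)
  expression <- expression[gene_ids]
  expression[is.na(expression)] <- 0
  gene_len <- setNames(models$genes$union_exon_length, models$genes$gene_id)[gene_ids]
  expression[gene_len < flen] <- 0
  expression <- expression / sum(expression)
  gene_strand <- setNames(models$genes$strand, models$genes$gene_id)[gene_ids]

  true_counts <- setNames(as.numeric(
    stats::rmultinom(1L, n_rna, expression)), gene_ids)

  blocks <- list(); frag_rows <- list(); bi <- 0L
  frag_id_counter <- 0L
  for (g in gene_ids[true_counts > 0]) {
    k <- true_counts[[g]]
    ex <- ue[[g]]
    ex <- GenomicRanges::sort(ex, ignore.strand = TRUE)
    ew <- IRanges::width(ex)
    tx_end <- cumsum(ew); tx_start <- tx_end - ew + 1L
    L <- tx_end[length(tx_end)]
    p <- sample.int(L - flen + 1L, k, replace = TRUE)
    fr <- IRanges::IRanges(p, p + flen - 1L)
    txr <- IRanges::IRanges(tx_start, tx_end)
    ov <- IRanges::findOverlaps(fr, txr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    ps <- pmax(IRanges::start(fr)[qh], tx_start[sh])
    pe <- pmin(IRanges::end(fr)[qh], tx_end[sh])
    gstart <- GenomicRanges::start(ex)[sh] + (ps - tx_start[sh])
    gend <- gstart + (pe - ps)
    ids <- frag_id_counter + qh
    ord <- order(ids, gstart)
    bi <- bi + 1L
    blocks[[bi]] <- data.frame(frag_id = ids[ord],
                               chrom = models$genes$chrom[match(g, models$genes$gene_id)],
                               start = gstart[ord], end = gend[ord],
                               stringsAsFactors = FALSE)
    nb <- tabulate(qh, nbins = k)
    read_strand <- ifelse(runif(k) < strandedness_purity,
                          ifelse(gene_strand[[g]] == "+", "-", "+"),
                          gene_strand[[g]])
    frag_rows[[bi]] <- data.frame(
      frag_id = frag_id_counter + seq_len(k),
      strand = read_strand, origin = "rna", gene_id = g, n_blocks = nb,
      stringsAsFactors = FALSE)
    frag_id_counter <- frag_id_counter + k
  }

  if (n_gdna > 0L) {
    tiles <- ref$tiles
    tlen <- tiles$end - tiles$start + 1L
    wts <- if (is.null(gc_bias)) as.numeric(tlen)
           else pmax(gc_bias[1L] + gc_bias[2L] * tiles$gc, 0) * tlen
    n_pos <- if (gdna_strand == "symmetric") n_gdna %/% 2L else n_gdna
    ti <- sample.int(nrow(tiles), n_pos, replace = TRUE, prob = wts)
    maxstart <- pmin(tiles$end[ti],
                     ref$chrom_lengths[tiles$chrom[ti]] - flen + 1L)
    minstart <- pmin(tiles$start[ti], maxstart)
    pos <- pmin(minstart + floor(runif(n_pos) * (maxstart - minstart + 1L)),
                maxstart)
    strands <- if (gdna_strand == "symmetric") c(rep("+", n_pos), rep("-", n_pos))
               else sample(c("+", "-"), n_pos, replace = TRUE)
    if (gdna_strand == "symmetric") {
      ti <- c(ti, ti); pos <- c(pos, pos)
    }
    ids <- frag_id_counter + seq_along(pos)
    bi <- bi + 1L
    blocks[[bi]] <- data.frame(frag_id = ids, chrom = tiles$chrom[ti],
                               start = pos, end = pos + flen - 1L,
                               stringsAsFactors = FALSE)
    frag_rows[[bi]] <- data.frame(frag_id = ids, strand = strands,
                                  origin = "gdna", gene_id = NA_character_,
                                  n_blocks = 1L, stringsAsFactors = FALSE)
    frag_id_counter <- frag_id_counter + length(pos)
  }

  blocks <- if (length(blocks)) do.call(rbind, blocks)
            else data.frame(frag_id = integer(0), chrom = character(0),
                            start = integer(0), end = integer(0))
  frags <- if (length(frag_rows)) do.call(rbind, frag_rows)
           else data.frame(frag_id = integer(0), strand = character(0),
                           origin = character(0), gene_id = character(0),
                           n_blocks = integer(0))
  ## per-fragment genomic span (blocks are disjoint and increasing per frag)
  b <- blocks[order(blocks$frag_id, blocks$start), , drop = FALSE]
  first <- !duplicated(b$frag_id)
  last <- !duplicated(b$frag_id, fromLast = TRUE)
  frags <- frags[order(frags$frag_id), , drop = FALSE]
  frags$chrom <- b$chrom[first]
  frags$start <- b$start[first]
  frags$end <- b$end[last]
  frags <- frags[, c("frag_id", "chrom", "start", "end", "strand", "origin",
                     "gene_id", "n_blocks")]
  rownames(frags) <- NULL
  blocks <- b

  truth <- list(
    sample_id = sample_id, seed = seed,
    contamination_fraction = contamination,
    strandedness_purity = strandedness_purity,
    gc_bias_coeffs = gc_bias,
    n_rna = n_rna, n_gdna = n_gdna,
    true_counts = true_counts,
    true_intergenic_fpb = n_gdna / sum(ref$chrom_lengths)
  )
  structure(frags, blocks = blocks, truth = truth, sample_id = sample_id,
            class = c("sim_fragments", "data.frame"))
}

## internal: sim_fragments -> (GRangesList blocks, strand, njunc)
.fragments_to_blocks <- function(frags, chrom_lengths) {
  blocks <- attr(frags, "blocks")
  gr <- GenomicRanges::GRanges(blocks$chrom,
                               IRanges::IRanges(blocks$start, blocks$end))
  GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths
  grl <- S4Vectors::split(gr, factor(blocks$frag_id, levels = frags$frag_id))
  list(blocks = grl, strand = frags$strand, njunc = frags$n_blocks - 1L)
}

#' Count a simulated fragment table against a feature catalog
#'
#' The table-based twin of [assign_fragments()]: identical assignment
#' semantics (category precedence, max-overlap region attribution, union-exon
#' gene counting with strand modes), applied directly to the simulator's
#' fragment blocks without a BAM round trip.
#'
#' @param frags A `sim_fragments` object.
#' @param catalog Feature catalog from [build_feature_catalog()] (its
#'   `intergenic` entry may be tiled with [tile_regions()]).
#' @param models A `gene_models` object.
#' @param strand_mode Strandedness counting mode.
#' @return A `fragment_assignment`.
#' @export
assign_fragment_table <- function(frags, catalog, models,
                                  strand_mode = c("unstranded", "forward",
                                                  "reverse")) {
  strand_mode <- match.arg(strand_mode)
  rep_ <- .fragments_to_blocks(frags, models$chrom_lengths)
  .assign_core(rep_$blocks, rep_$strand, rep_$njunc, catalog, models,
               strand_mode, sample_id = attr(frags, "sample_id") %||% "sample")
}

#' Write simulated fragments as a sorted, indexed BAM
#'
#' Emits deterministic single-end SAM records (spliced fragments get `M/N/M`
#' CIGARs), converts to BAM, coordinate-sorts and indexes.
#'
#' @param frags A `sim_fragments` object.
#' @param ref The `sim_reference` the fragments were simulated from.
#' @param path Output BAM path (`.bam`).
#' @return The BAM path, invisibly.
#' @export
write_fragments_bam <- function(frags, ref, path) {
  stopifnot(grepl("\\.bam$", path))
  blocks <- attr(frags, "blocks")
  bl <- split(blocks, blocks$frag_id)
  cigar <- vapply(bl, function(b) {
    b <- b[order(b$start), , drop = FALSE]
    m <- b$end - b$start + 1L
    if (nrow(b) == 1L) paste0(m, "M")
    else {
      gaps <- b$start[-1L] - b$end[-nrow(b)] - 1L
      paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
             m[length(m)], "M")
    }
  }, "")
  cigar <- cigar[as.character(frags$frag_id)]
  flag <- ifelse(frags$strand == "-", 16L, 0L)
  sam <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref$chrom_lengths),
            as.integer(ref$chrom_lengths)),
    sprintf("frag%07d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
            frags$frag_id, flag, frags$chrom, frags$start, cigar))
  samfile <- sub("\\.bam$", ".sam", path)
  writeLines(sam, samfile)
  tmp <- Rsamtools::asBam(samfile, sub("\\.bam$", "_unsorted", path),
                          overwrite = TRUE, indexDestination = FALSE)
  Rsamtools::sortBam(tmp, sub("\\.bam$", "", path))
  Rsamtools::indexBam(path)
  file.remove(tmp, samfile)
  invisible(path)
}

#' Generate the multi-sample contamination benchmark bundle
#'
#' Five groups of `n_replicates` samples sharing one expression truth and
#' differing only in the gDNA fragment fraction
#' (0, 0.01, 0.1, 1 and 10 percent), the synthetic analogue of a
#' contamination-spiking benchmark. Each sample is simulated, counted against
#' the feature catalog (intergenic regions tiled into `window_width` bp
#' windows for FPB stability), and returned together with its truth tables.
#'
#' @param seed Integer seed.
#' @param n_fragments Fragments per sample.
#' @param n_replicates Replicates per group.
#' @param contamination_levels Fragment mass fractions per group.
#' @param gc_bias Optional `c(a, b)` GC-linear gDNA density.
#' @param strandedness_purity RNA strandedness purity (0.5 = unstranded).
#' @param window_width Intergenic window width in bp.
#' @param ref Optionally, a pre-built `sim_reference` (else built from
#'   `seed`).
#' @return A list of class `sim_bundle`: `reference`, `catalog` (intergenic
#'   tiled), `samples` (metadata), `assignments`, `expr` (`gene_expr`),
#'   `intergenic_counts` (window-by-sample), `window_lengths`, `ir_percent`,
#'   and `truth` (`true_counts`, `true_intergenic_fpb`,
#'   `contamination_fraction`).
#' @export
make_dataset_I_analog <- function(seed, n_fragments = 200000L,
                                  n_replicates = 3L,
                                  contamination_levels = c(0, 1e-4, 1e-3,
                                                           0.01, 0.1),
                                  gc_bias = NULL, strandedness_purity = 0.5,
                                  window_width = 1000L, ref = NULL) {
  if (is.null(ref)) ref <- make_reference(seed)
  models <- ref$models
  catalog <- build_feature_catalog(models)
  catalog$intergenic <- tile_regions(catalog$intergenic, window_width)
  expr_w <- default_expression_weights(ref, seed + 7L)

  groups <- paste0(formatC(contamination_levels * 100), "%")
  meta <- data.frame(
    sample_id = paste0(rep(LETTERS[2:(1 + length(contamination_levels))],
                           each = n_replicates),
                       seq_len(n_replicates)),
    group = rep(groups, each = n_replicates),
    contamination = rep(contamination_levels, each = n_replicates),
    stringsAsFactors = FALSE)

  assignments <- vector("list", nrow(meta))
  true_counts <- NULL
  true_fpb <- numeric(nrow(meta))
  for (k in seq_len(nrow(meta))) {
    frags <- simulate_sample(
      ref, sample_id = meta$sample_id[k], n_fragments = n_fragments,
      contamination = meta$contamination[k], expression = expr_w,
      strandedness_purity = strandedness_purity, gc_bias = gc_bias,
      seed = (as.numeric(seed) * 1000 + k) %% .Machine$integer.max)
    assignments[[k]] <- assign_fragment_table(frags, catalog, models,
                                              "unstranded")
    tr <- attr(frags, "truth")
    true_fpb[k] <- tr$true_intergenic_fpb
    if (is.null(true_counts))
      true_counts <- matrix(0, length(tr$true_counts), nrow(meta),
                            dimnames = list(names(tr$true_counts),
                                            meta$sample_id))
    true_counts[, k] <- tr$true_counts
  }
  expr <- expr_from_assignments(assignments, models)
  ic <- vapply(assignments, function(a) a$per_region_counts$intergenic,
               numeric(nrow(catalog$intergenic)))
  colnames(ic) <- meta$sample_id
  rd <- read_distribution(assignments)
  structure(list(
    reference = ref, catalog = catalog, samples = meta,
    assignments = assignments, expr = expr,
    intergenic_counts = ic,
    window_lengths = region_lengths(catalog$intergenic),
    ir_percent = setNames(rd$ir_percent, rd$sample_id),
    truth = list(true_counts = true_counts,
                 true_intergenic_fpb = setNames(true_fpb, meta$sample_id),
                 contamination_fraction = setNames(meta$contamination,
                                                   meta$sample_id),
                 expression_weights = expr_w)
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic contamination benchmark:", nrow(x$samples), "samples in",
      length(unique(x$samples$group)), "groups\n")
  print(x$samples)
  invisible(x)
}
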