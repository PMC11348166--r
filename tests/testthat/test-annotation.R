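test_that("GTF parsing collects exons, biotypes and validates chromosomes", {
  ex <- data.frame(gene_id = c("G1", "G1", "G2", "G3"),
                   chrom = "chr1",
                   start = c(101, 301, 1001, 2001),
                   end = c(200, 400, 1500, 2300),
                   strand = c("+", "+", "-", "+"))
  m <- toy_models(ex, c(chr1 = 5000),
                  biotypes = list(G1 = "protein_coding", G2 = "lincRNA",
                                  G3 = NA))
  expect_s3_class(m, "gene_models")
  expect_equal(nrow(m$genes), 3L)
  expect_equal(m$genes$n_exons[m$genes$gene_id == "G1"], 2L)
  expect_equal(m$genes$biotype[m$genes$gene_id == "G2"], "lincRNA")
  expect_equal(m$genes$biotype[m$genes$gene_id == "G3"], "unknown")
  expect_equal(m$genes$union_exon_length,
               c(200, 500, 300)[order(c("G1", "G2", "G3"))])

  # chromosome absent from the genome
  ex_bad <- ex; ex_bad$chrom[4] <- "chrX"
  expect_error(toy_models(ex_bad, c(chr1 = 5000)), "chrX")
  # exon beyond chromosome end
  ex_far <- ex; ex_far$end[3] <- 6000
  expect_error(toy_models(ex_far, c(chr1 = 5000)), "outside chromosome")
})

test_that("union-exon length merges overlapping exons", {
  ex <- data.frame(gene_id = "G1", chrom = "c", start = c(1, 51), end = c(100, 150),
                   strand = "+")
  m <- toy_models(ex, c(c = 1000))
  expect_equal(m$genes$union_exon_length, 150)
})

test_that("feature catalog: complement, intron derivation, exon collapse", {
  # one gene span [201,400] on a 1000 bp chromosome -> intergenic complement
  m1 <- toy_models(data.frame(gene_id = "G1", chrom = "c", start = 201,
                              end = 400, strand = "+"), c(c = 1000))
  cat1 <- build_feature_catalog(m1, organellar_chroms = character(0))
  expect_equal(cat1$intergenic$start, c(1, 401))
  expect_equal(cat1$intergenic$end, c(200, 1000))

  # gene with exons [1,100],[201,300] -> intron [101,200]
  m2 <- toy_models(data.frame(gene_id = "G1", chrom = "c",
                              start = c(1, 201), end = c(100, 300),
                              strand = "+"), c(c = 1000))
  cat2 <- build_feature_catalog(m2, organellar_chroms = character(0))
  expect_equal(cat2$intron$start, 101)
  expect_equal(cat2$intron$end, 200)

  # two overlapping genes, exons [1,100] and [51,150] -> collapsed [1,150]
  m3 <- toy_models(data.frame(gene_id = c("G1", "G2"), chrom = "c",
                              start = c(1, 51), end = c(100, 150),
                              strand = "+"), c(c = 1000))
  cat3 <- build_feature_catalog(m3, organellar_chroms = character(0))
  expect_equal(cat3$collapsed_exon$start, 1)
  expect_equal(cat3$collapsed_exon$end, 150)

  # organellar chromosome must exist
  expect_error(build_feature_catalog(m3, organellar_chroms = "MT"), "MT")
})

test_that("exon/intron/intergenic partition non-organellar chromosomes at flank 0", {
  for (seed in 1:20) {
    ref <- make_reference(seed, n_chroms = 1L, chrom_length = 5e4,
                          n_genes = 6L, organellar_length = 5000L)
    catl <- build_feature_catalog(ref$models)
    main <- setdiff(names(ref$chrom_lengths), "MT")
    for (ch in main) {
      tot <- sum(region_lengths(catl$collapsed_exon)[catl$collapsed_exon$chrom == ch]) +
        sum(region_lengths(catl$intron)[catl$intron$chrom == ch]) +
        sum(region_lengths(catl$intergenic)[catl$intergenic$chrom == ch])
      expect_equal(tot, unname(ref$chrom_lengths[ch]))
    }
    # pairwise overlaps are empty (interval sweep over all three categories)
    ivs <- do.call(rbind, lapply(c("collapsed_exon", "intron", "intergenic"),
      function(cn) catl[[cn]][catl[[cn]]$chrom %in% main,
                              c("chrom", "start", "end")]))
    ivs <- ivs[order(ivs$chrom, ivs$start), ]
    same_chrom <- ivs$chrom[-1] == ivs$chrom[-nrow(ivs)]
    expect_true(all(ivs$start[-1][same_chrom] >
                      ivs$end[-nrow(ivs)][same_chrom]))
  }
})

test_that("flanked gene spans shrink the intergenic complement", {
  m <- toy_models(data.frame(gene_id = "G1", chrom = "c", start = 401,
                             end = 600, strand = "+"), c(c = 1000))
  catl <- build_feature_catalog(m, organellar_chroms = character(0),
                                intergenic_flank = 100)
  expect_equal(catl$intergenic$start, c(1, 701))
  expect_equal(catl$intergenic$end, c(300, 1000))
})

test_that("region and gene GC match per-base counting, with N exclusion", {
  fa <- toy_fasta(list(c1 = "ATGCNNNNACGTACGGGGCC"))
  rs <- structure(data.frame(region_id = c("R1", "R2", "R3"),
                             chrom = "c1", start = c(1, 5, 9),
                             end = c(4, 8, 20), strand = "."),
                  category = "custom", class = c("region_set", "data.frame"))
  gc <- calculate_region_gc(rs, fa)
  expect_equal(gc$gc[1], 0.5)          # "ATGC"
  expect_true(is.na(gc$gc[2]))         # "NNNN": undefined
  expect_equal(gc$gc[3], oracle_gc("ACGTACGGGGCC"))

  # interval beyond sequence end errors
  rs_bad <- rs; rs_bad$end[3] <- 99
  expect_error(calculate_region_gc(rs_bad, fa), "beyond")

  # gene GC over the union-exon sequence: "ATG" + "CCC" -> 4/6
  fa2 <- toy_fasta(list(c1 = "ATGAAAACCCAAAA"))
  m <- toy_models(data.frame(gene_id = "G1", chrom = "c1",
                             start = c(1, 8), end = c(3, 10), strand = "+"),
                  c(c1 = 14))
  ggc <- calculate_gene_gc(m, fa2)
  expect_equal(ggc$gc, 4 / 6, tolerance = 1e-12)
})

test_that("GC equals brute-force counting on random toy regions", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T", "N"), 5000, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.25, 0.05)), collapse = "")
  fa <- toy_fasta(list(z = seq))
  st <- sample(4500, 100)
  rs <- structure(data.frame(region_id = paste0("r", 1:100), chrom = "z",
                             start = st, end = st + sample(5:400, 100, TRUE),
                             strand = "."),
                  category = "custom", class = c("region_set", "data.frame"))
  gc <- calculate_region_gc(rs, fa)
  expected <- vapply(seq_len(100), function(i)
    oracle_gc(substring(seq, rs$start[i], rs$end[i])), 0)
  expect_equal(gc$gc, expected)
})

test_that("SAF round-trips region sets and rejects malformed files", {
  catl <- small_catalog()
  for (cn in names(catl)) {
    p <- tempfile(fileext = ".saf")
    write_saf(catl[[cn]], p)
    back <- read_saf(p, category = attr(catl[[cn]], "category"))
    expect_equal(as.data.frame(back), as.data.frame(catl[[cn]]))
  }
  # single row parse
  p <- tempfile(fileext = ".saf")
  writeLines(c("GeneID\tChr\tStart\tEnd\tStrand", "R1\tchr1\t1\t200\t+"), p)
  rs <- read_saf(p)
  expect_equal(unname(unlist(rs[1, ])), c("R1", "chr1", "1", "200", "+"))
  expect_equal(unname(region_lengths(rs)), 200)
  # fixture with three regions -> lengths by end - start + 1
  writeLines(c("GeneID\tChr\tStart\tEnd\tStrand",
               "A\tc\t1\t200\t.", "B\tc\t401\t1000\t.", "C\tc\t1101\t1200\t."), p)
  expect_equal(unname(region_lengths(read_saf(p))), c(200, 600, 100))
  # malformed column count names the line
  writeLines(c("GeneID\tChr\tStart\tEnd\tStrand", "A\tc\t1\t200"), p)
  expect_error(read_saf(p), "line 2")
})

test_that("intergenic windows tile without changing total length", {
  catl <- small_catalog()
  w <- tile_regions(catl$intergenic, 1000)
  expect_equal(sum(region_lengths(w)), sum(region_lengths(catl$intergenic)))
  expect_true(all(region_lengths(w) <= 1000))
  expect_false(anyDuplicated(w$region_id) > 0)
})
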