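# The four correction algorithms and the post-correction gene filters.

.mk_expr <- function(counts, lengths) new_gene_expr(counts, lengths)

test_that("global correction subtracts FPB x length, clamps and rounds", {
  cnt <- matrix(c(50, 5, 0), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  lens <- c(a = 1000, b = 1000, c = 500)
  ge <- .mk_expr(cnt, lens)
  out <- global_correction(ge, c(s1 = 0.01))
  expect_equal(unname(out$matrix[, 1]), c(40, 0, 0))  # 50-10, clamp(5-10), 0
  expect_s3_class(out, "corrected_expr")
  # zero contamination level leaves the matrix unchanged
  out0 <- global_correction(ge, c(s1 = 0))
  expect_equal(out0$matrix, cnt)
  # corrected counts stay non-negative integers
  expect_true(all(out$matrix >= 0 & out$matrix == round(out$matrix)))
})

test_that("GC correction with flat bins reduces exactly to global correction", {
  set.seed(23)
  cnt <- matrix(rpois(40, 60), 20, 2,
                dimnames = list(paste0("g", 1:20), c("s1", "s2")))
  lens <- setNames(sample(500:4000, 20), rownames(cnt))
  gc <- setNames(runif(20, 0.2, 0.9), rownames(cnt))
  ge <- .mk_expr(cnt, lens)
  fpb <- c(s1 = 0.004, s2 = 0.011)
  bins <- matrix(rep(fpb, each = 20), 20,
                 dimnames = list(paste0("gc_bin_", 1:20), names(fpb)))
  out_gc <- gc_correction(ge, bins, gc, global_fallback = fpb)
  out_gl <- global_correction(ge, fpb)
  expect_identical(out_gc$matrix, out_gl$matrix)
  # bin routing: a gene with GC 0.42 reads bin 9
  fit <- structure(list(method = "gc", global_fpb = fpb,
                        gc_bin_fpb = matrix(seq_len(40) / 1000, 20,
                          dimnames = dimnames(bins)),
                        span = 0.75, n_regions_used = c(10, 10)),
                   class = "contamination_fit")
  pred <- predict(fit, c(x = 1000), gene_gc = c(x = 0.42))
  expect_equal(pred["x", "s1"], 1000 * 9 / 1000)
})

test_that("GC-aware correction beats global correction under GC-biased truth", {
  ref <- small_ref(19)
  catl <- small_catalog(19)
  wcat <- catl
  wcat$intergenic <- tile_regions(catl$intergenic, 500)
  ggc <- calculate_gene_gc(ref$models, ref$fasta)
  rgc <- calculate_region_gc(wcat$intergenic, ref$fasta)
  fr <- simulate_sample(ref, "S", n_fragments = 120000, contamination = 0.3,
                        gc_bias = c(0.05, 1.9), seed = 91)
  fa <- assign_fragment_table(fr, wcat, ref$models)
  ge <- expr_from_assignments(list(fa), ref$models)
  fit <- contamination_fit(
    matrix(fa$per_region_counts$intergenic,
           dimnames = list(names(fa$per_region_counts$intergenic), "S")),
    region_lengths(wcat$intergenic), region_gc = rgc, method = "gc")
  tc <- matrix(attr(fr, "truth")$true_counts,
               dimnames = list(names(attr(fr, "truth")$true_counts), "S"))
  tc <- tc[rownames(ge$counts), , drop = FALSE]
  rmse <- function(m) sqrt(mean((m - tc)^2))
  r_gc <- rmse(gc_correction(ge, fit, ggc)$matrix)
  r_gl <- rmse(global_correction(ge, fit)$matrix)
  expect_lt(r_gc, rmse(ge$counts))   # correction helps at all
  expect_lte(r_gc, r_gl * 1.05)      # and the GC route is not worse
})

test_that("IR% correction recipe: log2 CPM offset and null-case stability", {
  # closed form: count 0 at library size 1e6
  cnt <- matrix(c(0, 999999 + 1, 10, 10), 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  libs <- colSums(cnt)
  y00 <- unname(log2((0 + 0.5) / (libs[1] + 1) * 1e6))
  expect_equal(y00, log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)

  # beta_IR = 0 truth: adjustment leaves the transform nearly untouched
  set.seed(29)
  n <- 8
  counts <- matrix(rnbinom(200 * n, mu = 80, size = 10), 200, n,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:n)))
  ir <- runif(n, 1, 3)  # varies, but independent of expression
  out <- ir_percent_correction(counts, rep("A", n), ir)
  delta <- out$matrix - out$params$log2cpm
  expect_lt(mean(abs(delta)), 0.15)
  expect_equal(dim(out$matrix), dim(counts))
  expect_equal(out$covariates$ir_percent, ir)

  # guard rails
  expect_error(ir_percent_correction(counts, rep("A", n), rep(2, n)),
               "uninformative")
  expect_error(ir_percent_correction(counts, paste0("s", 1:n), ir),
               "rank deficient|collinear")
})

test_that("IR% correction removes contamination-driven IR association", {
  set.seed(31)
  n <- 12
  ir <- c(rep(0.5, 4), rep(5, 4), rep(15, 4)) + runif(n, -0.2, 0.2)
  base <- matrix(rnbinom(300 * n, mu = 60, size = 20), 300, n)
  contam_per_ir <- runif(300, 0, 4)          # gene-length-like susceptibility
  counts <- round(base + outer(contam_per_ir, ir))
  dimnames(counts) <- list(paste0("g", 1:300), paste0("s", 1:n))
  out <- ir_percent_correction(counts, rep("A", n), ir)
  y <- out$params$log2cpm
  cors_y <- apply(y, 1, function(r) cor(r, ir))
  hot <- which(abs(cors_y) > 0.5)
  expect_gt(length(hot), 50)                  # contamination shows up pre-correction
  cors_adj <- apply(out$matrix[hot, , drop = FALSE], 1, function(r) cor(r, ir))
  expect_lt(mean(abs(cors_adj)), 0.1)
  # cross-check the precision-weight pipeline against the reference smoother
  skip_if_not_installed("limma")
  design <- model.matrix(~ I(ir - mean(ir)))
  v <- limma::voom(counts, design)
  fit_l <- limma::lmFit(v, design)
  expect_gt(cor(fit_l$coefficients[, 2], out$params$beta_ir), 0.98)
})

test_that("stranded subtraction is exact and clamps at zero", {
  s <- matrix(c(100, 10, 0), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  a <- matrix(c(40, 25, 0), 3, 1, dimnames = dimnames(s))
  out <- stranded_correction(s, a)
  expect_equal(unname(out$matrix[, 1]), c(60, 0, 0))
  # antisense all zero: identity
  expect_equal(stranded_correction(s, a * 0)$matrix, s)
  # mismatched ids refuse to subtract
  b <- a; rownames(b) <- c("a", "b", "z")
  expect_error(stranded_correction(s, b), "share")
})

test_that("noiseless stranded simulation is corrected exactly", {
  ref <- small_ref()
  catl <- small_catalog()
  fr <- simulate_sample(ref, "P", n_fragments = 20000, contamination = 0.2,
                        strandedness_purity = 1, gdna_strand = "symmetric",
                        seed = 37)
  sense <- assign_fragment_table(fr, catl, ref$models, "reverse")
  anti <- assign_fragment_table(fr, catl, ref$models, "forward")
  ge_s <- expr_from_assignments(list(sense), ref$models)
  ge_a <- expr_from_assignments(list(anti), ref$models)
  out <- stranded_correction(ge_s, ge_a)
  tc <- attr(fr, "truth")$true_counts[rownames(out$matrix)]
  expect_equal(unname(out$matrix[, 1]), unname(tc))
})

test_that("junction-support filter drops unsupported multi-exonic genes only", {
  cnt <- matrix(1, 4, 2, dimnames = list(c("mono", "multi0", "multi1", "multiN"),
                                         c("s1", "s2")))
  n_ex <- c(mono = 1, multi0 = 3, multi1 = 2, multiN = 4)
  js <- matrix(c(0, 0, 3, 0, 0, 0, 0, 5), 4, 2,
               dimnames = list(rownames(cnt), colnames(cnt)))
  kept <- filter_unsupported_multiexonic(cnt, n_ex, js,
                                         min_junction_fragments = 1)
  expect_setequal(rownames(kept), c("mono", "multi1", "multiN"))
  # a higher threshold can drop more
  kept2 <- filter_unsupported_multiexonic(cnt, n_ex, js,
                                          min_junction_fragments = 4)
  expect_setequal(rownames(kept2), c("mono", "multiN"))
})

test_that("low-in-clean filter keeps genes visible in any clean sample", {
  cnt <- matrix(c(
    0,   0,  500,  400,   # gA: only in contaminated samples -> dropped
    900, 800, 850, 900,   # gB: everywhere -> kept
    0,  600,   0,   0,    # gC: in a clean sample of cond2 -> kept
    0,   0,    0,   0),   # gD: nowhere -> dropped
    nrow = 4, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC", "gD"), c("c1", "c2", "d1", "d2")))
  cond <- c("x", "y", "x", "y")
  contam <- c(FALSE, FALSE, TRUE, TRUE)
  kept <- filter_low_in_clean(cnt, cond, contam, cpm_cutoff = 1)
  expect_setequal(rownames(kept), c("gB", "gC"))
  expect_error(filter_low_in_clean(cnt, c("x", "x", "y", "y"),
                                   c(FALSE, FALSE, TRUE, TRUE), 1),
               "no uncontaminated")
})

test_that("identical seeds give bitwise-identical corrected matrices", {
  run <- function() {
    ref <- make_reference(11, n_chroms = 1L, chrom_length = 6e4, n_genes = 8L,
                          organellar_length = 6000L)
    catl <- build_feature_catalog(ref$models)
    catl$intergenic <- tile_regions(catl$intergenic, 500)
    fr <- simulate_sample(ref, "S", n_fragments = 30000, contamination = 0.15,
                          seed = 5)
    fa <- assign_fragment_table(fr, catl, ref$models)
    ge <- expr_from_assignments(list(fa), ref$models)
    fit <- contamination_fit(
      matrix(fa$per_region_counts$intergenic,
             dimnames = list(names(fa$per_region_counts$intergenic), "S")),
      region_lengths(catl$intergenic),
      region_gc = calculate_region_gc(catl$intergenic, ref$fasta),
      method = "gc")
    gcg <- calculate_gene_gc(ref$models, ref$fasta)
    list(fa_hash = unlist(fa$per_region_counts),
         global = global_correction(ge, fit)$matrix,
         gc = gc_correction(ge, fit, gcg)$matrix,
         files = c(tools::md5sum(ref$fasta), tools::md5sum(ref$gtf)))
  }
  a <- run(); b <- run()
  expect_identical(a$global, b$global)
  expect_identical(a$gc, b$gc)
  expect_identical(a$fa_hash, b$fa_hash)
  expect_identical(unname(a$files), unname(b$files))
})
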