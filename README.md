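# gdnaclean

Detection and correction of genomic DNA (gDNA) contamination in bulk RNA-seq
data, for anyone doing post-alignment quality control or rescuing
contaminated libraries that cannot be re-sequenced.

Residual gDNA co-extracted with RNA is replicated by reverse transcriptase
and amplified alongside cDNA, producing reads that did not come from
transcripts. The tell-tale signal is an elevated **intergenic read fraction
(IR%)**: gDNA fragments land anywhere on the genome, transcription only on
exons. Contamination inflates counts of lowly expressed and mono-exonic
genes and generates spurious differential-expression calls, most severely in
rRNA-depleted and ultra-low-input libraries.

## What it computes

**Diagnostics.** From an Ensembl GTF + genome FASTA the package derives
coordinate-collapsed feature catalogs (exon, intron, intergenic, rRNA,
organellar), assigns aligned fragments (BAM or simulated tables) to them with
a native featureCounts-style counter, and reports: per-category read
percentages including IR%, expression distributions under standard
transforms, percent of genes above CPM/TPM cutoffs, pairwise correlations,
distances, clustering and PCA, plus library-strandedness inference
(stranded iff the matching-read proportion `max(p, 1-p) > 0.9`).

**Contamination model.** Per sample, intergenic coverage in fragments per
base, `FPB = count / length` over intergenic windows. The estimator is

- *global*: `f = median{ FPB_r : count_r > 0 }`, and per-gene expected
  contamination is `f * L_g`;
- *GC-stratified*: a loess fit of FPB on region GC content, summarised into
  20 equal-width GC bins (median of predictions per bin), so per-gene
  contamination is `f_bin(GC_g) * L_g`.

**Corrections.** Four algorithms:

| method | output | idea |
|---|---|---|
| `global_correction()` | counts | `round(max(0, c_gs − f_s L_gs))` |
| `gc_correction()` | counts | same, with GC-bin-specific `f` |
| `ir_percent_correction()` | log2-CPM | precision-weighted gene-wise linear model with centred IR% as covariate; adjusted matrix removes the `β̂_IR (IR%_s − mean IR%)` term |
| `stranded_correction()` | counts | `max(0, sense − antisense)`: gDNA is strand-symmetric, RNA is not |

plus two optional filters (multi-exonic genes without junction support;
genes low in all uncontaminated samples of every condition).

**Synthetic truth.** A deterministic generator (`make_reference()`,
`simulate_sample()`, `make_dataset_I_analog()`) builds toy genomes and a
5-group × 3-replicate contamination-spiking benchmark (0–10% gDNA fragments,
shared expression truth) with full per-sample truth tables, so every
estimator is validated against known answers.

## Worked example

Simulate a sample with 5% gDNA contamination, diagnose it, fit the
contamination model and correct the counts:

```r
library(gdnaclean)

ref <- make_reference(seed = 1, n_chroms = 1, chrom_length = 2e5, n_genes = 20)
catalog <- build_feature_catalog(ref$models)
catalog$intergenic <- tile_regions(catalog$intergenic, 1000)

frags <- simulate_sample(ref, "S1", n_fragments = 50000,
                         contamination = 0.05, seed = 2)
fa <- assign_fragment_table(frags, catalog, ref$models)
rd <- read_distribution(fa)

fit <- contamination_fit(
  matrix(fa$per_region_counts$intergenic,
         dimnames = list(names(fa$per_region_counts$intergenic), "S1")),
  region_lengths(catalog$intergenic))
expr <- expr_from_assignments(list(fa), ref$models)
corrected <- global_correction(expr, fit)
```

Output:

```
IR% = 3.62 (exon 96.09%, intron 0.30%)
gDNA contamination fit (method: global)
Global FPB (median over non-zero intergenic regions):
   S1
0.011
gDNA-corrected expression [method: global]: 21 genes x 1 samples (count scale)
true intergenic FPB     : 0.0114
mean |raw - true|       : 16.1
mean |corrected - true| : 5.19
```

Reading it: 3.62% of assigned fragments are intergenic — for this genome
that is the footprint of ~5% gDNA fragments (the rest fall in genic space).
The fitted global FPB of 0.011 fragments/base recovers the true placement
density 0.0114 within 4%, and subtracting `FPB × gene length` cuts the mean
absolute error of the count matrix against the RNA-only truth from 16.1 to
5.19 fragments per gene. For real data, start from
`assign_fragments(bam, catalog, models)` and
`import_quant(counts, lengths, tpm)` instead of the simulator; see the
vignette in `vignettes/` for the model details and assumptions.

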