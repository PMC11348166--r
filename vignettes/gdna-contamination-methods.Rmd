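---
title: "Detecting and correcting genomic DNA contamination in RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting genomic DNA contamination in RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdnaclean)
```

## The problem

Residual genomic DNA (gDNA) co-extracted with RNA survives library
preparation surprisingly well: reverse transcriptase replicates DNA templates,
and the replicated fragments are end-repaired, adaptor-ligated and amplified
indistinguishably from cDNA. The result is a background of reads that did not
come from transcripts. In rRNA-depleted and ultra-low-input libraries this
background can reach several percent of all fragments, inflating counts for
lowly expressed and mono-exonic genes, shifting expression distributions
upward, and generating spurious differential-expression calls. PolyA-selected
libraries are largely protected, because oligo-dT capture removes most gDNA.

Because gDNA fragments fall anywhere on the genome while transcription is
confined to annotated exons, the share of aligned fragments landing in
intergenic space — the intergenic read fraction, IR% — is the primary
diagnostic. `gdnaclean` computes IR% together with a battery of supporting
diagnostics, and then corrects gene-level count matrices with one of four
algorithms.

## Feature catalogs

All diagnostics rest on a partition of the genome derived from an Ensembl GTF
(`load_gene_models()`, `build_feature_catalog()`):

* **collapsed exons** — the genome-wide union of all annotated exons;
* **introns** — each gene's span minus its own exon union, collapsed across
  genes, minus the global exon union (so a base that is exonic in *any* gene
  is never intronic);
* **intergenic** — the chromosome complement of all gene spans, optionally
  extended by a flank, excluding organellar chromosomes;
* **rRNA exons** and **organellar chromosomes**, tallied separately.

With a flank of 0 the first three categories partition every non-organellar
chromosome exactly, a property asserted by the test suite by interval sweep.
The flank (default 0 bp) exists because incompletely annotated UTRs otherwise
leak genuine mRNA reads into the intergenic category and inflate IR%; it is a
user decision, not a calibrated constant. Organellar chromosomes default to
`MT` and rRNA biotypes to `rRNA`, `rRNA_pseudogene`, `Mt_rRNA` (Ensembl
naming); both are configurable because annotation dialects differ. One open
choice deserves a note: when genes overlap, we subtract the *global* exon
union when deriving introns, so a region exonic in gene A and intronic in
gene B counts as exonic. This keeps the three categories disjoint, at the
price of a slightly smaller intron set than a purely per-gene derivation.

## Fragment assignment

`assign_fragments()` (BAM) and `assign_fragment_table()` (simulated fragment
tables) share one counting engine. A *fragment* is the sequenced template: a
read pair counts once, a single-end read counts once. Secondary,
supplementary, unmapped and QC-fail alignments are ignored; duplicate-marked
reads are counted by default (configurable) since deduplication is a separate
judgement call in RNA-seq. Assignment semantics:

* a fragment belongs to the highest-precedence category
  (exon > intron > intergenic) for which any of its aligned blocks overlaps
  any region — so a fragment straddling an exon/intron boundary is exonic;
* within the category it is attributed to the single region of maximal
  overlap (ties: leftmost region start, then region order). This keeps
  per-window intergenic counts conservative — a fragment is never counted in
  two adjacent windows, so window coverage in fragments per base stays
  unbiased;
* rRNA and organellar features are tallied independently of the exclusive
  three;
* gene counts use union-exon overlap honoring the strand mode; fragments
  compatible with more than one gene are ambiguous and dropped. Spliced
  (N-containing CIGAR) counted fragments accumulate per-gene junction
  support.

Library strandedness is inferred by `detect_strandedness()` from fragments
overlapping unambiguous single-gene loci: the proportion of fragments
antisense to the annotated gene (the "reverse" convention of common stranded
kits) is reported, and the library is called stranded when
`max(p, 1 - p) > 0.9`, with direction read off the exceeding side. Below 100
evaluable fragments the call is "inconclusive" instead of a silent number.

## Diagnostics

Category percentages use the fragments assigned to
exon ∪ intron ∪ intergenic as denominator, so the three percentages sum to
100 and IR% is directly interpretable; rRNA, organellar and gene-assigned
fractions are reported against the same denominator but outside the budget.
Expression-level diagnostics follow standard recipes: median-of-ratios size
factors with `log2(normalised + 1)`; CPM with a pseudocount of one tenth of
the minimal *positive* CPM before log (a literal minimum over a matrix with
zeros would zero the pseudocount, hence the "positive"); percent of genes
with expression strictly above a user cutoff in CPM or TPM; Pearson
correlations, Euclidean distances, complete-linkage clustering order and PCA
(gene-wise centred and scaled, zero-variance genes dropped) on the
log-normalised matrix. The log2(normalised + 1) transform stands in for a
variance-stabilising transform in the PCA; it is simpler, dependency-free
and adequate for sample-level structure.

## The contamination estimator

For each sample, coverage of every intergenic region (long regions are tiled
into 1 kb windows for stability) is expressed in fragments per base,
FPB = count / length. The estimator (`contamination_fit()`) has two routes:

* **global** — the median FPB over intergenic regions with non-zero counts.
  The median over non-zero regions is robust to the zero-inflation of sparse
  contamination and to occasional unannotated transcription.
* **GC-stratified** — a loess regression (span 0.75, degree 2) of FPB on
  region GC content over the non-zero regions; GC is split into 20
  equal-width bins (`floor(GC * 20)`, GC = 1 closed into the last bin), each
  bin's estimate is the median of loess predictions at its member regions'
  GC, empty bins inherit the nearest populated bin, and estimates are
  clamped at zero. The loess is fitted on raw FPB (not log FPB) because the
  response is already a rate and zero-count regions are excluded; fitting on
  a log scale is a documented alternative that would down-weight the
  right tail. With fewer than 20 usable regions or fewer than 3 distinct
  bins the route falls back to the global estimate with a warning.

Expected per-gene contamination is then FPB × gene length, where gene length
is the per-sample effective length when a quantifier triplet was imported and
the union-exon length otherwise, and the FPB is either the global scalar or
the gene's GC-bin estimate (genes with undefined GC fall back to the global
scalar). GC content excludes non-ACGT bases from numerator and denominator.

## Corrections

**Global** and **GC%**: `corrected = round(max(0, count − FPB × length))`.
Clamping at zero and rounding to the nearest integer are our choices —
downstream count-based differential-expression tools require non-negative
integers, and the subtraction itself can overshoot on genes whose observed
count is below the expected contamination. Setting all 20 bins to the global
FPB makes the GC route reduce exactly to the global route, which the test
suite asserts as an identity.

**IR%**: instead of subtracting counts, IR% enters a gene-wise linear model
as a covariate. Counts are transformed to
`log2((count + 0.5) / (libsize + 1) * 1e6)`; the gene-wise mean–variance
trend (lowess, span 0.5, of the square-root residual standard deviation on
mean log2 count) yields observation precision weights `1 / trend^4`; each
gene is then fitted by weighted least squares on
`[intercept | group dummies | centred IR%]`, and the adjusted matrix removes
only the IR% term: `y − β̂_IR (IR% − mean IR%)`. Centring keeps the intercept
at the clean-sample baseline. The output is on the log2-CPM scale — it feeds
linear-model differential expression directly, or the IR% column of the
returned covariate table can be placed in a count-model design instead. The
model assumes IR% varies across samples (a constant covariate is refused)
and is not collinear with the group labels; in a benchmark where every group
*is* a contamination level, the honest design is a single group, and the
group factor should carry only biological structure.

**Stranded**: for libraries with stranded-read proportion above 0.9, both
strands of double-stranded gDNA template equally, so gDNA-derived counts are
strand-symmetric in expectation while RNA keeps the transcript orientation.
Quantifying each sample with the correct and the opposite strandedness and
subtracting (`max(0, sense − antisense)`) removes the gDNA component without
any distributional assumption. On noiseless strand-symmetric truth the
recovery is exact, which the suite asserts.

Two optional post-correction filters mirror common practice: dropping
multi-exonic genes with no splicing-junction support in any sample (retaining
mono-exonic genes always), and dropping genes whose CPM stays at or below a
cutoff in every uncontaminated sample of every condition. Both can raise
false negatives in junction-poor libraries and are off by default.

## The synthetic benchmark

`make_reference()` builds a deterministic toy genome (default: two 1.6 Mb
chromosomes plus a 20 kb organellar `MT`, 150 mono- and multi-exonic genes
including an rRNA-biotype and an organellar gene, regional GC drawn per
10 kb block from 0.35–0.65) and `make_dataset_I_analog()` simulates five
groups × three replicates at gDNA fragment fractions 0, 0.01, 0.1, 1 and
10 percent — the classic contamination-spiking design — from one shared
log-normal expression truth in which a quarter of genes are silent, at
200,000 fragments of 200 bp per sample. Intergenic regions are tiled into
1 kb windows, giving ≈ 2,700 windows with an expected ≈ 6 fragments per
window at 10% contamination; these sizes keep a full 15-sample benchmark
under a couple of minutes on one core while leaving enough regions for the
loess fit. RNA fragments are placed uniformly on union-exon transcripts
(spliced blocks mapped back through the exon structure), gDNA fragments
uniformly per base or with a GC-linear density, strands Bernoulli(0.5) or
exactly symmetric for noiseless stranded truth.

What the generator does *not* emulate: sequencing error, mapping ambiguity,
PCR duplication and "jackpot" amplification bias, fragment-length variation,
annotation incompleteness, and biological variability between replicates
(replicates differ only by sampling noise). Passing tests therefore
demonstrate the estimators' correctness under their own assumptions — a
uniform (or GC-linear) contamination field and a faithful annotation — not
robustness to misalignment or PCR artefacts. On real data those factors
widen the error of every subtraction method; the IR% covariate route, which
only assumes a linear IR–log-expression relationship, degrades most
gracefully, matching its behaviour on published benchmarks.

## Numerical choices and degenerate inputs

* All-zero intergenic counts raise "no evidence of contamination" rather
  than returning 0 — correcting a clean sample is a no-op that should be
  explicit.
* Regions or genes whose sequence has no ACGT base get `NA` GC and are
  routed to the global estimate.
* The per-region attribution tie-break (leftmost start, then region order)
  and the deterministic seeds threaded through every simulation make all
  fixture files and corrected matrices bit-reproducible, which the suite
  checks by hashing.
* `loess` uses exact ("direct") surface evaluation; with the default
  ~2,700 windows this is well within budget and avoids interpolation
  artefacts at bin edges.

## Limitations

The corrections assume contamination is adequately summarised by intergenic
coverage (global or per GC stratum). Very low contamination (< 1% in
rRNA-depleted data) is dominated by sampling noise and is better left
uncorrected; polyA-selected libraries violate the uniformity assumption
because oligo-dT capture selects gDNA fragments non-uniformly, and no
subtraction method is expected to help there. The stranded route requires a
genuinely stranded library (proportion > 0.9) and same-locus antisense
transcription will be subtracted along with the contamination.
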