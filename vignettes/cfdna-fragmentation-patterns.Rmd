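---
title: "Methods: cfDNA fragmentation patterns and the IFP ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentation patterns and the IFP ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `cfpattern`: what each fragmentation pattern measures, how the
classifier ensemble is assembled without information leakage, what the
synthetic cohort generator does and does not emulate, and where the design
was genuinely open and a choice had to be made.

## Background and scope

Cell-free DNA (cfDNA) circulates as nucleosome-protected fragments: the
length distribution peaks near 166 bp (a nucleosome plus linker) with a
10-bp periodicity below ~143 bp, and cleavage concentrates in
nucleosome-depleted open-chromatin regions (OCRs). In cancer patients a
tumor-derived component is admixed at some tumor fraction; it is shorter,
follows tumor-specific chromatin accessibility, and shifts 5′ end-motif
usage. `cfpattern` quantifies these signals as ten per-sample feature
sets over a region set, classifies samples per pattern, and stacks the
per-pattern probabilities into the Integrated Fragmentation Pattern (IFP)
score.

All genomic intervals are 0-based half-open internally (the BED/`.frag`
convention); 1-based formats (GFF3) are converted at the parser boundary.
Fragment "midpoint" (centroid) is `floor((start + end) / 2)` — a
deterministic integer rule; the midpoint must lie in `[start, end)` of a
region for the fragment to belong to it. The default chromosome universe
is whatever the supplied chromosome-sizes table declares; for human work
that would typically be the 22 autosomes.

## Region sets

* **Peak unions** merge overlapping *and* bookended (distance-0)
  intervals, matching common peak-union practice; the minimal disjoint
  cover is computed by `GenomicRanges::reduce`.
* **Width standardization** replaces each region with a fixed-width
  window (default 200 bp: 100 bp either side of the centroid; the
  centroid of an odd-length region is the floor of its midpoint).
  Regions whose standardized window would cross a chromosome boundary
  are **dropped, not clamped**: the position-offset patterns (WPS, OCF)
  require every region to share the exact width.
* **TSS windows** are strand-aware: `(−150, +50)` means 150 bp upstream
  of the TSS in the direction of transcription. Presets for 5-Mb genome
  bins and cytoband-derived chromosome arms support the coarser,
  genome-wide pattern definitions (fragment-ratio features over large
  bins, size distributions per arm).

## The ten patterns

Let a region's assigned fragments be those whose midpoint falls inside
it, with lengths `len = end − start`.

* **length** — per chromosome, proportions over 30 bins of 10 bp below
  300 bp plus a single ≥300 bp class (31 × n_chrom features). A
  chromosome with no counted fragments contributes a zero block, keeping
  the feature axis fixed.
* **pfe** — per region, Shannon entropy (base 2) of proportions over 17
  length categories: `<100`, fifteen 10-bp bins over `[100, 250)`, and
  `≥250`. The boundary length 250 goes to the overflow class
  (half-open consistency). Empty categories contribute 0; an empty
  region scores 0; the value is bounded by log₂ 17 ≈ 4.087.
* **fsr** — per region, proportions of short (65–150), medium (151–220)
  and long (221–400 bp) fragments **among in-range fragments only**:
  lengths outside all three classes are excluded from the denominator.
* **fsd** — per chromosome, proportions over 67 bins of 5 bp spanning
  65–400 bp; the final bin is closed at 400 so the scheme has exactly 67
  categories. Computed over region-assigned fragments (a whole-genome
  variant is available by using per-chromosome regions).
* **coverage** — midpoint count per region.
* **ends** — number of fragment end positions inside the region; the
  left end is `start`, the right end is the last covered base
  `end − 1`. A fragment contributes 0, 1 or 2 (0 when it spans the whole
  region). All fragments are scanned, not only midpoint-assigned ones.
* **ocf** — orientation-aware fragmentation. With region center `c`,
  upstream-end counts `U_p` (fragment starts) and downstream-end counts
  `D_p` (fragment last bases), OCF = Σ_{p∈[c−70,c−50]} (D_p − U_p) +
  Σ_{p∈[c+50,c+70]} (U_p − D_p) — 20-bp flank ranges from a 60-bp shift.
  Values are reported raw (the defining equation carries no depth
  normalization); an optional per-region normalization exists but is off
  by default.
* **ifs** — integrated fragmentation score `n·(1 + l/L)` with `n`
  midpoint-assigned fragments, `l` their mean length, and `L` the mean
  length of region-assigned fragments on that chromosome. Regions on a
  fragment-free chromosome score 0.
* **wps** — windowed protection score. For each locus `p` of the
  region, a 120-bp window `[p − 60, p + 60)` scores +1 per fragment
  spanning the whole window and −1 per fragment overlapping it with at
  least one end inside; the region's value is the mean over its loci.
  The implementation evaluates the per-fragment locus counts in closed
  form, which equals the sliding per-locus evaluation (verified against
  a brute-force oracle in the tests). The window is centered at the
  locus; the anchor is not fixed by the definition, and centering is the
  symmetric choice.
* **edm** — per chromosome, proportions of the `4^k`
  (default k = 4 → 256) possible 5′ end motifs among region-assigned
  fragments: for a plus-strand (or strandless) fragment the k reference
  bases at `[start, start + k)`, for a minus-strand fragment the
  reverse complement of `[end − k, end)`. Motifs containing N are
  excluded from numerator and denominator. One motif is counted per
  fragment (the sequenced 5′ end); counting both ends is available as an
  option.

No fragment-length filter is applied to WPS / coverage / ends / OCF / IFS
by default (none is part of their definitions); a configurable filter
exists for sensitivity analyses.

## Preprocessing

**GC correction.** Region GC fractions exclude N bases from numerator
and denominator; all-N regions are recorded as missing and excluded from
fitting. For each sample, a Lowess curve (span 0.75) of score versus
region GC is fitted across regions and scores are replaced by residuals.
The fit is per sample — GC bias is a property of each library — so the
correction uses no cross-sample information and cannot leak labels.
Per-chromosome matrices (length, fsd, edm) pass through unchanged: their
features do not correspond to fixed-GC loci. Fewer than 10 regions with
defined GC is refused.

**Standardization.** Each sample row is rescaled to mean 0 and
*population* (n-denominator) SD 1 across its features — "standardize
each sample". The alternative axis (per-feature scaling across training
samples) is available where cross-region weight comparison matters (see
the importance screen); when used inside cross-validation it must be
fitted per training fold. Zero-variance rows become all-zero rather than
NaN.

**PCA.** Optional per-pattern reduction before the SVM, fitted on
training rows only and applied to held-out rows with frozen center and
rotation. The default cap is 50 components (bounded by
`min(n_train − 1, n_features)`); the reference analyses reduce "to the
same dimensions" without stating the value, so the cap is configurable
and recorded.

The canonical order is GC-correct, then Z-score; `PatternMatrix` flags
record both steps and double application is refused.

## Classification and evaluation

* **Folds.** Repeated stratified k-fold (default 10 × 10): per repeat,
  each class is shuffled and dealt across folds, preserving the class
  ratio within one sample. Everything derives from one top-level seed
  through named sub-seeds, so runs are exactly reproducible.
* **Base models.** Linear-kernel SVMs (cost 1) with Platt probability
  calibration. The linear kernel is required structurally: the region
  importance screen reads the absolute weights of the decision function,
  which only linear models provide.
* **Stacking.** Per repeat, the samples × patterns matrix of
  *out-of-fold* probabilities is itself cross-validated with the same
  fold partition: the meta SVM scoring fold f is trained on the other
  folds' rows only. A sample's IFP score (mean over repeats, in [0, 1])
  therefore never involves a model that saw that sample — neither at the
  base nor at the meta level. How the original analysis obtained its
  training-set probabilities is not specified; out-of-fold stacking is
  the leakage-safe reading and is what the leakage tests pin down.
* **Metrics.** Rank-based AUC (ties count ½, equal to the scaled
  Mann–Whitney U), and sensitivity at 95% / 85% specificity, defined as
  the maximum sensitivity over thresholds whose specificity meets the
  target (equivalently an exhaustive threshold sweep; predicting
  positive at score ≥ threshold). The per-pattern report gives the mean
  AUC over repeats with the repeat-level 95% CI
  (mean ± 1.96·SD/√repeats) and sensitivities on repeat-averaged
  out-of-fold scores.
* **Null calibration.** The repeat-level CI measures fold-assignment
  noise around this cohort's point estimate, not the sampling noise of
  an AUC under a permuted-label null; it can be arbitrarily narrow. The
  null-control test therefore checks coverage of 0.5 with the
  Mann–Whitney null SE, √((n₁+n₀+1)/(12 n₁ n₀)), the statistically valid
  scale for that hypothesis.
* **Tissue of origin.** One-vs-rest per cancer type with the same
  stacked construction; classes are ranked per sample by probability
  (ties broken by fixed class order) and first / second accuracies are
  the fraction of samples whose true class ranks top-1 / top-2.
* **Independent validation.** `train_ifp` freezes full-data base models,
  the meta SVM, and every feature axis; external cohorts must match the
  axes exactly and are scored without any refitting.
* **Stratified evaluation.** Tumor-fraction bins are half-open at the
  published boundaries: low [0, 2%), medium [2%, 15%), high [15%, 100%]
  (the bracket notation in the source material is inconsistent; 2% goes
  to medium, 15% to high). Each cancer stratum is scored against the
  full control set; strata are compared by Wilcoxon rank-sum
  (consecutive pairs) and Kruskal–Wallis (overall).

## Region importance and signatures

Each of the seven region-resolved patterns (pfe, fsr, coverage, ends,
ocf, ifs, wps) contributes per-region |weight|s from a linear SVM fitted
on the full, un-reduced feature matrices (when the PCA path is active
for classification, this interpretation fit is a parallel non-PCA fit).
FSR's three per-class weights are summed first, so every region has
exactly seven importance entries; their sum ranks regions, and the top-k
(default 15,000) screen uses region order as the deterministic
tie-break, making selections nest as k grows. The per-chromosome
patterns carry no region-specific weights and are excluded.

The interpretation fit uses a heavily regularized margin (cost 0.01)
rather than the classification default: with the number of regions on
the order of the sample count, a lightly regularized SVM's weight vector
is dominated by margin noise and ranks regions poorly even when
per-region effects are individually strong; under strong regularization
the weight vector approaches the class-centroid difference direction,
which is a stable importance measure. In the very-high-dimensional
regime (hundreds of thousands of regions, n ≪ p) this distinction
matters less; at desk scale it is decisive, and the benchmark's planted
regions are recovered reliably only with the regularized fit.
Classification models are unaffected (cost 1).

The differential-IFS signature keeps regions with a lower case mean and
a two-sided Wilcoxon rank-sum p below 0.01, unadjusted for multiplicity
(by design — the screen feeds a gene-mapping step, not inference). The
test uses exact enumeration when both groups are under 20 samples and
tie-free, otherwise the tie-corrected normal approximation. Gene mapping
expands each region ±75 kb and reports unique overlapping gene bodies,
optionally restricted to protein-coding biotypes; regulatory-potential
weighting of distal peaks (as in enhancer-mode gene-mapping web tools)
is intentionally not reproduced.

Pattern correlation is Spearman, in two modes: across samples on
per-pattern predicted probabilities, or across regions on healthy-median
vectors of the six patterns sharing the region dimension (pfe, coverage,
ends, ocf, ifs, wps; fsr is excluded because its per-region dimension is
3).

## The synthetic cohort generator

The generator exists so every stage — IO, calculators, preprocessing,
cross-validation, stacking, screening — can be exercised end to end with
known ground truth. Its defaults are the package's benchmark conditions:

| parameter | default | meaning |
|---|---|---|
| genome | 4 chromosomes × 1 Mb | uniform random A/C/G/T (optional sinusoidal GC landscape) |
| regions | 50 per chromosome, 200 bp | jittered grid ≥ 1 kb apart, log-normal(0, 0.5) openness |
| cohort | 60 healthy + 60 cancer | 30,000 fragments per sample |
| healthy lengths | N(166, 10) + comb | sub-nucleosomal comb at 83–143 bp (10-bp steps, SD 3), weight 0.15 |
| tumor lengths | N(145, 10) + comb | comb weight 0.30 |
| tumor fraction | log-uniform [0.01, 0.5] | per cancer sample; healthy = 0 |
| planted regions | 10% of regions | openness ×1.6 for tumor-derived draws |
| end-motif bias | CCCA, factor 3 | rejection sampling of tumor draws against the reference |
| background | 20% of fragments | uniform off-region placement |
| positioning | SD 40 bp | midpoints around region centers |

Rationale for the free choices: the mono-nucleosomal and comb components
reproduce the published length phenomenology (the 166-bp mode and 10-bp
periodicity are descriptive targets, not a generative law, so narrow
normals on a 10-bp grid are the simplest faithful mixture); the tumor
mean of 145 bp and the 1.6× openness fold-change are the benchmark's
stated effect sizes; the log-uniform tumor-fraction law spans the
clinically reported range so that all three stratification bins
(2% / 15% boundaries) are populated, with realistic weight on
hard, low-fraction samples; 50 regions per chromosome gives each region
enough assigned fragments (~100 per sample on average) for per-region
statistics to be meaningful at 30,000 fragments per sample — a
deliberate desk-scale choice, denser region sets dilute per-region
coverage below what the real-data regime (hundreds of millions of
fragments) provides. Motif bias is implemented by rejection against the
actual toy reference so that the EDM calculator reads real sequence;
every fragment is resampled as a whole on rejection (bounded retries),
keeping positions and lengths consistent. The stage surrogate is the
tumor-fraction tertile among cancers, enabling stage-stratified
evaluation without clinical semantics. Fragments are clamped into
chromosome bounds; only background draws can be affected because regions
sit ≥ 10 kb from chromosome ends.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: real chromatin landscapes
and peak shapes, sequencing error, duplicates, mappability, batch
effects, inter-individual coverage bias beyond the planted GC trend, and
biological end-motif structure (beyond the single planted motif). The
benchmark demonstrates that the machinery recovers planted signal of the
assumed form at realistic effect sizes; it cannot certify clinical
performance.

## Benchmark problem sizes and determinism

The repository's seeded benchmark (tests and `scripts/acceptance.R`)
uses the generator defaults above: 120 samples × 30,000 fragments over
200 regions, 10 × 10 cross-validation for all ten patterns plus
stacking, an importance screen against the planted truth, a full
permuted-label null, and tumor-fraction stratification. These sizes were
chosen so the complete run finishes in minutes on a single CPU while
leaving all effects well-resolved. Every stochastic step (reference,
regions, cohorts, folds, SVM probability calibration) descends from one
top-level seed via named sub-seeds; identical seeds give byte-identical
fragment files and feature tables.

Numerical edge cases are handled explicitly and tested: empty regions
and chromosomes produce zeros (never NaN), proportions blocks sum to 1
or are identically zero, zero-variance samples standardize to zero,
all-N regions drop out of GC fitting, degenerate AUC inputs (a single
class) are errors, and importance ties break by region order.

## Known limitations

* The importance screen interprets linear weights; it says which regions
  the model uses, not which are biologically causal.
* Out-of-fold stacking is the conservative reading of the ensemble
  construction; in-fold stacking would report optimistically and is not
  offered.
* BAM decoding is out of scope by design: the canonical input is the
  `.frag` text dialect (an upstream contract of proper-pair,
  deduplicated, MAPQ-filtered fragments), so alignment tooling is never
  a test dependency.
* The Lowess correction removes smooth per-sample GC trends only;
  fragment-level GC effects and batch structure are out of scope.
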