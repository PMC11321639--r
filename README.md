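# cfpattern

Fragmentation-pattern analysis of cell-free DNA (cfDNA) over regulatory
regions, with a stacked classifier ensemble for cancer detection.

Plasma cfDNA is released mostly by dying blood cells as nucleosome-protected
fragments (a length peak near 166 bp with a 10-bp periodicity below ~143 bp).
Tumor-derived cfDNA is shorter, redistributes coverage around
cancer-specific open-chromatin regions (OCRs), and shifts fragment
end-motif usage. `cfpattern` turns these signals into ten feature sets per
sample, computed over a BED region set (OCR peaks standardized to 200 bp,
TSS windows, genome bins, or chromosome arms):

| pattern | features | definition |
|---|---|---|
| `length` | 31 × chrom | fragment-length proportions, 10-bp bins below 300 bp + one ≥300 bp class |
| `pfe` | per region | fragmentation entropy −Σ pᵢ log₂ pᵢ over 17 length categories (<100, 15 × 10 bp, ≥250) |
| `fsr` | 3 per region | short (65–150) / medium (151–220) / long (221–400 bp) proportions |
| `fsd` | 67 × chrom | fine size distribution, 5-bp bins over 65–400 bp |
| `coverage` | per region | fragment midpoints in the region |
| `ends` | per region | fragment end positions in the region |
| `ocf` | per region | orientation-aware end imbalance Σ(D−U) + Σ(U−D) over ±60±10 bp flanks of the center |
| `ifs` | per region | integrated fragmentation score n·(1 + l/L) |
| `wps` | per region | windowed protection score: spanning − partially-covering fragments of a sliding 120-bp window, averaged over loci |
| `edm` | 256 × chrom | 5′ end-motif (4-mer) proportions per chromosome |

Region-axis features are GC-corrected per sample by Lowess regression
(span 0.75) of score on region GC and standardized by per-sample Z-scores.
Each pattern trains a linear SVM with probability calibration under
repeated stratified cross-validation (default 10×10); the ten out-of-fold
probabilities are stacked by a second linear SVM into the **Integrated
Fragmentation Pattern (IFP)** score. The package also screens
classifier-important regions (sum of absolute linear weights over the
seven region-resolved patterns), extracts differentially-low IFS signature
regions (Wilcoxon rank-sum, lower case mean, p < 0.01) with ±75 kb gene
mapping, runs one-vs-rest tissue-of-origin calling, and ships a synthetic
cfDNA cohort simulator so the whole pipeline is testable without external
sequencing data.

## Worked example

Simulate a small labelled cohort, extract all ten patterns, and train the
IFP ensemble:

```r
library(cfpattern)

cfg <- sim_config(seed = 11, n_chrom = 2, chrom_length = 200000,
                  n_regions = 20, n_healthy = 12, n_cancer = 12,
                  n_fragments = 3000, tf_range = c(0.1, 0.5))
co    <- simulate_cohort(cfg, "cohort/")
sizes <- read_chrom_sizes(co$sizes_path)
rs    <- read_bed(co$regions_bed, sizes = sizes)
ref   <- load_reference(co$ref_path)
sheet <- read_sample_sheet(co$sheet_path)

mats <- extract_cohort_features(sheet, rs, ref, sizes)
prep <- preprocess_patterns(mats, region_gc(rs, ref))
plan <- make_folds(sheet$label, repeats = 2, folds = 4, seed = 1)
cv   <- cross_validate(prep, sheet$label, plan, positive = "cancer", pca_dim = 8)
st   <- stack_ifp(cv, sheet$label, plan, positive = "cancer")
rbind(cv$report, st$report)
```

```
     pattern       auc     ci_lo     ci_hi sens_spec95 sens_spec85
 1:   length 1.0000000 1.0000000 1.0000000  1.00000000   1.0000000
 2:      pfe 0.5798611 0.5594444 0.6002778  0.25000000   0.4166667
 3:      fsr 1.0000000 1.0000000 1.0000000  1.00000000   1.0000000
 4:      fsd 1.0000000 1.0000000 1.0000000  1.00000000   1.0000000
 5: coverage 0.7500000 0.6411111 0.8588889  0.25000000   0.2500000
 6:     ends 0.7361111 0.5863889 0.8858333  0.25000000   0.2500000
 7:      ocf 0.5347222 0.4802778 0.5891667  0.25000000   0.2500000
 8:      ifs 0.5555556 0.4058333 0.7052778  0.16666667   0.1666667
 9:      wps 0.6215278 0.4241667 0.8188889  0.08333333   0.2500000
10:      edm 0.6493056 0.6425000 0.6561111  0.16666667   0.1666667
11:      IFP 1.0000000 1.0000000 1.0000000  1.00000000   1.0000000
```

Each row is one pattern's cross-validated AUC (mean over repeats, with the
repeat-level 95% CI) and its sensitivity at 95%/85% specificity on pooled
out-of-fold scores; `IFP` is the stacked ensemble. On this deliberately
tiny cohort (12 vs 12, 3,000 fragments) the length-driven patterns
dominate — the simulated tumor fragments are shorter — and the stacked
IFP score is already perfect. At the default benchmark scale (60 vs 60,
30,000 fragments) every pattern clears chance and IFP reaches AUC ≈ 1.

A command-line front end with `simulate` / `features` / `train` / `too`
subcommands is installed at `inst/cli/cfpattern.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cfpattern.R",package="cfpattern"))')" \
    simulate --out cohort --seed 2 --healthy 10 --cancer 10 --fragments 5000
```

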