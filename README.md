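# barnyard

Benchmarking toolkit for two-species ("barnyard") single-cell RNA-seq
experiments.

## The problem

How well does a high-throughput scRNA-seq platform recover the cells you
load, keep its reads inside cell-containing partitions, detect transcripts
across expression levels, and support differential-expression calling? A
barnyard design answers all of this on one sample: a 1:1:1:1 mixture of
four lymphocyte cell lines from two species — mouse EL4 and IVA12, human
Jurkat and TALL-104 (a deliberately small, low-mRNA line). Since every
gene belongs to one species, barcodes with substantial counts from both
species unambiguously reveal cell multiplets, and bulk RNA-seq signatures
of the four lines give ground truth for classification and DE scoring.

This package implements the analysis stages of that benchmark for people
evaluating platforms or QC-ing mixed-species runs, together with a
synthetic generator with full per-barcode ground truth so every stage is
testable without sequencing data.

## The statistics at the core

* **UMI correction**: reads grouped by `<cid, gene, umi>`; a group at
  Hamming distance 1 from a strictly larger group is merged into it
  (deterministic tie/chain handling; reads conserved exactly).
* **Depth normalization**: Gaussian KDE (normal-reference bandwidth) on
  log10 per-cell totals; the first significant mode *d<sub>i</sub>* anchors
  scaling factors *s<sub>i</sub>* = min<sub>j</sub>(d<sub>j</sub>)/d<sub>i</sub>,
  applied by binomial thinning.
* **Cell calling**: on the log-log barcode-rank curve, a cubic smoothing
  spline (df = 20) yields the **knee** (argmin of signed curvature
  y''/(1+y'²)^(3/2)) and **inflection** (argmin of y'); capture efficiency =
  CIDs above the inflection / cells loaded.
* **Classification**: Pearson correlation of ln(count+1) with each bulk
  ln(FPKM+1) signature over a marker panel (FPKM > 50, ln fold difference
  > 3), assigned by mutually exclusive threshold rules.
* **Multiplet rate**: CIDs whose per-species totals both exceed the 10th
  percentile of the classified cells' distributions, divided by
  λ = 2·n<sub>h</sub>·n<sub>m</sub>/(n<sub>h</sub>+n<sub>m</sub>−n<sub>hm</sub>)².
* **Dropout / GD50**: per-gene dropout fraction vs bulk FPKM fitted as
  f(x) = a·exp(−b·x) by nonlinear least squares; GD50 = ln(2a)/b, the
  expression level detected in half of cells.
* **DE evaluation**: log2(count/total×10⁴+1) normalization, a two-part
  hurdle likelihood-ratio test (or Wilcoxon rank-sum), BH FDR < 1e-4,
  n = 199 cells × 10 repetitions, recall/precision against genes with a
  1.5-fold bulk difference.

## Worked example

```r
library(barnyard)
report <- run_benchmark(benchmark_config(seed = 7))
print(report)
#> Barnyard benchmark report
#>   CIDs: 12000 (2017 above inflection; capture 50.4%, pool 96.6%)
#>   adjusted multiplet rate: 4.44% (lambda 0.525)
#>   modal depth: 25541 counts/cell
#>   EL4      n=484   median nUMI 24587   median nGene 838    GD50 0.5
#>   IVA12    n=487   median nUMI 25709   median nGene 835    GD50 0.5
#>   Jurkat   n=466   median nUMI 25445   median nGene 806    GD50 0.6
#>   TALL104  n=467   median nUMI 5193    median nGene 560    GD50 2.3
#>   DE (hurdle, n=199 x 10 reps): mean nDE 609.7 [605.0, 614.4]; recall 1.000, precision 0.374
```

Reading the report: 12,000 barcodes were simulated (2,000 cell-containing,
10,000 ambient); 2,017 sit above the inflection point of the rank curve,
i.e. 50.4% of the 4,000 nominally loaded cells, holding 96.6% of all
counts. The cross-species multiplet estimate (4.44% after the λ
adjustment) tracks the generating 5% two-cell rate. The TALL-104-like
population shows its configured ~5× lower mRNA content (5,193 vs ~25,000
median UMIs) and correspondingly higher GD50 (lower detection
sensitivity). GD50 magnitudes and the DE recall/precision reflect the
desk-scale gene universe (1,000 genes per species) and should be compared
within a run, not with genome-wide values — see the methods vignette
(`vignettes/barnyard-methods.Rmd`).

Individual stages are plain functions, e.g.:

```r
gt  <- generate_ground_truth(seed = 1)
ds  <- simulate_cells(gt, sim_config(seed = 1))
rc  <- build_rank_curve(Matrix::colSums(ds$counts))
tp  <- knee_inflection(rc)
panel <- select_markers(ds$bulk)
asn <- classify_cells(ds$counts, ds$bulk, panel, classification_rules())
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's two parameter-recovery
benchmarks from scratch by running the installed package: (1) the
λ-adjusted cross-species multiplet rate on a fresh 5,000-cell synthetic
mixture generated at a 5% multiplet frequency, reported as a percentage,
and (2) the GD50 recovered by nonlinear least squares from detection
simulated under the exponential dropout model (3,000 genes × 300 cells,
generating GD50 13.6 FPKM). Run it as:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a `value` and problem size `n` per target.
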