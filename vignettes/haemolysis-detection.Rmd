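---
title: "Detecting haemolysis in plasma miRNA-seq with haemoQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting haemolysis in plasma miRNA-seq with haemoQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haemoQC)
```

## The problem

Circulating miRNAs in human plasma are attractive biomarkers, but red blood
cells are themselves dense miRNA repositories. When erythrocytes shear
during blood draw or handling (haemolysis), their miRNAs leak into the
plasma fraction and inflate the apparent abundance of a characteristic set
of transcripts, distorting both individual measurements and global library
normalisation. The wet-lab gold standards — the qPCR ΔCq(miR-23a-3p −
miR-451a) assay and free-haemoglobin absorbance at 414 nm — need the
physical specimen, which public sequencing data rarely comes with. haemoQC
provides the corresponding *in silico* check: a per-sample score computed
from the counts table alone.

## The haemolysis metric

Let $Z$ be the matrix of log2 counts-per-million after TMM normalisation,
$p_1$ the number of miRNAs in the *reduced signature set* (red-blood-cell
associated, after user exclusions) and $p_2$ the number of remaining
*background* miRNAs. For sample $i$ the metric is the difference of
geometric means taken over the log2-CPM values themselves:

$$
H_i \;=\; \Big(\prod_{x=1}^{p_1} Z_{xi}\Big)^{1/p_1}
      \;-\; \Big(\prod_{y=1}^{p_2} Z_{yi}\Big)^{1/p_2}.
$$

Samples with $H_i \ge 1.9$ are labelled **Caution** (the boundary is
closed on the Caution side), all others **Clear**. The threshold was
chosen by the method's authors for comparability with the ΔCq cutoff
of 7.

Two conventions for "geometric mean on the log scale" coexist in
practice: the formula above (geometric mean *of* the log2 values, the
printed definition, our default `geomean_log2`) and the arithmetic mean
of log2 values (equivalently the log of the linear-scale geometric mean,
our `mean_log2`). Both are implemented; `metric_mode` in `run_config()`
switches them, and reproduction sweeps report both.

## Pipeline and its order

`assess_haemolysis()` runs, in this fixed order:

1. **Depth QC** — samples with total miRNA reads strictly below 1,000,000
   are removed (a library of exactly one million is kept).
2. **Low-expression filter** — keep miRNAs with raw CPM ≥ `min_cpm`
   (default 1) in at least `min_samples` samples. Set `min_samples` to the
   smallest group of interest; `NULL` uses all retained samples, the most
   conservative choice.
3. **TMM normalisation** — doubly trimmed (M-trim 0.30, A-trim 0.05),
   inverse-variance-weighted trimmed mean of M-values against the sample
   whose 75th-percentile CPM is closest to the mean of those percentiles
   (ties broken to the lowest sample index). Factors are rescaled to
   geometric mean 1, making the metric invariant to global depth.
4. **log2-CPM** — prior-damped transform with prior count 2, the prior
   scaled by relative library size, on TMM-effective library sizes.
5. **Positivity guard** — see below.
6. **Partition and score** — signature ∩ retained features versus the
   rest; exclusions leave *both* sets; per-sample metric and label.

The order QC → filter → TMM → log2-CPM is a deliberate choice (the
upstream tool does not document its internal order): depth QC first so
that junk libraries cannot influence filtering or the TMM reference, and
filtering before TMM so factors are estimated on reliably observed
miRNAs.

A single-sample table skips TMM (undefined without a second library) with
factor 1 and a warning. A table declared pre-normalised is taken as
log2-scale expression directly and skips steps 1–4; we fix the accepted
normalised dialect to "already log2 scale" and document it rather than
guessing another tool's convention.

### Why a positivity guard

The geometric means in $H_i$ require every $Z_{xi} > 0$. The damped
log2-CPM of a zero count is roughly $\log_2\!\big(2\cdot 10^6/\bar{L}\big)$
with $\bar{L}$ the mean effective library size — positive for libraries
averaging below ~2M reads but slightly *negative* above that. Rather than
let deep studies fail or silently produce `NaN`, `assess_haemolysis()`
drops any miRNA with a non-positive value in *any* retained sample, from
both sets, before partitioning. The guard is uniform across samples (so
sample exchangeability is preserved), is reported in the log, and
typically removes only features sitting at the filter boundary.
`haemolysis_metric()` itself still refuses non-positive input.

## The default signature

The method rests on a 20-member signature of reliably abundant,
red-blood-cell-overrepresented miRNAs, designed with enough redundancy
that removing a few members does not compromise the score. The original
validated list is not redistributable here: the packaged default
(`default_signature()`) is a clearly labelled reconstruction — two members
anchored by published reproduction tables (hsa-miR-30c-5p,
hsa-miR-191-5p) and eighteen curated from the haemolysis-susceptibility
literature (miR-451a, miR-486-5p, miR-16-5p, miR-92a-3p and similar
erythrocyte-enriched mature miRNAs). Nothing runs without an explicitly
supplied signature; users holding the original list should load it with
`read_signature()`. Before scoring a case–control study, exclude signature
members known to be differentially expressed in the biology under study
(`exclusions` in `run_config()`): exclusions are removed from both the
signature and the background.

## The simulator

`simulate_study()` emulates plasma small-RNA libraries well enough to
exercise the pipeline with known ground truth:

- **Abundance**: baseline relative abundances are log-normal(0, 2) —
  heavy-tailed, spanning ~5 orders of magnitude, as real plasma miRNA
  profiles are. Signature members are drawn from log-normal(0.25, 0.8):
  reliably quantifiable (they must survive filtering, as the real set was
  designed to) but not dominant. These values were fixed once so that
  uncontaminated samples score a realistic mean metric near 0.7,
  comfortably below 1.9 — the defining property of clean plasma under
  this method — and are not tuning knobs.
- **Contamination**: haemolysis multiplies the signature members'
  relative abundance by a factor λ and renormalises, so contaminating
  reads displace background reads as mixing does. λ = 6 is the default
  "clearly haemolysed" condition; λ = 1 is the degenerate clean limit.
- **Counts**: negative binomial with dispersion 0.1 (typical RNA-seq
  overdispersion; 0 gives Poisson) around library-size × abundance.
- **Depth**: library sizes uniform on 0.8–5M reads, deliberately
  straddling the 1M QC boundary so the QC rule is exercised.

One global seed drives all draws sequentially, so a seed reproduces a
study bit for bit. The truth table records both the drawn target depth
and the realised column total; QC operates on realised totals.

What the simulator does *not* model: isomiR structure, sequence-level
effects, additive mixing of a measured erythrocyte profile (our
multiplicative inflation is a one-knob simplification of the same
mechanism), batch effects, or biological differential expression between
groups. Passing recovery tests on simulated data therefore shows the
pipeline correctly detects the *mechanism it models*, not that the
threshold 1.9 is optimal for any particular real cohort.

## Numerical choices

- Geometric means are computed in log space.
- TMM is delegated to edgeR's reference implementation; the test suite
  holds it to an independently coded brute-force oracle at 1e-10.
- The weighted TMM factor is *not* exactly invariant to rescaling one
  sample's counts (weights depend on absolute counts); the unweighted
  variant is, and the invariance test uses it.
- Results CSVs serialise metrics with 17 significant digits so re-reading
  reproduces them bit-exactly.
- Reference-sample ties in TMM and all other ties break deterministically
  (lowest index), so permuting samples permutes results exactly.

## Reproducing published public-data results

`reproduce_dataset()` encodes the four public GEO datasets used to
demonstrate the method (GSE153813, GSE105052, GSE151341, GSE118038) with
their published exclusion lists and Caution counts. Counts tables are not
downloaded automatically; supply the GEO file and the function sweeps both
metric modes and a small grid of filter settings (the original cutoffs
are unpublished), reporting agreement per setting rather than asserting
one. The test-suite reproduction runs only when these tables are placed
under `tests/testthat/geo/`.

## Known limitations

- The metric is a screen, not a quantification: it does not estimate a
  contamination fraction, and values near the threshold deserve manual
  review of the density plots.
- The packaged signature is a reconstruction (above); exact numerical
  agreement with results computed under the original list is not
  guaranteed, though the redundancy property makes the label robust to
  single-member differences.
- The reference barcode shipped for the histogram overlay is synthetic
  demonstration data, never a validated ΔCq cohort; ΔCq concordance in
  any real reference can be affected by cohort characteristics such as
  pregnancy status.

## Problem sizes used by the test suite

Simulated studies in the tests and acceptance script use 400 miRNAs and
10 + 10 samples, with 10–20 seeds per stochastic property — sizes chosen
to estimate the recovery rates stably while keeping the suite quick to
run routinely.
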