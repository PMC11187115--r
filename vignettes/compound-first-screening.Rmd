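---
title: "Methods: phenotypic bioactivity calling, calcium-transient metrics, and MS dereplication"
author: "npscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic bioactivity calling, calcium-transient metrics, and MS dereplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npscreen)
```

npscreen implements the downstream analysis stages of a compound-first
natural product screening campaign: a high-content (cell painting)
phenotypic bioactivity caller, a calcium-transient phenotyper for
iPSC-derived cardiomyocytes, mass-spectrometry dereplication arithmetic with
a self-contained molecular networker, and a microfractionation antibiotic
plate scorer. Seeded generators produce synthetic inputs with recorded
ground truth for every stage, so calibration and power can be studied
without imaging or LC-MS/MS data. This vignette documents the models, the
parameters that matter, and the design decisions behind them.

## Phenotypic profiles: signed KS statistics

Each well on a plate is summarized by one signed Kolmogorov–Smirnov
statistic per single-cell feature, comparing the well's cells with the
pooled DMSO control cells of the same plate. The magnitude is the sup-norm
distance between the two empirical distribution functions; the sign is read
off `ECDF(pool) − ECDF(well)` at the (first) point of maximal deviation, so
positive entries mean the treated cells shifted toward *larger* feature
values. This convention is a package choice — the direction is not
standardized in the field — and it is exactly antisymmetric under swapping
samples, including tie cases, because the deviation is evaluated on the
combined jump grid.

Decisions that matter here:

* **DMSO pooling is per plate** (one plate per cell line); cross-plate
  pooling is disabled to avoid batch effects.
* **DMSO wells are profiled leave-one-out**: a control well's own cells are
  excluded from its reference pool, so control profiles are not biased
  toward zero.
* **`min_cells = 50`**: wells with fewer usable cells are excluded and
  listed, never silently kept. Cells with any missing feature are dropped
  before profiling (the simplest defensible rule; counts are recorded).
* **Zero-variance features** in the DMSO pool are dropped and recorded.
* No per-plate feature normalization is applied before profiling: the KS
  statistic is rank-based and invariant to monotone transforms, so scaling
  would be a no-op.

For large pools the per-well statistic is computed from the well side only
in `O(n log m)` using pool rank counts; the test suite verifies exact
agreement with the brute-force evaluation.

## Bioactivity: Mahalanobis distance against a kernel-smoothed empirical null

Profiles have far more features than there are DMSO wells, so a full-rank
profile covariance is singular. The package therefore computes the
Mahalanobis metric in a reduced space: the leading
`k = min(n_dmso − 1, 20)` principal axes of the DMSO profiles, with the
projected covariance shrunk toward its diagonal,
$\hat\Sigma = (1-\lambda)S + \lambda\,\mathrm{diag}(S)$, with
$\lambda = 0.1$ by default. This preserves the metric while keeping it
well-posed; at full rank with $\lambda = 0$ the distances are invariant
under any invertible linear transform of the profiles (tested).

The null distribution is empirical: Gaussian kernels centered on the
DMSO–DMSO distances (Silverman's rule-of-thumb bandwidth by default,
configurable), with the one-sided p-value
$p(d) = \tfrac1n \sum_i \Phi((d_i - d)/h)$ and the 99th percentile `q99`
solved by bisection on the kernel CDF. Two details deserve emphasis:

* **Leave-one-out null distances.** A DMSO profile's distance is computed
  against a reference space refit *without* that profile. In-sample
  distances are deflated by the fit (the effect grows with `k / n_dmso`),
  which would make every test compound look too extreme; with the
  leave-one-out refit, null and test distances are exchangeable and the
  observed fraction of inactive wells beyond `q99` lands at the nominal 1%.
* **Kernel smoothing inflates the extreme tail slightly**, so `q99` sits a
  little above the empirical 99th percentile and the realized exceedance of
  fresh null draws is marginally below 1%. This is inherent to kernel
  nulls, not a defect; the calibration test allows for it.

A compound × line call aggregates replicate wells by the **median**
distance (robust to one bad well) and reports *both* stated criteria:
`p ≤ 1e-6` (the headline call) and `d ≥ 2·q99`. Under a kernel null the
two are not mathematically equivalent, so neither is silently preferred —
both flags are always emitted, with inclusive boundaries. The significance
transform is `-log10(p)`.

Reference-class prediction is nearest-class by cosine similarity of
profiles, with a confidence score equal to the similarity margin between
the best and runner-up class clamped to [0, 1] and a unique-profile flag at
the configurable 0.1 threshold. The exact confidence formula used in prior
cell-painting work is not public; this margin construction is the package's
documented reconstruction.

### Calibration study design

The calibration experiment simulated by the acceptance checks uses 2048
DMSO wells, 1000 inactive compounds in triplicate, 200 cells per well, and
40 features. The compound count and nominal rates are fixed by the design
being emulated; the DMSO well count is deliberately large because `q99`
must be estimated accurately for a ±0.5 percentage-point calibration band
to be meaningful — with a handful of control wells the quantile-estimation
error (both its sampling noise and the kernel-smoothing inflation, which
scale as the bandwidth does with `n^{-1/5}`) would dominate the quantity
being measured. Exchangeability is assessed on *well*
distances (1% should exceed `q99`), while the false-call count at
`p ≤ 1e-6` is assessed on *compound-level* (median-aggregated) calls — the
two operate at the levels where each criterion is applied in practice.
The power study (nine cell lines, six active, effect size 2 SD on 10% of
100 features, 500 cells/well, triplicate, 16 DMSO wells per plate) recovers
exactly the active lines at `p ≤ 1e-6`.

## Calcium transients

Traces (default 20 s at 30 Hz) are baseline-corrected with an iterative
clipped polynomial fit (degree 2, up to 100 passes): fit, clip the working
signal to the fit wherever it exceeds it, refit. Positive-going transients
are clipped away, so the polynomial settles under the beats. The analysis
window defaults to frames 200–600 (about 13 s), clamped to the trace.

Peaks are local maxima with topographic prominence at least five times a
robust noise scale, at least 0.2 s apart (the larger peak wins; 0.2 s
corresponds to a maximal plausible ~5 Hz beat rate). The noise scale is the
MAD of the trace's first differences divided by √2 rather than the MAD of
the trace itself: once beats occupy much of a recording the trace MAD is
signal-dominated and a threshold tied to it misses every beat, whereas the
differenced MAD stays pinned to the noise. Candidates are located on a
3-point moving average so single noise samples cannot clear the prominence
bar; the reported index and amplitude come from the unsmoothed trace.

Beating frequency uses the inter-peak span, `(n_peaks − 1) / (t_last −
t_first)`, which avoids the edge bias of dividing by the window length
(the alternative is a one-line change); it is defined as 0 with fewer than
two peaks. Amplitude is the mean baseline-corrected height at the detected
peaks, measured on the corrected (not raw) signal.

The generator's transient kernel is a difference of exponentials (50 ms
rise, 400 ms decay) on top of polynomial drift and Gaussian noise (default
0.02 a.u. — genetically encoded calcium indicators are high-SNR). At 2 Hz
the 400 ms decay makes consecutive transients summate, so the requested
amplitude is *not observable* in the trace: the realized peak-over-onset
height of the clean kernel sum is about 10% lower. The ground truth
therefore records both `amplitude_nominal` (requested) and `amplitude`
(realized, on the sampling grid); recovery is judged against the realized
value, which is what any trace-based analysis can measure. Frequency and
amplitude are both recovered within 5% across 0.5–2 Hz and 1–5 a.u.

## Dereplication arithmetic and molecular networking

Monoisotopic masses use a pinned lightest-isotope table (H 1.007825032,
C 12 exactly, N 14.003074005, O 15.994914620, S 31.972071174,
P 30.973761998, Na 22.989769282, Cl 34.968852682, Br 78.918337601 Da;
electron 0.000548579909 Da). Adduct m/z values are electron-corrected, so
`[M+H]+` adds 1.007276 Da. Published "calcd" values from other software can
differ in the fourth decimal; agreement is asserted within 0.001 Da.
Degrees of unsaturation use the standard CHNOPS+halogen valence classes.
Neutral-loss annotation defaults to a 10 mDa absolute tolerance — wide
enough to cover sulfate-loss attributions that sit several mDa off the
calculated 79.9568 Da.

Isotope patterns are built by per-element polynomial convolution and
aggregated at unit (nominal-mass) resolution — the level at which
halogen clusters are read off a survey scan; fine structure is out of
scope. Halogen inference fits theoretical Cl$_n$Br$_m$ cluster shapes to
the even-offset envelope by least squares, with both sides renormalized to
sum to one (robust to the base peak moving to M+2 in heavily halogenated
species) and ties broken toward fewer halogens. On noiseless theoretical
patterns the inference is exact over the (0..2)² grid against 50 random
C₁₀–C₄₀ backbones.

Networking follows classical molecular networking: fragment ions within
±17 Da of the precursor are removed, each peak must rank in the top 6 by
intensity within its ±50 Da window, and pairs are scored with the modified
cosine (√-intensity weighting, 0.05 Da fragment tolerance, precursor-shift
matching). Edges require cosine ≥ 0.7 and ≥ 4 matched fragments ("more
than three"); molecular families are capped at 100 nodes by repeatedly
deleting the lowest-scoring edge inside an oversized component. Spectra
whose precursors differ by no more than the 0.02 Da precursor tolerance are
compared without the shift.

One deliberate algorithmic choice: the peak assignment inside the modified
cosine is an **exact maximum-weight bipartite matching** (Hungarian, via
igraph) rather than the greedy intensity-descending pass common in
networking tools. Greedy matching can under-count shared intensity whenever
a peak has two in-tolerance partners (one direct, one precursor-shifted),
and filtered spectra are small enough that exactness is essentially free;
conflict-free candidate sets — the overwhelmingly common case — bypass the
matching entirely. The test suite checks the score against an independent
exhaustive-assignment oracle on a thousand random small spectra.

## Microfractionation bioassay

Fractions collected every 15 s from 1.8 min over a 20 min run give 80
half-open retention-time intervals. Growth inhibition is
`100 × (1 − ΔOD_well / ΔOD_control)` with ΔOD the optical-density increase
over incubation, clamped to [0, 100] (evaporation and reader noise can push
raw values outside). ΔOD rather than final OD is used because turbidity is
read both before and after incubation. Plates are only scored after control
QC: positive controls must show ≥ 90% inhibition and negative controls
≤ 10%, otherwise the plate aborts with a diagnostic. Active fractions
(≥ 80% inhibition by default — heatmaps in this assay family are colored
without a printed cutoff, so the threshold is explicit and configurable)
are merged into maximal retention-time windows with their peak fraction.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* each stage consumes:
per-well multivariate feature distributions with line-specific means and
optional equicorrelation (independent unit-variance features by default —
no published feature covariance exists to copy); truncated-Poisson cell
counts (≥ 10, so ECDFs stay meaningful); periodic transients with drift and
noise; spectra with family-shared fragments, isotope clusters, and SO₃
companion ions; OD growth with inhibition windows. They do **not** emulate
image formation, segmentation errors, heavy-tailed or correlated feature
noise, plate-edge effects, chromatographic peak shapes, or instrument
dialects — so passing tests demonstrate that the *pipeline arithmetic* is
correct and calibrated under its stated assumptions, not that real-data
idiosyncrasies are handled. Every generator takes one seed from which all
of its randomness flows, and equal seeds give identical outputs.

The number of DMSO wells per plate in a real campaign is not fixed by any
protocol we emulate; the generator default of 16 is a free parameter.

## Problem sizes and interfaces

The bundled studies use deliberately compact sizes (40–100 features,
150–500 cells per well, 20-second traces) chosen so the full statistical
behavior — calibration, power, recovery — is measurable in minutes on a
laptop; all sizes scale up through the same configuration objects.

All tabular artifacts are comma-separated text with headers; spectra use
MGF. `run_config()` collects every stage threshold (round-tripping
losslessly through a flat key=value file), and `run_screen_pipeline()`
chains simulate → profile → call. The package's interface is its functions
plus the reproduction script `scripts/acceptance.R`; no shell subcommand
wrapper is shipped, as an R analysis package's natural entry points are its
exported functions.

```{r example, eval = FALSE}
cfg <- screen_config(n_cell_lines = 9, n_dmso_wells = 16,
                     cells_per_well_mean = 500, n_features = 100,
                     affected_feature_fraction = 0.1, effect_size_delta = 2,
                     active_lines = c(1, 3, 4, 6, 8, 9), seed = 42)
res <- run_screen_pipeline(cfg)
res$calls[res$calls$bioactive_by_p, c("line", "distance", "neg_log10_p")]
```

## Known limitations

* The reduced-space rank `k` caps at `n_dmso − 1`; with very few control
  wells the null is coarse and `q99` noisy — the pipeline runs but
  calibration claims weaken.
* The kernel null's extreme tail is an extrapolation of, at best,
  `n_dmso` points; `p ≤ 1e-6` calls lean on the Gaussian kernel's tail
  shape.
* Isotope patterns at unit resolution cannot separate isobaric
  contributions (e.g. ³⁴S vs two ¹³C).
* The family-cap pruning is greedy (globally lowest edge first) and is one
  of several defensible cap semantics.
* Single-point AUC quantitation assumes linearity through the origin and
  matched chromatographic conditions.
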