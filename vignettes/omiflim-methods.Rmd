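---
title: "Methods: single-cell optical metabolic imaging from FLIM decays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell optical metabolic imaging from FLIM decays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`omiflim` implements a label-free optical metabolic imaging (OMI) analysis
chain for immune cells measured by fluorescence lifetime imaging microscopy
(FLIM) with time-correlated single photon counting (TCSPC). The chain has
four stages, each usable on its own:

1. **Synthetic data** — ground-truthed decay cubes and feature cohorts
   (`build_scene()`, `sample_feature_table()`);
2. **Decay fitting** — spatial binning, background thresholding, and
   biexponential fitting with instrument-response (IRF) reconvolution by
   Poisson maximum likelihood (`bin_pixels()`, `threshold_background()`,
   `fit_biexponential()`, `fit_image()`);
3. **Cell features** — per-cell aggregation of the 10 OMI variables with
   quality control (`extract_features()`, `apply_qc()`, `gate_cd56()`,
   `gate_cd69()`);
4. **Statistics and classification** — Cohen's d effect sizes, COV
   heterogeneity, Ward clustering, and balanced one-vs-rest random forests
   (`cohens_d()`, `heterogeneity_table()`, `ward_cluster()`,
   `run_classification()`).

The numbered scripts under `analysis/` run the full workflow and write
tables under `results/`.

# The decay model

At each pixel the TCSPC histogram records photon counts per arrival-time
bin. The expected signal is a two-component exponential decay observed
through the instrument response and a constant background:

$$ I(t) \;=\; \alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2} + C, $$

with short (quenched, free-cofactor) and long (unquenched, protein-bound)
lifetimes $\tau_1 \le \tau_2$. The amplitude-weighted mean lifetime is

$$ \tau_m = \frac{\alpha_1\tau_1 + \alpha_2\tau_2}{\alpha_1 + \alpha_2}, $$

and reported amplitude fractions are normalised,
$\alpha_i / (\alpha_1+\alpha_2)$, as percentages summing to exactly 100.

**Time axis.** 256 bins across 12.5 ns (bin width 48.828125 ps), the
repetition window of an 80 MHz pulsed laser. The bin count is a common
TCSPC configuration, not a universal constant, and is configurable
(`make_irf(n_bins =, bin_width_ps =)`).

**Periodicity.** Because $\tau_2 \approx 2.5$ ns is not negligible against
the 12.5 ns window, decay tails wrap into the next pulse period. Both the
simulator and the fitter therefore treat all convolutions as *circular*
over the window; on the discrete periodic axis the wrapped exponential,
normalised to unit sum, is simply $e^{-t/\tau}/\sum_k e^{-t_k/\tau}$.

**Amplitude convention.** Component curves are normalised to unit area
before scaling, so an amplitude is the *expected photon count* of its
component and the generator's `alpha1_frac` is a photon fraction. Two
consequences worth stating plainly:

* $\tau_m$ computed from these amplitudes equals the background-free mean
  photon arrival time — which is what makes the mean-arrival-time checks in
  the test suite exact;
* the conventional "amplitude at $t=0$" fraction of FLIM software is a
  different normalisation. An amplitude fraction of 70–80% for the free
  component corresponds to a photon fraction near 0.35–0.50, because the
  long component integrates more photons per unit amplitude. The default
  cell-type profiles are therefore parameterised with $\alpha_1$ photon
  fractions around 38–47% and photon-weighted $\tau_m$ near 1.3–1.6 ns.
  This is also the statistically comfortable regime: both components carry
  enough photons to be identifiable at the 2,500-photon floor.

# Fitting

`fit_biexponential()` maximises the Poisson log-likelihood of the observed
counts under the reconvolution model (equivalently, minimises the Poisson
deviance), using L-BFGS-B with analytic gradients over
$(\tau_1, \tau_2, A_1, A_2, C)$, amplitudes and background bounded below at
zero and lifetimes restricted to [20, 6000] ps by default. The 6 ns ceiling
reflects that within a 12.5 ns periodic window a much longer component is
nearly flat and degenerates with the constant background.

* **Initialisation** is method-of-moments: $\tau_m$ from the
  background-corrected mean arrival time (IRF centroid subtracted),
  components at $0.4\times$ and $2.5\times$ that value, $\alpha_1 = 0.7$,
  $C$ from the last 5% of bins. Non-convergence triggers up to three
  restarts from a *fixed* perturbation schedule, so identical inputs always
  give bit-identical fits.
* **Ordering** $\tau_1 \le \tau_2$ is enforced by post-hoc sorting with the
  amplitudes permuted, keeping the objective smooth.
* **Goodness of fit** is the Pearson reduced chi-square over bins with
  expected counts of at least 5, divided by (bins used − 5). The commercial
  software this mirrors does not publish its exact statistic, so the
  conventional 1.3 quality cutoff should be treated as approximately
  transferable, not exact.
* At any optimum with free amplitude and background, total modelled counts
  equal total observed counts (a stationarity property of the Poisson
  likelihood); the tests assert this to 10⁻⁴ relative.

`fit_image()` composes binning, thresholding and per-pixel fitting.
Spatial binning follows the FLIM "bin factor" convention: a sliding
(2b+1)×(2b+1) kernel *sum* that preserves the image grid (factor 2 → 25
pixels for NAD(P)H; factor 3 → 49 pixels for FAD), with zero padding at the
edges. The photon floor (default 2,500 after binning, boundary inclusive)
is applied before fitting; acquisition software does not publish its
exact "low-intensity background" threshold, so the floor itself is the
default.

# Per-cell features and quality control

Cell masks are ingested as integer label images (segmentation itself is out
of scope). For each cell:

* lifetime variables are unweighted means over *valid* fitted pixels in the
  mask (the record keeps the valid-pixel fraction);
* the optical redox ratio is computed at the cell level from summed raw
  intensities, $ORR = \sum I_{NAD(P)H} / (\sum I_{NAD(P)H} + \sum I_{FAD})$,
  which bounds it in [0, 1] and equals the intensity-weighted mean of
  per-pixel ratios;
* `mean_nadph_intensity` is total NAD(P)H photons divided by area, in
  arbitrary units with a configurable scale (intensity units do not
  transfer across instruments);
* the chi-square aggregate is recorded twice: `chi2_max` (pixel maximum,
  conservative) and `chi2_mean`. The per-cell exclusion rule in the source
  protocol does not define the aggregation; `apply_qc()` defaults to the
  maximum but accepts `chi2_col = "chi2_mean"`. On binned synthetic scenes
  the maximum is dominated by edge pixels whose kernels mix cell and
  background photons — a genuine model mismatch that inflates the pixel
  maximum even when every interior fit is good — so the whole-image
  workflow in `analysis/` gates on the mean.

The four exclusion rules use strict inequalities with boundary values
retained, exactly as stated in the protocol: mean NAD(P)H intensity < 10
a.u.; area < 70 px; chi-square > 1.3; NAD(P)H $\tau_1$ < 350 ps. QC is
idempotent and every exclusion carries reason codes.

Gating: CD69⁺ is intensity > quiescent mean + 1.5 SD (sample SD, n−1
denominator — the convention used everywhere SD appears in this package);
CD56 bright is intensity > 100 a.u., a threshold calibrated so the
synthetic NK stain distribution (lognormal, meanlog log 55, sdlog 0.47)
puts roughly 10% of NK cells above it.

# Statistics

**Cohen's d** is $d = (M_1 - M_2)/\sqrt{(SD_1^2 + SD_2^2)/2}$. The source
text renders the denominator ambiguously; the equal-weight root-mean-square
of the two group SDs is the standard form of the cited definition and is
what this package computes. Categories: $|d| < 0.2$ none, $0.2 \le |d| <
0.5$ small, $0.5 \le |d| < 0.8$ medium, $\ge 0.8$ large, with boundaries
falling upward. For activation contrasts, group 1 is the activated
population, so the sign of $d$ is the direction of change with activation.
Effect sizes are preferred to p-values throughout because single-cell n is
large; a 100-cell minimum per group is enforced as a warning.
`activation_effect_sizes()` stratifies per (cell type, donor) by default
with a pooled option, since the source figure caption does not resolve
which was used.

**Heterogeneity** is the coefficient of variation SD/mean per
(cell type, condition, variable), undefined (flagged) for non-positive
means.

**Clustering** z-scores each variable over all included cells, then applies
Ward's minimum-variance linkage on Euclidean distances via the
Lance–Williams recurrence (`stats::hclust(method = "ward.D2")`), verified
in the tests against direct enumeration of the Ward criterion on
three-point instances. Annotations (condition, donor, cell type) are
carried alongside and never enter the distances; the first split (k = 2) is
reported. UMAP embeddings are deliberately not implemented; the parameters
a practitioner would use (Euclidean metric, 6 neighbours, minimum distance
0.6) are recorded here for use with an external embedding library, and
nothing downstream depends on them.

# Classification

The protocol is: undersample every class to the minority count (so
misclassification is penalised equally across classes), split 70/30 at
random, train a random forest on the 10 OMI variables, and report per-class
ROC/AUC (trapezoidal, threshold sweep over unique scores; tied scores
collapse to single ROC vertices), accuracy, precision/recall, confusion
matrices in counts and row percentages, and normalised feature importances.

Choices the source does not pin down, and what this package does:

* **Balance before or after the split?** Balancing precedes the split, so
  test sets are balanced too and accuracy is comparable across classes.
  Both orders are reachable through the API (`balance_classes()` /
  `split_train_test()` compose either way).
* **Forest hyperparameters** are unstated; defaults are 500 trees,
  unlimited depth, $\sqrt{p}$ features per split, fixed seed — the
  `randomForest` defaults, documented in `classifier_config()`.
* **One-vs-rest realisation**: a single multi-class forest whose per-class
  vote fractions are the one-vs-rest scores (default), or literal per-class
  binary forests (`mode = "per_class"`) when per-class importances are
  wanted.
* Repeated random splits (`reruns`) report mean ± SD of each metric.

# The synthetic generator

`build_scene()` emulates: per-pixel photon arrival histograms for two
spectral channels, generated from per-cell biexponential emitters convolved
with a Gaussian IRF (220 ps FWHM by default, standing in for the
second-harmonic response of a urea crystal) and Poisson-sampled; elliptical
non-overlapping cell footprints (axis-aligned, jittered eccentricity —
shape realism is not load-bearing); and a flat Poisson background. One RNG
sub-stream per (seed, channel, cell) makes scenes reproducible and
partially regenerable. `sample_feature_table()` bypasses the imaging
physics and draws the 10 OMI variables directly, for fast statistical
tests.

Cell-type profiles give each quantity as (mean, CV) with normal per-cell
draws clamped to physical ranges. $\tau_2$ is derived per cell from
$(\tau_1, \tau_m, \alpha_1)$ — capped at 3.5 ns, the physiological ceiling
for protein-bound cofactor lifetimes — which guarantees
$\tau_1 \le \tau_m \le \tau_2$ row-wise. The per-cell FAD photon budget is
derived from the drawn ORR so the expected cell-level redox ratio equals
the draw.

The default PBMC profiles encode the qualitative structure of the measured
contrasts: monocytes with low NAD(P)H $\tau_m$, high $\alpha_1$ and large
area; B cells with slightly elevated $\alpha_1$; NK cells distinct in ORR
and FAD $\tau_1$; and with activation, lymphocyte $\tau_m$ down /
$\alpha_1$ up, monocyte $\tau_m$ up / $\alpha_1$ down, ORR up and NAD(P)H
$\tau_1$ down for every type, with mildly widened dispersions. Photon
budgets (~170 photons/pixel NAD(P)H) keep binned decays comfortably above
the 2,500-photon floor, as a practitioner maintaining count rates would.
Abundances follow the relative per-type cell counts of a typical PBMC
imaging cohort.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: optical blur and detector artefacts
(afterpulsing, pile-up); intra-cell lifetime texture (each cell is a single
emitter); irregular cell shapes and touching cells; donor-level batch
structure (donor labels are assigned round-robin, not drawn from donor
effects); any coupling between surface-stain intensity and metabolism (the
synthetic CD56 stain is independent of the lifetime draws, so bright/dim
metabolic contrasts are near zero by construction); and the true joint
distribution of the 10 variables, which is modelled as independent draws
within a type.

# Numerical choices and degenerate inputs

* All thresholds: photon floor passes at ≥; QC excludes on strict
  inequality, as printed in the protocol.
* `make_irf()` with sub-bin FWHM returns an exact delta; a pulse centre
  outside the window is a configuration error.
* All-zero decays are an error; per-pixel fit failures inside
  `fit_image()` invalidate the pixel and are counted, never fatal.
* A cell whose mask contains no valid fitted pixel in *either* channel is
  emitted with `qc_pass = FALSE` (reason `no-valid-pixels`) rather than
  dropped.
* Zero-variance quiescent populations make the CD69 gate equal the mean,
  with a warning. Zero-variance feature columns are dropped from z-scoring
  with a warning. Ties in Ward merges are broken deterministically by
  `hclust`'s pair ordering.
* Problem sizes used by the test suite and acceptance script — 500 decays
  per photon budget for recovery, 20 decays against a ~10⁵-point
  brute-force grid, a 100-cell two-type scene for the end-to-end check,
  cohorts of ~4,000 cells for the statistical procedures — were chosen as
  the smallest sizes at which the Monte-Carlo statistics are stable.

# Known limitations

* The Poisson-MLE fitter estimates photon-fraction amplitudes; comparing
  its $\alpha$ values against amplitude-normalised software requires the
  $\alpha_i \propto A_i/\tau_i$ conversion.
* At photon-fraction $\alpha_1 \gtrsim 0.8$ with long $\tau_2$, the long
  component carries too few photons to be well identified within a 12.5 ns
  window and $\tau_m$ estimates inflate; the default profiles avoid this
  regime (it is also physiologically implausible), but user-supplied
  profiles are not guarded.
* The 1.3 chi-square cutoff presumes a reduced Pearson statistic; other
  fitting software may scale its statistic differently.
* Classification metrics on synthetic cohorts reflect the configured
  contrasts, not instrument reality; they demonstrate that the *procedures*
  recover what was put in, nothing more.
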