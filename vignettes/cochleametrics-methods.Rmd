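---
title: "Models, phantoms and numerical choices in cochleametrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, phantoms and numerical choices in cochleametrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleametrics)
```

cochleametrics implements the quantitative machinery used to study
metabolic (lateral-wall) hearing loss: calcium-proxy FCS in the tectorial
membrane, TM/organ-of-Corti morphometry, stereocilia kinematics from
phase-stamped confocal sequences, evoked-potential analysis, and the
group statistics. This vignette explains the models, the assumptions
behind them, the synthetic-data generators that stand in for animal and
human recordings, and the numerical decisions that were genuinely open.

## FCS: model and assumptions

A confocal detection volume is modelled as a 3-D Gaussian with lateral
1/e² radius $w$ and axial elongation $S$ (axial radius $S\,w$). For
molecules whose displacements are Gaussian with per-axis mean-squared
displacement $2 D t^\alpha$, the fluctuation autocorrelation is

$$G(t) = \frac{1}{N}\,\frac{1}{1+(t/\tau_D)^\alpha}\,
  \frac{1}{\sqrt{1+(1/S^2)(t/\tau_D)^\alpha}},\qquad
  \tau_D^\alpha = \frac{w^2}{4D},$$

with $N$ the mean number of molecules in the effective volume
$V_{\mathrm{eff}} = \pi^{3/2} w^3 S$. The anomalous exponent
$\alpha \in (0,1]$ captures hindered diffusion in the tectorial-membrane
gel; $\alpha = 1$ is free diffusion. An optional factor
$1 + \frac{T}{1-T} e^{-t/\tau_T}$ models triplet-state shelving.
Molecular brightness is defined operationally as the background-corrected
mean count rate divided by $N$; for a Gaussian profile this equals the
beam-centre emission rate times $2^{-3/2}$, and the simulator records this
*apparent* brightness as the ground truth that the estimator should
recover.

Assumptions worth stating: Poisson photon emission (no bleaching or
saturation), a scalar pre-injection background with no drift, and a
detection profile known up to $(w, S)$. No instrument calibration for
$(w, S)$ is available, so defaults ($w = 0.25$ µm, $S = 5$, typical for a
high-NA confocal) are declared, not inferred; `S` is fixed during fitting
because fitting $S$ jointly with $\alpha$ is ill-conditioned. The triplet
term is included only when it improves AIC by at least 4 *and* the fitted
$\tau_T < \tau_D/10$; on noiseless curves whose plain-model residuals are
at numerical zero the comparison is skipped, since AIC differences there
are floating-point artefacts.

### Correlator

`autocorrelate()` evaluates the exact estimator
$\hat G(k) = \frac{1}{(n-k)\bar F^2}\sum_i \delta F_i\,\delta F_{i+k}$
either at every lag (`direct`) or on a multi-tau grid — 16 linear lags per
octave with the spacing doubling each octave, smallest lag one bin — the
standard way to span the several decades a 10-s trace supports. Both
schemes share the same per-lag sums, so they agree to machine precision at
shared lags; the test suite checks them against an independent plain-R
implementation.

Because the mean is estimated from the same finite trace, the estimator
sits a constant $\approx 2\sum_k G(k)/n$ *below* the true curve. The
offset is invisible at the plateau but dominates the tail, and with
$\alpha$ bounded above by 1 it asymmetrically drags $\tau_D$ down.
`fit_anomalous_diffusion()` therefore fits a free additive baseline
$G_\infty$ by default, the same device most FCS software uses.

### Uncertainty

Residuals of a correlation fit are strongly correlated across lags, so
the naive least-squares covariance is far too optimistic. Two remedies are
provided: a single-curve AR(1) effective-sample-size inflation of the
covariance (honest to within a factor), and — preferred —
`fit_fcs_repetitions()`, which mirrors the experimental design (10-s
recordings repeated 6–8 times per location), averages the per-repetition
curves with inverse-variance weights, and derives jackknife
(leave-one-repetition-out) standard errors. In simulations at the default
conditions ($N_{\mathrm{eff}} = 5$, 6 × 10 s, 1-ms bins,
$D = 1\ \mu m^2/s$) the jackknife 95% intervals cover the generating $N$
and $\tau_D$ in well over 80% of experiments, and the median relative
errors of $\hat N$ and $\hat\tau_D$ stay below 15%.

### Photon-trace simulator

Molecules move in a periodic box, Brownian paths by direct increment
sampling (compiled), anomalous paths as fractional Brownian motion with
Hurst index $\alpha/2$ synthesised by circulant embedding (Davies–Harte)
of the fractional-Gaussian-noise covariance, with a Cholesky fallback for
short series. The box is 10 beam waists wide laterally — wide enough that
lateral truncation is negligible — and is elongated axially to six axial
radii: with a cubic box the axial Gaussian tail touches the periodic
boundary and measurably suppresses the slow part of the correlation
(early development showed a ~15% downward bias in $\tau_D$ until the box
was elongated). Per-bin counts are Poisson draws around the summed
intensity plus background. Default rates put the simulated recordings at
~100 kHz total count rate, the working level for indicator recordings in
scala media.

## Morphometry

Areas follow the pixel-count rule (pixels whose centres fall inside the
ROI, times the squared pixel size) — matching how ROI areas are measured
on section images; the continuous shoelace area serves only as a test
oracle. The TM–organ gap is the minimum Euclidean distance between the TM
polygon boundary (all edges, not only vertices) and the surface polyline;
intersection yields 0 rather than a negative penetration depth, and for
human sections without an explicit lamina trace the upper boundary of the
OoC ROI is used as the surface. Coordinates are 0-based pixel indices
(x = column, y = row) with distances computed in continuous coordinates.
The detachment flag defaults to "any measurable gap" (threshold 0 µm),
the convention under which control cohorts show no detachment. The two
apical locations of each cochlea are averaged before statistics.

The section phantom builds both structures as rectangles whose corners
lie on half-integer pixel boundaries, so the configured areas, width and
gap are exact by construction, and the measured values must agree within
one pixel-equivalent.

## Kinematics

Phase binning assigns every pixel sample to one of $n$ half-open phase
bins $[2\pi b/n, 2\pi(b+1)/n)$ (default 16) and averages per pixel; an
empty pixel/bin combination is an error naming the pixel, never silently
interpolated. Frames are smoothed with a spatial Gaussian (σ = 1 px
default; the acquisition literature gives no filter parameters).

Per-pixel motion is estimated by iterative Lucas–Kanade gradient flow
against the cycle-mean image: 5 × 5 windowed normal equations, bilinear
warping between iterations (5 by default), displacement clamped per
iteration to keep the linearisation valid, and the per-pixel cycle mean
removed so trajectories are relative to rest. The wavelet optical-flow
estimator used with the original acquisition system lives in proprietary
tooling; this implementation is a documented equivalent validated against
programmed-motion phantoms (a 0.3 px global shift is recovered within
0.05 px). Structure-tensor degeneracy (texture-free regions) is flagged
as low confidence rather than reported as motion.

Deflection is the bin-wise tip-minus-base vector difference after
5 × 5-region averaging; its amplitude is the maximal distance from the
cycle mean. Normalised deflection divides by the base amplitude by
default — the axis convention for normalised-deflection summaries is not
standardised, so the choice is recorded in the output. The declared
measurement floor is 30 nm, matching the pixel-size choice of the
original recordings. The motion phantom translates an analytic
Gaussian-blob texture by a spatially blended field (Gaussian influence
regions around base and tip anchors); symmetric cross-talk between the
regions scales the tip–base difference without rotating it, which keeps
the programmed deflection honest. At the default noise level the
recovered deflection stays within max(30 nm, 15%) of the programmed value
across seeds.

## Evoked potentials

Filtering is a 4th-order Butterworth band-pass applied forward–backward,
so the cochlear-microphonic phase is never biased by the filter; the
300–3000 Hz passband is the conventional evoked-response band. All
Fourier quantities are computed on windows trimmed to whole stimulus
cycles with a rectangular window; the summating potential is the
whole-cycle mean minus the pre-stimulus baseline and can be positive or
negative, so group comparisons use absolute values. Phase analyses
exclude responses below 10 µV peak. DPOAE extraction requires the
standard primary ratio $f_2/f_1 = 1.2$ and a window long enough to
resolve the $2f_1-f_2$ component; a cubic nonlinearity $x + \varepsilon
x^3$ produces the textbook $\tfrac{3}{4}\varepsilon a_1^2 a_2$ component,
which the tests verify exactly.

No criterion for audiometric threshold is stated with the recordings this
package targets, so `io_function_and_threshold()` takes the criterion as
an argument (recommended: 3× the pre-stimulus noise SD of the averaged
trace) and interpolates linearly between the bracketing stimulus levels;
raising the criterion can never lower the threshold. Brainstem-response
latency is reported as the largest-peak latency after onset — a declared
convention, not wave labelling.

## Statistics

The brightness model is Gaussian generalised least squares with
compound-symmetric within-animal correlation (equal correlation between
any two sites of one preparation), estimated by maximum likelihood via
`nlme::gls`; "generalised linear model with a symmetrical correlation
structure" in the physiology literature denotes exactly this
construction. Wald 95% intervals are reported; REML is available. The
test suite cross-checks the implementation against an independent
profiled-likelihood optimiser and the OLS limit at ρ = 0, and verifies
nominal behaviour where it matters: the dose-coefficient type-I error
stays within [0.03, 0.07] at nominal 0.05 over 1000 null simulations of
the study-shaped design (4 sites × 25 animals per group, ρ = 0.5).

Group comparisons use one-way ANOVA with Tukey–Kramer intervals (the
unequal-n studentized-range form throughout, since group sizes differ),
rank-sum tests reported Matlab-style (rank sum of the first sample plus
the tie-corrected normal Z), Kruskal–Wallis for more than two groups, and
OLS with added-variable diagnostics for the human threshold model. All
tests are two-sided with no multiplicity correction beyond Tukey–Kramer.
The dose coding for the GLS simulations is 0/1/2 for control/low/high
dose — the dose "unit" is not defined by the source analyses, so
simulations expose it as a free parameter.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* the estimators rely
on: Poisson photon statistics over anomalously diffusing emitters,
rasterised geometry with exact ground truth, textured scenes translating
along programmed trajectories with phase-stamped sampling, tone responses
with AC + DC components, and compound-symmetric grouped tables. They do
not emulate photobleaching, detector afterpulsing, optical aberrations,
tissue autofluorescence, histological distortion, nonlinear cochlear
mechanics, or non-Gaussian electrode noise. Passing tests therefore
demonstrate correctness of the estimators under their stated models, not
robustness to every artefact of real recordings.

## Problem sizes and reproducibility

Simulation sizes were chosen so the full validation remains desk-scale:
50 six-repetition FCS experiments for parameter recovery, 200 replicates
for dose-effect recovery, 1000 replicates for the null-calibration
checks, 20 seeds for kinematics, 100 random polygon pairs for geometry.
Every generator takes an explicit integer seed and fixed seeds give
byte-identical outputs; `run_pipeline()` fans a single global seed out to
per-stage substreams and writes a provenance record (package version,
config digest, seeds) next to every artifact.

## Known limitations

* Fitted `alpha` lives on $(0,1]$; data generated at the boundary
  $\alpha = 1$ make Wald intervals for `alpha` itself unreliable (the
  jackknife intervals for $N$ and $\tau_D$ remain calibrated).
* The pixel-count area is biased low by roughly half a perimeter-pixel
  band for convex ROIs; this matches the measurement convention and is
  below one pixel-equivalent for study-scale ROIs.
* The Lucas–Kanade estimator assumes locally uniform motion within its
  window; strong motion gradients within 5 px bias the estimate toward
  the window average, which the 5 × 5 region averaging then shares.
* `fit_gls_cs()` requires at least one cluster with two or more
  observations; ρ is unidentifiable from singleton clusters.
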