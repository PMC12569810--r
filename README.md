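# cochleametrics

Quantitative analysis of cochlear function for studies of metabolic
(lateral-wall) hearing loss: calcium-indicator fluorescence correlation
spectroscopy (FCS) in the tectorial membrane, organ-of-Corti morphometry,
sound-evoked stereocilia kinematics, evoked-potential analysis, and the
statistics layer that ties the measurements together. Every stage ships
with a synthetic-data generator with known ground truth, so the full
pipeline can be validated end to end without access to animal or human
recordings.

## Who it is for

Auditory physiologists and image-analysis scientists working with:

* photon-count traces from confocal FCS in scala media (count rates around
  100 kHz),
* confocal or histological section images with regions of interest over
  the tectorial membrane (TM) and organ of Corti (OoC),
* phase-stamped rapid confocal sequences of stereocilia bundles under
  acoustic stimulation,
* round-window or intracochlear evoked potentials (CAP/ABR, cochlear
  microphonic, summating potential) and distortion-product otoacoustic
  emissions,
* grouped molecular-brightness tables with within-preparation correlation.

## The models at the core

**FCS.** The fluctuation autocorrelation of a photon trace,
G(τ) = ⟨δF(t)·δF(t+τ)⟩ / ⟨F⟩², is fitted with the three-dimensional
anomalous-diffusion model

    G(t) = (1/N) · [1 + (t/τ_D)^α]⁻¹ · [1 + (1/S²)(t/τ_D)^α]^(−1/2)

where `N` is the mean number of molecules in the detection volume, `τ_D`
the diffusion time, `α` the anomalous exponent (α = 1 is free diffusion)
and `S` the axial/lateral aspect ratio of the detection volume; an
optional multiplicative term `1 + T/(1−T)·exp(−t/τ_T)` accounts for
triplet-state formation. Molecular brightness — a calcium proxy for the
indicator used in the cochlea — is the background-corrected mean count
rate divided by `N`.

**Morphometry.** ROI areas are pixel counts times the squared pixel size;
the TM–organ gap is the shortest Euclidean distance between the TM
boundary and the reticular-lamina polyline; measurements from the apical
locations of each cochlea are averaged before statistics.

**Kinematics.** Phase-stamped pixel streams are rebinned into one frame
per stimulus-phase bin, low-pass filtered, and per-pixel subpixel motion
is estimated by iterative Lucas–Kanade gradient flow against the
cycle-mean image. Stereocilia deflection is the bin-wise vector difference
between tip and base trajectories (each averaged over a 5 × 5 pixel
region).

**Evoked potentials.** Epochs are band-pass filtered (zero-phase,
300–3000 Hz) and averaged; the cochlear microphonic is the
stimulus-frequency Fourier component (amplitude and phase relative to the
speaker drive), the summating potential the whole-cycle DC shift, and
DPOAEs the 2f₁−f₂ component under two-tone stimulation with f₂/f₁ = 1.2.
Input–output functions yield interpolated thresholds at a configurable
criterion.

**Statistics.** Brightness tables are analysed by Gaussian generalised
least squares with a compound-symmetric within-animal correlation
(`nlme::gls`), group comparisons by one-way ANOVA with Tukey–Kramer
post-hoc tests or rank tests, and human thresholds by ordinary least
squares on age and TM–OoC gap.

## Worked example

```r
library(cochleametrics)

# simulate one FCS location: 6 x 10-s recordings, ~5 molecules in focus
traces <- lapply(1:6, function(r)
  simulate_photon_trace(fcs_sim_config(n_effective = 5, duration = 10,
                                       bin_width = 1e-3,
                                       diffusion_coefficient = 1,
                                       seed = 100 + r)))
fit <- fit_fcs_repetitions(lapply(traces, autocorrelate), S = 5)
print(fit)
#> Anomalous-diffusion fit: N = 5.21, tau_D = 0.0136 s, alpha = 1.000, S = 5 (fixed)

pooled <- photon_trace(unlist(lapply(traces, `[[`, "counts")),
                       bin_width = 1e-3, background_rate = 1000)
molecular_brightness(pooled, fit)
#> Molecular brightness [TM1]: 21.4 kHz/molecule (N = 5.21)
```

The fitted `N` and `tau_D` agree with the generating configuration
(N_eff ≈ 5, τ_D = 15.6 ms), and the brightness of 21.4 kHz per molecule is
the generator's apparent-brightness ground truth; jackknife confidence
intervals over the repetitions are in `fit$conf_int`.

A synthetic brightness study analysed with the compound-symmetry GLS:

```r
tab <- synth_brightness_table(brightness_table_config(
  n_animals_per_group = 25, dose_levels = c(0, 1, 2),
  dose_slope = -61, intra_animal_correlation = 0.5, residual_sd = 40,
  seed = 23))
fit_gls_cs(tab)$coefficients["dose", c("estimate", "lower", "upper")]
#>       estimate     lower     upper
#> dose -63.42028 -71.02142 -55.81914
```

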