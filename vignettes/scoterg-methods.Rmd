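---
title: "Methods: scotopic ERG analysis and retinal bioenergetics with scoterg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scotopic ERG analysis and retinal bioenergetics with scoterg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoterg)
```

## What the package computes

`scoterg` implements the analysis chain used to characterize early retinal
dysfunction in diabetic mouse models from two kinds of raw measurement:
scotopic full-field electroretinogram (ERG) epochs, and oxygen-consumption
traces of retinal punches in an extracellular-flux (Seahorse-type) analyzer.
The chain is:

1. **Stimulus calibration** — flash energies in log cd·s/m² are converted to
   photoisomerizations per rod (R\*/rod) with the scotopic calibration
   1 scot cd/m² = 516 R\*/rod/s, and classified into the four conventional
   light zones (rod threshold, rod–bipolar, mixed, cone-involved).
2. **Waveform features** — a-wave, b-wave, and positive scotopic threshold
   response (pSTR) amplitudes and implicit times.
3. **Oscillatory potentials (OPs)** — isolated by a hard spectral mask
   (FFT, zero all bins outside 65–300 Hz, inverse FFT) and quantified as the
   first four wavelets: implicit time from stimulus onset to peak,
   amplitude from peak to adjacent trough, plus their sum (ΣOPs).
4. **Intensity–response fitting** — the Naka–Rushton function
   $V(I) = V_{max} I^n / (I^n + \sigma^n)$ fitted to b-wave amplitude versus
   flash intensity inside the rod operating range (< −0.3 log cd·s/m²),
   reporting the maximum rod-driven response $B_{max}$.
5. **Bioenergetics** — basal, maximal, spare, and non-mitochondrial
   respiration from three-phase OCR traces (basal → FCCP → rotenone +
   antimycin A), optionally protein-normalized.
6. **Group statistics** — Shapiro–Wilk normality gate, pooled and Welch
   two-sample t-tests from raw samples *or* published (mean, SEM, n)
   summaries, split-plot (mixed) ANOVA with Greenhouse–Geisser correction,
   and simple main effects.

A synthetic-data module generates ground-truthed inputs for every stage, so
the full chain is testable without access to animal recordings.

## The synthetic ERG model

No generative waveform model is mandated by the measurement conventions the
package implements, so the simulator uses minimal smooth shapes whose peak
times and amplitudes are exact by construction:

* **a-wave** — a negative gamma-shaped lobe with its trough exactly at
  `a_peak_ms` (default 15 ms), present only at zone 3–4 intensities. A
  gamma lobe (rather than a Gaussian) rises smoothly from zero at stimulus
  onset; a truncated Gaussian would leave a discontinuity at t = 0 whose
  spectral splatter biases low-pass-filtered amplitude readback.
* **b-wave** — a positive gamma lobe peaking at `b_peak_ms` (default
  70 ms) whose amplitude follows the Naka–Rushton function of intensity
  with true parameters (`b_amp_max` = 600 µV, semisaturation 10⁻² cd·s/m²,
  exponent 1 by default). This makes the fitted $B_{max}$ directly
  comparable to a known truth.
* **OPs** — `n_wavelets` (default 4) Gabor wavelets at `op_freq_hz`
  (default 110 Hz, inside the 65–300 Hz isolation band) spaced one carrier
  period apart from `op_onset_ms`, each with amplitude `op_gain` × the
  epoch's b-wave amplitude and geometric decay 0.85 per wavelet. The
  Gaussian envelope width is 0.75 carrier periods: short envelopes are
  spectrally broad and leak appreciable energy below the OP band, which
  contaminates the low-passed a-trough; 0.75 periods keeps the four peaks
  separable while keeping that leakage below the closure tolerances.
* **pSTR** — a small Gaussian lobe (default 20 µV at 130 ms). Its
  amplitude does not scale with intensity; it dominates at zone-1 stimuli
  simply because the b-wave has collapsed there.
* **Scotopic floor** — stimuli below `response_floor_log` (default
  −5 log cd·s/m², about 5 × 10⁻³ R\*/rod) produce no stimulus-driven
  component at all, reflecting absolute threshold.
* **Noise** — i.i.d. Gaussian with sd `noise_sd`/√`n_sweeps`, emulating
  averaging of 40 sweeps (default per-sweep sd 10 µV).

Defaults (2 kHz sampling, 350 ms epochs with 50 ms pre-stimulus) reflect
typical murine scotopic recordings and leave ample Nyquist margin above the
300 Hz band edge. Every list-generating simulator derives child seeds from
the master seed by `split_seed(seed, index)`, a documented
multiplicative-congruential mix, so series are element-wise reproducible.

What the simulator does **not** emulate: electrode drift and
low-frequency baseline wander, line interference, photoreceptor (PIII)
kinetics, intensity-dependent implicit-time shifts, inter-animal waveform
variability, and cone-pathway intrusion above the rod range. Passing tests
therefore certify the *measurement* chain (given a waveform of the stated
form, features are recovered at stated tolerances), not the biological
realism of the waveforms themselves.

## Measurement conventions and numerical choices

* **Baseline**: the pre-stimulus mean is subtracted; all features are then
  invariant to constant offsets.
* **Smoothing**: peaks are located *and* amplitudes read on a 60 Hz
  low-passed copy of the trace (FFT mask with a raised-cosine edge between
  60 and 90 Hz; the taper suppresses Gibbs ringing around stimulus onset).
  Without this, OP wavelets — which ride exactly on the b-wave rising limb
  — capture the b-peak and bite into the a-trough. `smooth = FALSE`
  disables it.
* **b-wave reference**: trough-to-peak (b-peak minus a-trough) when a
  credible a-wave is present, otherwise baseline-to-peak. "Credible" means
  exceeding both 3× the pre-stimulus noise sd and an absolute 1 µV floor;
  dim flashes otherwise promote sub-microvolt numerical dips into an
  a-wave. Both conventions are selectable (`b_reference`).
* **Search windows** (all configurable): a-wave 3–50 ms, b-wave 20–150 ms,
  pSTR 80–200 ms, OP wavelets 10–100 ms — standard murine scotopic timing.
* **OP mask**: hard and inclusive at the 65 and 300 Hz edges — components
  *beyond* the cut-offs are eliminated, the cut-off bins themselves
  survive. No zero-padding: padding moves bin frequencies and would change
  which components survive; it is available only implicitly by resampling
  before the call. Ringing from the hard mask is accepted and bounded by
  the recovery tests; a raised-cosine taper is available (`taper_hz`) but
  off by default.
* **Adjacent trough**: resolved as the trough *following* the OP peak,
  falling back (with a flag) to the preceding one for a terminal peak. The
  preceding-trough convention is available as an option.
* **Naka–Rushton fit**: residual sum of squares minimized over
  ($B_{max}$, log₁₀ σ, n) with L-BFGS-B from five deterministic starts
  spread across the data's intensity span — fits are reproducible without
  a seed. Bounds: $B_{max} \in [0, 2\,\max(\text{amplitude})]$, σ within
  the data range ± 1 log unit, $n \in [0.5, 3]$. A line-search stall at a
  point a restart cannot improve is treated as converged. `fix_n = 1`
  selects the classical two-parameter hyperbola. The package fits per
  animal (amplitudes from one animal's intensity ladder), matching the use
  of $B_{max}$ as a per-subject measure in repeated-measures designs;
  fitting group-mean amplitudes is possible by passing averaged data.
* **Respiration parameters**: basal uses the *last* pre-injection
  measurement and maximal the *highest* FCCP-phase measurement (the usual
  flux-analyzer report conventions); mean-of-phase alternatives are
  provided. With FCCP injected first there is no oligomycin phase, so
  ATP-linked respiration and proton leak are deliberately not computed.
  Negative basal or spare values are flagged, never clamped.
* **Statistics**: orientation is fixed as second group minus first
  (diabetic minus control when called in that order), two-sided p-values,
  no multiplicity correction. The pooled t is the default (published
  degrees of freedom in this literature are n₁ + n₂ − 2 throughout);
  Welch is available. The split-plot ANOVA uses the definitional
  orthogonal decomposition — valid for unequal group sizes as long as
  every subject is measured at every timepoint — and the
  Greenhouse–Geisser ε from the double-centered pooled within-group
  covariance, clamped to [1/(k−1), 1]. Simple main effects default to the
  per-timepoint error term (F = t² for two groups); the omnibus
  between-subjects error is available, but note that published
  simple-main-effect F values are generally not recoverable from printed
  summaries because the error term actually used is rarely stated.

## Worked example

```{r example}
# a two-group synthetic cohort, analyzed end to end
res <- run_pipeline(list(
  seed = 7,
  groups = list(ctrl = list(n = 5), db = list(n = 5, b_amp_max = 420))
))
res$stats$bmax$group_means
round(c(t = res$stats$bmax$t, df = res$stats$bmax$df, p = res$stats$bmax$p), 4)
```

The diabetic group is simulated with a reduced true $B_{max}$ (420 versus
600 µV); the fitted values recover the deficit and the pooled t-test flags
it. Note the fitted `bmax` exceeds the configured lobe amplitude by roughly
the a-wave amplitude, because the default b-wave convention is
trough-to-peak.

```{r reported}
# published (mean, SEM, n) pairs versus their reported t statistics
head(reproduce_reported_t()[c("comparison", "t", "t_reported", "df", "pass")])
```

## Problem sizes used in the test suite

The suite runs the noisy Naka–Rushton recovery at 200 replicates, the
sweep-averaging Monte Carlo at 100 × 40 sweeps, the type-I calibration at
10⁴ null simulations of n = 10 per group, and the compound-symmetry ε check
at 200 subjects × 4 timepoints. These sizes give Monte-Carlo standard
errors several times smaller than the tolerances they are checked against.

## Known limitations

* The simulator's components are stylized; extraction accuracy on real
  recordings with drift, blinks, or non-stationary noise is not certified
  by these tests.
* The two internal light-zone boundaries (−3.8, −2.0 log cd·s/m²) are
  conventional choices separating the canonical example stimuli; only the
  −0.3 rod-range edge is fixed by the rod operating range. Both are
  configurable.
* Whether the 516 R\*/rod/s calibration should be rescaled for long
  (non-impulse) flashes is protocol-dependent; the package treats
  intensities as flash energies and applies the constant per flash.
* `mixed_anova` requires complete data; it refuses designs with missing
  cells rather than imputing.
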