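---
title: "Methods: modelling frog communication space under road noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling frog communication space under road noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callspace)
```

# The problem and the model

Chorusing frogs advertise in a narrow band (here 1.0–4.5 kHz) that road
noise partially occupies. The quantity of ecological interest is not the
call's level per se but the *region of space and fraction of time* over
which a female can detect it. `callspace` models this with three pieces.

**Propagation.** A call with band-limited source level $s$ (dB re 20 µPa,
referenced to 1 m) is received at distance $r$ as

$$\mathrm{RL}(r) = s - 20\log_{10} r - A_e r,$$

spherical spreading plus a linear excess-attenuation term
($A_e = 0.2$ dB/m by default, a mid-range value for open field and
deciduous-forest conditions in this band; an optional linear atmospheric
absorption term exists but defaults to 0 because it is negligible —
hundredths of a dB — at these ranges). $\mathrm{RL}$ is strictly
decreasing in $r$ and diverges as $r \to 0^+$, so the masking radius below
always exists.

**Masking radius.** Detection fails when the call falls to the ambient
level $n$ (plus an optional detection threshold $\tau$, default 0 dB — a
deliberately conservative masking criterion; psychoacoustic work on a
confamilial treefrog suggests thresholds up to ~30 dB, which would shrink
every radius below). The radius solves $\mathrm{RL}(r^*) = n + \tau$. With
$\Delta = (s - n - \tau)/20$ and $k = A_e \ln 10 / 20$ the solution is
closed-form via the principal Lambert-W branch,
$r^* = W(k\,10^{\Delta})/k$, reducing to $r^* = 10^{\Delta}$ when
$A_e = 0$. The implementation iterates Halley steps to machine precision;
tests hold it to $10^{-9}$ relative error against an independent bisection
oracle and to $10^{-6}$ dB on the composition
$\mathrm{RL}(r^*) = n + \tau$. Radii below the 1 m reference are returned
as-is with a `sub_reference` flag rather than clamped, so degenerate
regimes stay visible.

**Time–volume.** The communication space is taken as a hemisphere (a frog
calling at the water surface), $V = \tfrac{2}{3}\pi r^{*3}$, and the
per-minute spatiotemporal measure multiplies in calling behaviour:
$\mathrm{TV} = d \cdot \mathrm{rate} \cdot V$ with duration $d$ (s) and
rate (calls/min). TV is linear in $d$ and rate and strictly decreasing in
$n$; both are tested properties.

# Calibration chain

Digital full-scale samples $x \in [-1, 1]$ convert to pressure as
$p = x \cdot V_{FS} / 10^{(S + G)/20}$ with microphone sensitivity $S$
(dB re 1 V/Pa), gain $G$ (dB) and ADC full-scale voltage $V_{FS}$.
Recorders rarely publish $V_{FS}$; it is an explicit field of
`calibration_spec()` (default 1.0 V) rather than a hidden constant.
Nominal sensitivities are used; the ±4 dB manufacturing tolerance of
typical recorder microphones is treated as measurement uncertainty, not
modelled. Band-limited SPL extraction is: zero-phase 4th-order Butterworth
band-pass (biquad cascade; forward–backward application squares the
magnitude response, so the half-power corner is effectively −6 dB), then
per-window RMS pressure, then $20\log_{10}(p_\mathrm{rms}/20\,\mu\mathrm{Pa})$.
Windows are non-overlapping, aligned to clip start; a trailing partial
window is dropped; silence maps to a $-\infty$ sentinel, never an error.
The nominal 0–1,000 Hz traffic band is realized as 10–1,000 Hz: a true DC
edge is unfilterable, and synthesized (and real) scenes carry negligible
energy below 10 Hz.

No audio/DSP package is assumed: WAV PCM I/O and the Butterworth design
are implemented in the package and were cross-checked during development
against an independent DSP reference to four decimal places; the test
suite asserts the *contracts* (pass-band flatness, ≥20 dB an octave out of
band, Parseval consistency between time-domain RMS and spectral energy)
rather than borrowed numbers.

# Call measurement choices

* **Duration is annotation-bounded.** Selections define call start/end;
  duration is their difference, and a 0.05 s buffer widens the *analysis*
  window only. The cited noise-robust feature set's internal duration
  algorithm is not specified in the source methods, so the package
  reproduces the documented workflow (bounds + buffer) instead of
  guessing.
* **Received level is energy over the buffered window normalized by the
  annotated duration.** Normalizing by the buffered window length would
  systematically under-read every call by $10\log_{10}((d+0.1)/d)$ —
  1.2–1.5 dB for typical 0.2–0.3 s calls. Normalizing by $d$ makes the
  buffer bias-free: it collects smeared energy without diluting the RMS.
* **Centroid frequency** is the energy-weighted mean over 4096-point FFT
  bins inside 1.0–4.5 kHz, Hann-windowed, Welch-averaged (50% overlap) for
  segments longer than one FFT. Pure tones localize within one bin
  (~2.7 Hz at 11,025 Hz).
* **Analysis rate.** Recordings are decimated 44.1 kHz → 11,025 Hz before
  measurement, as in the field workflow. The decimator is a linear-phase
  windowed-sinc FIR (Blackman, 301 taps, cutoff 94% of the new Nyquist) —
  equivalent to polyphase resampling for integer factors. An IIR
  anti-alias filter was tried first and rejected: its pass-band tilt at
  the call's 1.5× harmonic biased centroids by up to ~9 bins.
* **Screening.** Calls flagged as overlapping another frog, or with SNR
  (call-window band SPL minus site median ambient) below 10 dB, are
  excluded from feature measurement. The 10 dB default operationalizes the
  field protocol's qualitative "high signal-to-noise ratio". Call *rate*
  counts every annotated call — the field definition is calls per minute
  of recording, not accepted calls per minute.
* **Source level at 1 m** inverts the propagation model:
  $s = \mathrm{RL} + 20\log_{10} r + A_e r$. Whether the original field
  back-calculation included the $A_e r$ term at short range is unstated;
  both behaviours are available ($A_e$ is configurable to 0) and the
  default keeps the model self-consistent.

# Ambient noise

A site-night's ambient level $n$ is the median of the windowed band SPL
values whose window *start* falls in a configurable clock interval,
default 16:00–17:00 local standard time — before evening chorusing, so the
measure is road noise, not frogs. The masking model always uses the
1.0–4.5 kHz band median as $n$; the 10–1,000 Hz traffic band is
descriptive only (which band fed which published site average is ambiguous
in the source). Across sites, medians are regressed on
$A = 1/d_\mathrm{km}^2$, the linearizing regressor the inverse-square law
predicts for outdoor propagation.

# The synthetic world

The generator states one fixed world; its defaults are not tuned to test
outcomes.

* **Sites.** Eight sites at 90, 100, 110, 120, 1200, 2000, 3000, 4000 m
  from a busy road; $n_i = 37.44 + 0.158/d_{\mathrm{km},i}^2 + \epsilon_i$,
  $\epsilon \sim N(0, 1\ \mathrm{dB})$. Intercept and slope were chosen
  once so that near (<1 km) and far sites average ≈52.3 and ≈37.5 dB —
  the published field means — with a realistic ~57 dB loudest site.
* **Frogs.** 89 males allocated round-robin over sites and 3 nights per
  site. Each response follows
  $y = \beta_0 + \beta_T T + \beta_n n + u_\mathrm{site} +
  u_\mathrm{date(site)} + \epsilon$; log-duration is generated on the log
  scale and exponentiated; call rates are truncated at zero (a <0.1%
  event under defaults). The four slope pairs are the published Table-2
  effect sizes. Intercepts are unpublished; they are anchored so that at
  the study-mean covariates (9.59 °C, ~45 dB) the population means are
  species-typical: ~30 calls/min, ~2400 Hz, ~0.25 s, ~90 dB at 1 m.
  Variance components are likewise unpublished and set to plausible field
  magnitudes (residual SDs 8 calls/min, 120 Hz, 0.15 log-s, 4 dB; site
  SDs 2, 40, 0.06, 1.5; night-in-site SDs 1.5, 25, 0.04, 1). Source
  levels default to Normal(90, 4) dB — a placeholder, explicitly
  configurable, since the species' measured source-level distribution is
  not published. Nightly temperatures are uniform on 4–15 °C (Pacific
  Northwest late-winter breeding nights, mean near 9.6 °C).
* **Audio.** A call is a three-component harmonic stack (0.5×, 1×, 1.5×
  the target centroid, amplitudes 0.3/1/0.3 — symmetric, so the
  energy-weighted centroid equals the target exactly), shaped into two
  raised-cosine syllables (35% of the duration each, 30% gap), scaled to
  the requested RMS. This matches the species' two-syllable call
  qualitatively; it is not a vocal-tract model. Road noise is white
  Gaussian through a one-pole 500 Hz low-pass plus a −34 dB flat floor,
  scaled so its 1.0–4.5 kHz band SPL hits the requested level. Scenes mix
  Eq.-1-attenuated calls over this noise in pascal, then render to digital
  through the inverse calibration; clipping is counted and warned about.
  Scene truth tables flag calls that overlap another frog's call, since
  the measurement protocol excludes such calls.
* **What a green round-trip establishes — and what it does not.** Tests
  recover source levels to ±1 dB, centroids to ±2 bins, and rates exactly
  on these scenes at SNR ≥ 20 dB. The scenes have no reverberation,
  vegetation scattering, wind nonstationarity, chorus babble, or moving
  sources; recovery there validates the *measurement chain*, not
  robustness to every field condition.

# Inference

Every response uses the same structure the field analysis used:
`y ~ noise + temperature + (1 | site/date)`, REML, via `lme4`; duration on
the natural log scale (base unstated in the source; natural log chosen,
and `percent_change_per_unit()` back-transforms as
$100(1 - e^{\beta})$). Random intercepts only, matching the stated design.

Reference df for t-statistics and intervals are containment-style, at the
level where each covariate varies: noise is constant within site → df
$= n_\mathrm{sites} - 2$; temperature varies by night → df
$= n_\mathrm{site\text{-}nights} - n_\mathrm{sites} - 1$; intercept → df
$= n - 3$. A plain normal approximation was tried first and measured
marginally anticonservative for the site-level noise effect (89.5%
coverage of nominal 95% intervals over 200 replicates — the expected
small-cluster effect with 8 sites); containment df restore coverage into
the 90–99% band. The exact df convention used in the original analysis is
not recoverable from its text; this one is documented and tested.

Degenerate designs (one site, or an all-zero-variance synthetic dataset
that REML cannot profile) fall back to fixed-effects OLS with a message;
the zero-variance identity test exercises exactly this path's accuracy.

# Pipeline, determinism, degenerate inputs

`run_pipeline()` goes from a JSON config to a CSV bundle: site noise
table, frog records, inverse-square fit, all five mixed models (including
the derived masking-radius response), per-frog communication space, and a
time–volume comparison across the observed noise range computed with the
call rate held at its mid-range prediction versus following its noise
coefficient — the contrast that shows the temporal component amplifying
communication loss at loud sites (negative shift) while slightly
inflating it at quiet ones (positive shift).

All generators are pure functions of (config, seed): one master seed,
per-stage derived streams, bit-identical outputs on reruns (tested down to
WAV bytes and report CSVs). Empty or single-site frog tables produce
explicit empty report sections, not crashes. Numerical tie-breaks and
sentinels: silence → $-\infty$ SPL; zero in-band energy → `NA` centroid;
buffered windows clamped to clip bounds with a warning.

# Known limitations

Hemispherical geometry ignores vegetation, caller position, substrate and
frequency-dependent attenuation. The detection threshold default (0 dB)
overestimates radii if real perception thresholds are higher. The
synthetic world's unpublished parameters (intercepts, variance components,
source-level distribution) are stated choices, not estimates; analyses of
real recordings should supply their own calibration and site metadata.
Field-study regression coefficients themselves cannot be reproduced here
because the underlying recordings are not public — the package validates
recovery of *known* synthetic truth instead.
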