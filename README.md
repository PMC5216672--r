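# callspace

Road traffic is loud in exactly the band where chorusing frogs advertise.
`callspace` quantifies what that costs a calling male: it turns field
recordings (or fully synthetic soundscapes with known ground truth) into
calibrated sound-pressure levels, measures per-call acoustic features, and
evaluates a simple spatiotemporal model of how much space and time a call
commands before it sinks below the noise floor. It is aimed at acoustic
ecologists studying masking by anthropogenic noise, and at anyone who wants
a tested, scriptable version of this analysis chain.

## The model

A call with band-limited source level *s* (dB re 20 µPa at 1 m) propagates
under spherical spreading plus linear excess attenuation:

```
RL(r) = s − 20 log10(r) − A_e r
```

with *A_e* = 0.2 dB/m by default. Against background noise *n*, the
**masking radius** *r\** solves `RL(r*) = n` (closed form via the Lambert-W
function; a detection threshold above *n* is configurable). The
**communication volume** is the hemisphere `V = (2/3) π r*³`, and the
per-minute **time–volume** folds in calling behaviour:

```
time.volume = d · rate · (2/3) π r*³     [m³·s per minute]
```

where *d* is call duration (s) and *rate* is calls per minute. Call
parameters themselves are analysed with linear mixed models
`y ~ noise + temperature + (1 | site/date)`.

## What is in the package

- **calibration** — digital ↔ pascal conversion from microphone
  sensitivity/gain, SPL, zero-phase Butterworth band-pass, windowed
  band-limited RMS SPL series. WAV I/O is self-contained (16/24-bit PCM).
- **soundscape** — ambient-noise profiles per site-night (median of the
  16:00–17:00 windows) and the inverse-square noise-vs-distance regression.
- **call_features** — overlap/SNR call screening, annotation-bounded
  duration with 0.05 s analysis buffer, 4096-point spectral centroid,
  1 m source-level back-calculation, call rate, per-frog aggregation.
- **commspace** — received level, masking radius, hemisphere volume,
  time–volume, acoustic-barrier insertion-loss scenarios.
- **stats_pipeline** — `lme4`-backed mixed models with containment-style
  df, percent-change back-transforms, replicated recovery simulations, and
  `run_pipeline()` from a JSON config to a CSV report bundle.
- **synthetic_data** — generators for sites, frog populations (defaults use
  the published effect sizes for *Pseudacris regilla*: +16.676 Hz/°C,
  −4.422 Hz/dB, +1.566 calls·min⁻¹/°C, −0.048 log-duration/°C, …) and
  fully calibrated audio scenes (two-syllable harmonic-stack calls over
  500 Hz-corner low-pass road noise) with truth selection tables.

## Worked example

```r
library(callspace)

p <- propagation_params()              # A_e = 0.2 dB/m, threshold 0 dB
comm_space(s = 90, n = c(37.48, 52.27), d = 0.25, rate = 30, p)
#>   s     n radius_m volume_m3 time_volume
#>  90 37.48    75.06    885676     6642570
#>  90 52.27    34.66     87230      654221
```

A 90 dB call that reaches 75 m at a quiet site (n = 37.5 dB) carries only
34.7 m at a roadside site (n = 52.3 dB): a ~10× loss of volume and
time–volume. A noise barrier worth 5 dB of insertion loss buys back 12 m of
radius at the loud site:

```r
barrier_scenario(90, 52.27, barrier_spec(5), p)
#>   radius_before_m radius_after_m delta_m
#> 1           34.66          46.71   12.05
```

Synthetic audio round-trips through the measurement chain:

```r
clip <- synthesize_call_clip(freq = 2400, duration = 0.3, source_level = 90)
centroid_frequency(clip)                                   # 2400
band_rms_spl(clip, band = c(1000, 4500), window_s = 0.3)$spl_db  # 89.93
```

A full synthetic study (sites → frogs → mixed models → communication space
→ CSV report) is one call:

```r
res <- run_pipeline(list(scenario = "synthetic", seed = 1), out_dir = "report")
res$lmm_fits$centroid_frequency
```

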