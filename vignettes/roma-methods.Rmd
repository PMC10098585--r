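---
title: "Heart rate and signal quality from raw PPG: the methods behind romahr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart rate and signal quality from raw PPG: the methods behind romahr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romahr)
```

`romahr` extracts heart rate (HR) from a raw single-channel
photoplethysmography (PPG) waveform two independent ways — beat counting in
the time domain and spectral peak tracking in the frequency domain — and
scores the record's quality by how well the two agree and how stable the
spectral line is. This vignette explains the model, every tunable that
matters, the numerical choices, and what the synthetic test bed does and
does not establish about real data.

## The signal model and its assumptions

A PPG waveform is quasi-periodic: each cardiac cycle contributes a narrow
positive systolic lobe (the package's normalized convention puts it at +1),
a small diastolic secondary bump near zero, and a broad negative undershoot
around −0.5. Three classes of corruption are modelled:

* **slow non-periodic drift** (breathing, sweating, adhesive tension) —
  band-limited well below the cardiac band;
* **impulsive contact-loss artifacts** — sharp level changes when the
  sensor loses and regains skin contact, whose transforms spread as
  broadband "streaks" across the spectrogram while the true pulse vanishes;
* **narrowband cadence interference** — a tone near 100 BPM, twice a
  50 RPM pedaling cadence, during cycling exercise.

The method assumes HR stays within a physiological band (the search band
defaults to 40–210 BPM) and that drift is slower than roughly 0.8 Hz so the
baseline filter can separate it from the pulse.

## Preprocessing chain

**Baseline (`moving_mean_baseline`).** A centered moving mean over
`baseline_window_s` (default 0.6 s) smooths out the sub-0.3 s
systolic/diastolic peaks while following drift; subtracting it
(`highpass_subtract`) is a time-domain high pass with response
$1 - H(f)$, where $H$ is the Dirichlet kernel of a length-$L$ moving
average with first null at $f_s/L$. One wrinkle deserves a note: at the
46.3 Hz chest-sensor rate, a 0.6 s window rounds to $L = 28$ samples,
whereas the canonical description of this chain quotes $L = 30$
(equivalently 0.648 s, first null 1.543 Hz). The distinction is immaterial
downstream — both nulls sit far above the drift band — and tests that
exercise the $L = 30$ response construct that window explicitly.

**Low pass (`lowpass_pulse`).** A minimum-order elliptic design applied
forward–backward (zero phase). `cutoff_hz` (3.5 Hz = 210 BPM) is the
passband edge; `steepness` (0.8) places the stopband edge at
$f_c + (1-s)(f_s/2 - f_c)$. Design targets are half the contract per pass
(0.25 dB ripple, 31 dB attenuation) because the two passes double the dB
scale; the measured zero-phase response stays within 0.5 dB in the passband
and below −60 dB in the stopband. Zero-phase filtering is what lets beat
*timing* survive filtering: on clean synthetic records, systolic peak times
move by less than one sample through the whole chain.

**Cadence notch (`notch_cadence`, off by default).** An elliptic band-stop
(order 3, 0.25/18 dB per pass) with passband edges at
`center ∓ 0.54 × width`, chosen so the zero-phase −3 dB width equals the
nominal `notch_width_bpm` (50 BPM): at the defaults the response is −48 dB
at 100 BPM yet within 0.1 dB at 70 and 130 BPM, so a genuine HR line next
to the artifact is untouched. It is optional because it is only needed for
records showing a visible cadence line.

**Amplitude normalization (`normalize_moving_max`).** A *trailing* moving
maximum over `max_window_s` (0.5 s) tracks the systolic amplitude `w`; the
normalized signal is `r = z / max(w, ε)` with `ε = 1e-6·max|v|` guarding
all-zero input. Trailing (not centered) matters: the current sample is
always inside its own window, so `r ≤ 1` everywhere and every systolic peak
touches exactly +1 regardless of slow amplitude changes. The low-passed
sequence `z` feeds this normalization and peak picking; the spectrogram
instead consumes the pre-lowpass `v`, whose broadband content is exactly
what the STD-width index needs to see.

## Time-domain heart rate

Systolic peaks are maxima of `r` above `peak_threshold` (0.5 — diastolic
bumps sit near or below zero, so they never cross it) separated by at least
`min_separation_s` (0.25 s, a 240 BPM ceiling consistent with the 210 BPM
low pass). Because the trailing-max normalization pins the whole systolic
ascent at exactly 1, maxima are detected plateau-aware (the last tied
sample is the peak — the maximum of the underlying pulse), and a candidate
needs real neighbours on both sides, so a pulse truncated by the record
boundary is not counted. Peak time is the time of the maximum sample, with
no sub-sample interpolation: at 30 Hz and above the ≤33 ms quantization is
small against beat periods.

Instantaneous HR is $60/T_{0,k}$ from successive peak differences. Outliers
— sharp jolts to the sensor — are flagged when they deviate from a centered
40-beat local median by more than 3 scaled MADs (scale 1.4826, the normal
consistency constant), then replaced by the previous beat's cleaned value
(a flagged first beat takes its window median) and *masked* so downstream
statistics exclude them. One numerical guard: when beat times sit on a
coarse sampling grid, periods quantize to adjacent sample counts and a
window's MAD can collapse to zero, which would flag pure grid jitter. The
deviation scale is therefore floored at one quantization step of
instantaneous HR, $\mathrm{med}^2/(60 f_s)$ — below measurement resolution
the MAD carries no information. On clean generated records fewer than 0.1%
of beats are flagged. Finally a centered 40-beat moving mean (≈30 s at
typical rates, matching the spectrogram window) smooths the cleaned series,
emitted at every beat; windows shrink at the series edges rather than
padding.

## Frequency-domain heart rate

`compute_spectrogram` takes Hamming-tapered frames of `window_s` (30 s)
every `hop_s` (7.27 s — an HR update rate short enough to be clinically
useful and long enough to average many beats), zero-padded to the next
power of two at or above 4× the frame length so that peak and width
measurements resolve sub-bin variation (width quantization ≤ 0.25 bin).
Each frame's magnitude-squared spectrum is stored normalized to unit peak.
For 10 s records the defaults cannot fit a window; the short-record mode
(`window_s = 2.5`, `hop_s = 0.6`) yields an HR value every 0.6 s at the
cost of 24 BPM spectral resolution.

`track_peak_and_width` reports, per frame, the argmax frequency within
`band_bpm` (40–210: the lower bound excludes respiratory peaks, the upper
equals the low-pass edge) times 60, and the **line width**: the frequency
extent, lowest to highest crossing within the band, of the region where
power reaches `width_level` (0.5) of the tracked peak's power, with linear
interpolation at the crossings. Two conventions hide here and both were
deliberate:

* the level is relative to the *tracked in-band peak* (the peak
  fundamental, normalized to 1), not the frame's global maximum, which
  during artifacts can sit in the sub-band impulse shoulder;
* the width spans the *whole* supra-level region rather than only the
  contiguous lobe around the peak. On a clean record the two coincide (the
  peak's main lobe, ≈2.6 BPM at 30 s windows). On noise-like corrupted
  frames the contiguous lobe stays a few resolution cells wide no matter
  how bad the frame is — the supra-level *span*, by contrast, jumps to tens
  of BPM as power scatters across the band, which is precisely the
  dispersion the quality index must quantify. `width_level` is the single
  most consequential free parameter of the frequency path; halving or
  doubling it rescales widths but preserves the clean/corrupted contrast.

The asymmetric pulse has genuine second-harmonic power, but the fundamental
dominates (the template's second harmonic carries about 6% of the
fundamental's power), so per-frame argmax needs no harmonic
disambiguation. Per-frame HR is interpolated linearly back to the
time-domain beat stamps (`hr_freq_series`, endpoints held) for
point-by-point comparison.

## Quality indices and classification

**Self-consistency** is the percentage of non-masked beats at which the
smoothed time-domain HR and the interpolated frequency-domain HR agree
within `sc_tol_bpm` (10 BPM, inclusive). The two paths share almost no
machinery — beat counting vs spectral argmax — so corruption that derails
either shows up as disagreement.

**STD-width** is the sample standard deviation (n−1) of the per-frame line
width, in BPM. A cleanly mounted sensor gives a narrow, *stable* line;
intermittent contact loss makes the width flip between narrow and broad,
inflating its standard deviation. (A consequence worth knowing: a record
corrupted uniformly from start to end can have a *wide but stable* line and
a deceptively low STD-width — the index detects variability, not width
itself. Self-consistency covers that case.)

A record is **adequate** iff self-consistency > `sc_cut` (30) AND STD-width
< `width_cut` (10 BPM); boundary values classify as poor (strict
inequalities), and failing either index is enough. For new datasets with
expert good/poor labels, `roc_cutpoint()` rebuilds the ROC over all
observed thresholds (treating poor as the detected class), computes
trapezoid AUC, and picks the threshold maximizing
min(sensitivity, specificity), breaking ties by larger Youden's J and then
by the smaller threshold.

## Agreement statistics

`error_metrics` follows the reporting conventions of the chest-PPG
validation literature, including an RMSE with a $1/(n-1)$ denominator;
`rmse_denom = "standard"` switches to $1/n$ (the default is kept for
comparability, and it is always ≥ the standard form). MAE% normalizes by
the reference, so it is not symmetric under swapping series. Accuracy is
the percentage of beats within 5 BPM (inclusive). Point-biserial
correlation is the Pearson correlation with a 0/1 coding; correlations in
`roma_evaluate` are reported with Fisher-z confidence intervals, labelled
as such. Cohen's kappa uses marginal-product expected agreement with the
Landis–Koch interpretation bands (0.81–1.00 "almost perfect"); the
degenerate case of two identical constant raters is defined as 1 with a
warning. All agreement computations exclude beats masked by the outlier
rule.

## The synthetic generator

`synth_ppg()` exists so every stage and both indices are testable without
external downloads. Defaults emulate a 20-minute chest recording at
46.3 Hz. Its pieces:

* **pulse template** — Gaussian lobes: systolic (σ = 0.055 periods, peak
  +1 at phase 0.2), diastolic bump (0.15 at phase 0.45), and an undershoot
  whose depth is `pulse_asymmetry` (0.5) and whose width is solved so the
  template integrates to ≈0 over a period; the template is recentred and
  rescaled so its maximum is exactly +1 at phase 0.2;
* **HR trajectories** — constant, sinusoid, and a bike session (rest for
  half the record at 75 BPM, ramp to 120, climb to 150 at three quarters,
  recover to 95), all confined to 45–200 BPM; phase is the cumulative
  integral of HR/60, and true systolic times are emitted alongside a 1 Hz
  ground-truth HR series;
* **drift** — three random-phase sinusoids between 0.02 Hz and
  `drift_band` (0.3 Hz, breathing scale), total amplitude `drift_amp` (1
  pulse unit): band-limited below the baseline filter's null by
  construction, unlike a random walk;
* **contact loss** — Poisson-scheduled events (`contact_loss_rate`
  events/s) of uniform 0.5–3 s duration during which the pulse is gated to
  zero (a detached sensor sees no blood-flow signal), with ±`contact_loss_amp`
  (10 pulse amplitudes) step transients re-baselining exponentially
  (τ = 0.5 s) at both the loss and re-contact instants — the sharp swings
  whose transforms produce broadband streaks;
* **cadence** — an optional pure tone at `cadence_bpm` with amplitude
  `cadence_amp`, plus white noise of `noise_sd` (0.05).

Generation is deterministic given `seed`, and `make_fixture_suite()`
writes a byte-reproducible labelled CSV suite (three clean records, three
with increasing contact-loss rates of 0.05/0.15/0.3 events/s) with a YAML
manifest.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: beat-to-beat HR variability (trajectories are
smooth, so real sinus arrhythmia jitter is absent), pulse-shape physiology
beyond the three-lobe template (no dicrotic-notch dynamics, no SpO₂
wavelength effects), skin-tone- or perfusion-dependent amplitude, colored
sensor noise, and the many-shaped reality of motion artifacts beyond steps,
tones and drift. Results on synthetic records validate the *mechanics* of
the chain and the *direction* of the quality-accuracy relationship, not
field performance.

## Numerical choices and degenerate inputs

* Sample timestamps are 0-based (`t = t0 + n/fs`); all windows in seconds
  convert to sample counts by rounding to nearest, and every moving window
  shrinks at record edges instead of padding.
* Zero-phase filtering uses odd-symmetric edge padding before the
  forward-backward pass, shrinking start-up transients.
* All-zero input to normalization returns an all-zero signal with a
  warning; no peaks above threshold returns an empty beat set with a
  warning; fewer than two peaks, fewer than two frames, single-class
  labels, and non-positive reference HR are data errors with typed
  condition classes (`romahr_data_error`, `_format_`, `_config_`, `_io_`).
* Records shorter than one spectrogram window raise a data error that
  names the short-record configuration.
* ROC threshold ties break deterministically (min(sens, spec), then
  Youden, then smaller threshold); quality boundaries classify poor.

## Problem sizes in the test suite

The suite generates everything it needs at run time: module tests use 10 s
to 6-minute records; the end-to-end property checks use ten 20-minute
replicates per contact-loss rate for the dose-response medians, twenty
20-minute bike-protocol replicates for parameter recovery (time-domain MAE
< 2 BPM, frequency-domain < 2.5 BPM against truth), one hundred random
small instances for oracle equivalence of the statistical kernels, and a
six-record fixture suite for classification agreement. One acceptance
check targets two public PhysioNet datasets and reports failure when the
data are not present locally.

## Known limitations

* STD-width is blind to uniformly poor records (see above); the
  conjunction with self-consistency is what makes the label robust.
* Per-frame argmax has no tracking continuity: a strong artifact line can
  capture isolated frames (the cadence scenario) — that is by design, since
  such captures are exactly what self-consistency penalizes, and the notch
  exists for the known cadence case.
* The 30 s window trades frequency resolution (2 BPM) against time
  resolution; fast HR ramps smear the line and inflate widths slightly,
  which compressed test protocols exaggerate relative to real sessions.
* Sub-sample peak timing is deliberately not interpolated; below ~30 Hz
  sampling the quantization floor in the outlier rule becomes increasingly
  load-bearing.
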