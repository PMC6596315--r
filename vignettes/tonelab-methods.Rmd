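---
title: "Methods: models, measurement choices and what the synthetic tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, measurement choices and what the synthetic tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`tonelab` analyzes how the Mandarin Tone 1 (high level) versus Tone 4 (high
falling) contrast is produced and perceived, with the comparison of
normal-hearing (NH) children and pediatric cochlear-implant (CI) users in
mind. Because CI processors convey F0 poorly, listeners and speakers may
shift weight onto duration and intensity; the package measures that shift.
This vignette documents the measurement model, every tunable that matters,
the synthetic world used for validation, and the judgement calls made where
the underlying design was open.

## 1. The acoustic measurement chain

**Intensity.** Frame energy is a 30-ms Hann-weighted mean square, sampled
every 5 ms, expressed in dB re full scale (floor −100 dB). Only the 5-ms
sampling is externally prescribed; the 30-ms window is our choice — long
enough to average ≥ 2 glottal periods at 75 Hz, short enough to keep
syllable edges sharp. The dB reference cancels in every derived measure
(peaks are compared within and between syllables of the same token).

**Syllable segmentation.** The two syllables are the two most prominent
local maxima of the intensity contour. Prominence is the standard
topographic definition (height above the higher of the two minima separating
the peak from higher terrain or the signal edge). Detection starts at a
20-dB prominence requirement; when fewer than two peaks qualify — a shallow
inter-syllable dip — the requirement is relaxed in 2-dB steps to a floor of
6 dB, and the prominence actually used is recorded per token. Each syllable
is then trimmed at the last/first crossing of `peak − cutoff` (cutoff 20 dB
for the main analysis, 10 dB for the conservative variant), with sub-frame
linear interpolation of the crossing time; the search is bounded by the
inter-syllable minimum, so windows truncate there rather than overlap, and
windows clamped at a bound are flagged.

**F0 tracking.** Short-term autocorrelation with: 40-ms frames every 5 ms;
Hann-tapered frames; the tapered autocorrelation divided by the taper's own
autocorrelation (otherwise the decaying lag envelope skews peaks toward
shorter lags and biases F0 upward — on a stationary 147-Hz complex the raw
estimator was ~0.15 st sharp, the corrected one is exact to the printed
digit); parabolic interpolation of the correlation peak; an octave cost of
0.05 per octave of candidate period (the subharmonic at twice the true
period can tie the true peak's correlation on strongly periodic signals);
and a pre-whitening AGC that divides the signal by its 30-ms smoothed
amplitude envelope before framing, so a steep intensity ramp inside a frame
cannot drag the estimate toward the louder side — without it, glides under
realistic syllable envelopes measured up to 0.1 octave shallow. A frame is
voiced when its normalized correlation peak reaches the voicing threshold
(default 0.45, fallback 0.1 — the same semantics as the reference tool's
parameter) and its level clears a −70 dBFS silence gate. Voiced runs are
5-point median smoothed on log-F0 and residual jumps > 6 st against an
11-point local median are unvoiced.

**Vocal range.** All of a speaker's recordings are tracked at the broad
75–600 Hz range, pooled, and a normal density is fitted on the log-F0 axis;
its mean is the vocal-range center. Each token is re-tracked inside
±6 st of the center. Two automated fallbacks stand in for the manual
interventions a human analyst would make: (1) if voiced coverage inside a
syllable window falls below 60%, the voicing threshold drops to 0.1; (2) if
≥ 3 consecutive voiced frames sit within 0.25 st of a band edge, the band
widens to +12/−9 st. Both triggers and their outcomes are logged per token.
Whether the ±6 st restriction should hard-clip candidates or merely bound
the search was open; it is implemented as a search-range bound.

## 2. Tone descriptors

Per token, from the cutoff windows:

* `duration_ratio` — window 2 length / window 1 length (dimensionless);
  ratios discard speaking-rate differences.
* `intensity_peak_diff_db` — peak 2 − peak 1 (dB).
* `f0_median_rel_st` — 12·(median log2-F0 of syllable 2 − mean log2-F0 of
  syllable 1). The median/mean asymmetry follows the normalization used for
  contour plots (syllable 1 enters as its mean); both statistics are
  arguments.
* `f0_movement_st` — 12·(mean log2-F0 over the last 30 ms − first 30 ms of
  syllable 2); negative = falling. Whether the 30-ms edges should skip
  unvoiced frames was unstated; the default takes the first/last six
  *voiced* frames (skipping inward), and a `voiced_only = FALSE` switch
  takes the literal 30-ms spans instead.

Normalized patterns resample the windowed contour onto 100 points over
0–100% of the window (intensity in dB re the window peak; F0 in st re the
syllable-1 mean; F0 patterns with > 30% unvoiced coverage are marked
unavailable), and aggregation averages repetitions within speaker before
averaging across speakers.

Descriptors are computed per repetition and enter the models unaveraged
(repetitions are observations in the mixed models).

## 3. The perception continuum

The 96 tokens cross F0 slope (−1, −0.8, −0.6, −0.4, −0.3, −0.2, −0.1, 0
octaves), duration (40–140% in the stated six steps) and F0 height (120 or
220 Hz). Because the base stimulus here is synthetic, each token is
regenerated from source parameters rather than resynthesized from audio:
the second syllable's F0 runs linearly in log2 from `height` at the measured
window onset to `height · 2^slope` at the offset (onset anchoring was chosen
where the original anchor point was unstated), and its physical duration is
calibrated so that the *measured* 20-dB window is exactly the requested
percentage of the base token's. All tokens share one amplitude contour and
are scaled to a common RMS over their non-silent span (−26 dBFS). Every
token is verified by round-trip analysis: slope by interior-frame regression
of log2-F0 (frames within 20 ms of the window edges, whose analysis windows
overhang the syllable edge, and frames with fewer than three periods per
window are excluded), duration by the window length.

## 4. Mixed models and cue weights

**Production.** For one descriptor at a time:
`value ~ 1 + Contrast*Hearing + (1 + Contrast | Participant)`, maximum
likelihood, with Tone 1 and NH as references (0/1 coding keeps the random
slope numeric, so a diagonal-covariance refit is available for singular
fits, which are flagged). t statistics use residual-style degrees of freedom
(n − 4; 446 at the 75-speaker × 2-tone × 3-repetition design), matching the
reporting style of mixed-model analyses of this design; the merMod object is
returned for likelihood-ratio alternatives.

**Perception.** Tone 1 responses are aggregated to binomial counts per
participant × token and fitted as
`cbind(k, n−k) ~ Population*F0variation*Duration +
(1 + F0variation + Duration + F0height | Participant)`. F0 variation is the
*fall magnitude* in octaves (0 = flat, 1 = full-octave fall) — this is the
coding under which a steep NH psychometric function yields a large negative
coefficient. Duration enters as log(duration_pct/100) centered at the
6-level grid's log-mean. F0 height is contrast-coded ±0.5 and appears only
as a random slope, not a fixed factor. The default integrator is the
Laplace approximation (`nAGQ = 1`); `nAGQ = 0` is available for fast
exploration. Listeners with all-identical responses are flagged as
separated; their estimates exist only through shrinkage.

**Cue weights.** A subject's weight on a cue is the applicable group fixed
effect plus the subject's BLUP; whether the original per-subject
coefficients were BLUP-only or BLUP+fixed was unstated, so BLUP+fixed is the
default with the alternative behind `include_fixed = FALSE`. F0 weights are
additionally reported as log10|w| for cross-group variance homogeneity.
Coupling correlations (Pearson r, r², p; per group) are computed for the two
substantive pairs — duration weight × Tone 4 movement, log10|F0 weight| ×
Tone 1 relative median — and two null-check pairs. No multiple-testing
correction is applied by default, mirroring the original reporting; a
Bonferroni adjustment is a one-liner on the returned table.

## 5. The synthetic world

**Speakers.** Group defaults encode the documented strategies: NH speakers
lengthen syllable 2 by ~15% for both tones, place the Tone 1 median > 4 st
above syllable 1 with a slow +2.5 st rise, and fall −4.5 st for Tone 4 with
a ~+2 dB intensity boost; CI speakers lengthen Tone 1 only (~30% vs ~0%),
hold Tone 1 flat about +3 st, fall −4.5 st for Tone 4, and boost intensity
for Tone 4 only. Between-speaker variation (SDs: 0.08 on ratios, 0.8 st on
F0 measures, 0.75 dB on intensity, 2 st on the vocal-range center, 10% on
syllable-1 duration) and repetition jitter (5% on durations, 1 dB on
intensity, 0.5 st on F0 measures) are invented, configurable placeholders —
no within- or between-speaker variance figures were available to anchor
them.

**Utterances.** A harmonic source (20 harmonics, −12 dB/octave roll-off,
unit RMS) is shaped by a dB-domain envelope: a Tone 3 shape (peak at 1/3)
for syllable 1; an inverse-U (flat-topped) shape for Tone 1 and an inverse-V
for Tone 4; −20-dB anchors at 3%/97% of the syllable; a voiced
inter-syllable gap 30 dB below the peaks by default (15 dB in the
`shallow_dip` testing mode that exercises prominence relaxation); 400-ms
silent pads. Syllable 1's F0 is a fall-then-shallow-rise spanning 2.5 st
with the minimum at 2/3 of the window (position configurable). A
`breathiness` parameter mixes in envelope-shaped noise to lower periodicity
strength for testing the voicing-threshold fallback.

**Generator–analyzer calibration.** A 30-ms RMS window blurs any envelope,
so physical durations and peak gains are calibrated against an
envelope-domain prediction of what the analyzer will measure (same
smoothing, same 5-ms frame grid, same crossing interpolation); continuum
tokens get a final audio-domain refinement because a pulse-train-like 60-Hz
source interacting with the steep offset decay shifts the measured crossing
by ~1 ms. Syllable 2's F0 ramp is laid over the predicted window, widened by
L/(L−30) so the 30-ms edge means recover the requested movement, and
extended at constant slope to the physical syllable edges so tracker frames
near the window edges average over the continuing ramp rather than a held
value. The truth table therefore contains values the analyzer should
reproduce exactly up to tracking error, and the recovery tests bound that
error (duration ±2%, intensity ±0.5 dB, F0 measures ±0.5 st).

**Listeners.** P(Tone 1) = lapse/2 + (1−lapse)·logistic(intercept +
β_F0·fall + β_dur·centered-log-duration + β_height·height-contrast).
Group-mean defaults: intercepts 4.5 (NH) / 2.0 (CI), β_F0 −20.7 / −4.3,
β_dur 6.6 in both groups, β_height 0. The default lapse is 0 — the
generative twin of the fitted model, which has no lapse parameter.
Between-listener SDs are 1 (intercept), 3 (F0 slope and duration), 0.5
(height), common across groups. The F0-slope SD deserves a note: a draft
used group-specific SDs (6 vs 2) to echo the observed variance
heterogeneity, but the fitted model — whose random covariance is shared
across groups by design — then attenuates the NH group coefficient by ~4%
purely through generator/model mismatch. Since the only stated anchor for
this SD is 3, the common value was adopted; heteroscedastic worlds remain
available through per-listener overrides.

**What a green test does not establish.** The generator produces voiced,
harmonically clean, fixed-shape syllables. It does not emulate consonant
articulation (/n/, /ŋ/ codas that motivated the 10-dB variant), formant
dynamics, creak or diplophonia, background noise, microphone coloration, or
the irregular timing of real child speech. Recovery results therefore
validate the *pipeline's correctness*, not its robustness to every
pathology of real recordings; the fallback logic is exercised only through
the stylized breathy/high-register/shallow-dip modes.

## 6. Numerical choices and degenerate inputs

* All-zero audio: intensity contour at the −100 dB floor; tracking returns
  all-unvoiced; no exceptions.
* Segmentation failure (fewer than two peaks at the 6-dB prominence floor)
  raises a classed condition (`tonelab_segmentation_failure`) carrying the
  contour.
* Insufficient voiced material marks a descriptor unavailable (`NA` with a
  reason attribute) rather than erroring, and `analyze_cohort` carries
  availability flags through the tidy table.
* Ties in peak selection are broken by prominence, then height, and reported
  in temporal order; plateau maxima take the first index.
* Seeds: every stochastic routine derives an independent sub-stream from
  integer seeds (multiplicative hashing into [1, 2^31−2]), so cohorts are
  byte-identical under a fixed master seed regardless of call order.
* WAV output is 16-bit PCM; the read/write round trip is exact to one LSB.

## 7. Known limitations

* The tracker's chirp bias grows with (period/window)²; tokens whose F0
  reaches 60 Hz at a full-octave fall are measured to ~0.017 octave rather
  than the ~0.003 typical elsewhere. The verification regression therefore
  excludes frames with fewer than three periods per analysis window.
* The LME t-test uses residual-style df (n − 4); with 450 observations this
  is indistinguishable from z, and type-I calibration on null cohorts lands
  inside the tested 2–8% band, but small designs should prefer the
  likelihood-ratio route on the returned model objects.
* The coupling analysis assumes perception and production data come from the
  same participants; the pipeline pairs same-index synthetic listeners and
  speakers, which models the join but not any real shared mechanism beyond
  what the generator is told to couple.
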