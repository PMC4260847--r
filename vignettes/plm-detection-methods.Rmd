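---
title: "Methods: noise-adaptive detection of periodic leg movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noise-adaptive detection of periodic leg movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plmad)
```

## The problem

Periodic leg movements (PLM) are stereotyped anterior-tibialis EMG bursts
recurring every few tens of seconds during sleep. Clinical scoring rules
(ASDA 1993, WASM 2006, AASM 2007) define a leg movement (LM) by amplitude —
the EMG must rise 8 µV above baseline and later fall back below 2 µV — by
duration (roughly 0.5–10 s), and define a PLM as a run of four or more LMs
with onset-to-onset inter-movement intervals (IMIs) of 5–90 s. Scoring a
full night by hand is slow and inconsistent, and naive automatic detectors
fail in exactly the places real recordings are hard: cardiac interference
leaking into the leg channel, baseline noise that drifts over the night,
sub-200-ms myoclonic spikes, and leg activity caused by apneas and
hypopneas rather than by a movement disorder. `plmad` implements a detector
that addresses each of these, plus a synthetic polysomnogram generator so
that every stage is testable without any real recording.

## Pipeline

For a recording with leg-EMG channel(s) `x(n)` (µV, sampling rate `fs`):

1. **Channel merge.** Two leg channels are combined per sample (mean by
   default). The cohorts this detector family was designed on used a
   hardware-combined channel; the software mean approximates it and keeps
   the µV scale. Sum and rectified-max rules are available because the
   hardware convention cannot be recovered from the data.
2. **Adaptive cardiac cancellation.** A recursive-least-squares (RLS)
   filter predicts the leg EMG from the ECG channel; the prediction error
   is the EMG without cardiac interference. Defaults: 5 taps, forgetting
   λ = 0.999, initial inverse-correlation diagonal δ = 100. λ near 1 tracks
   slow heart-rate drift without chasing EMG bursts; the source literature
   does not print λ or δ, so these are declared package defaults, exposed
   in the config. When no ECG exists, a self-reference mode predicts the
   channel from a five-sample-advanced copy of itself: smooth, periodic
   QRS interference is predictable across a ~10 ms advance, broadband EMG
   is not. Note the advance is in *samples*: at 100 Hz it spans 50 ms and
   cannot track a QRS-width wavelet, so the mode is only meaningful at the
   ECG-grade rates (≥ 256 Hz) it was designed for. The forward predictor
   will also attenuate genuinely narrowband low-frequency EMG; with no ECG
   channel and low-frequency activity of interest, set
   `adaptive.mode = "off"`.
3. **Noise floor.** η(n) is the centered 20-s moving average of the
   rectified cleaned signal (the mean of raw zero-centered EMG would be
   ≈ 0, so rectification is required). 20 s is twice the maximum LM
   duration, so one movement cannot dominate its own baseline. Edge
   windows shrink to the available samples.
4. **Variable amplitude thresholds.** The displayed equations in the
   source render only as figures, so the package uses the declared form
   that satisfies every stated constraint:
   α(n) = U·(1 + ln(1 + η(n)/L)), β(n) = 0.25·α(n),
   ψ(n) = (α(n) + β(n))/2, with U = 8 µV, L = 2 µV. At η = 0 this reduces
   to the static AASM 8/2/5 µV criteria; α grows with the natural log of
   the noise floor; β/α is the AASM 2/8 ratio everywhere; and the detector
   disables wherever η exceeds 50 µV.
5. **SNR+ (optional).** Where η < 2 µV, the signal is passed through the
   two-tap summing filter y(n) = x(n) + x(n−1): gain 2 at DC, unity at
   fs/3 (33 Hz at 100 Hz), attenuation above. This lifts clearly visible
   but sub-8-µV movements on very quiet baselines without amplifying
   high-frequency noise. It departs from the strict AASM amplitude rule,
   which is why it is a flag and not the default.
6. **Envelope and candidate detection.** The 0.15-s RMS envelope is
   compared with the thresholds by a state machine: onset at the first
   sample strictly above α; close after the envelope stays strictly below
   β for 0.05 s; offset one sample past the last point at or above ψ
   before that drop. The short fall time lets the detector reset quickly
   after transients. Ties are fixed (onset strict `>`, release strict `<`)
   to make the machine unambiguous.
7. **Bridging and duration rules**, in exactly this order: gaps ≤ 0.1 s
   bridged; durations < 0.75 s rejected (0.5 s AASM minimum + 0.25 s of
   filter stretching); survivors within 2.0 s merged (groups alternating
   legs recorded to one channel); durations > 10 s rejected. The order
   matters — a merge-then-reject case is part of the acceptance suite.
8. **Two passes.** First-pass movements inflate η around themselves, so
   the rectified signal inside first-pass LM intervals is replaced by
   β(n)/2 and η and the thresholds are recomputed before the second,
   final pass. Exactly two passes: more would keep lowering the floor and
   breed false positives (as would substituting zero).
9. **AUC screen.** Real movements hold their amplitude; myoclonic spikes
   do not. Each candidate is scored by the trapezoidal integral of the
   rectified signal over its interval, divided by its duration (a mean
   amplitude in µV), and kept iff that is ≥ 0.5 × the mean α over the
   interval. Raw area in µV·s is not dimensionally comparable to a µV
   threshold, which is why the normalized form is the default
   (`detector.auc_mode = "raw"` restores the raw reading). With SNR+ on,
   the screen reads the same boosted signal the thresholds saw — the
   source text is inconsistent on this point, and screening the unboosted
   signal would reject the very sub-8-µV movements SNR+ exists to find.
   An inverted mode returns the rejected candidates, which is a
   fragmentary-myoclonus detector.
10. **Respiratory exclusion.** Movements overlapping
    [onset − 5.0 s, onset + 0.5 s) or [offset − 0.5 s, offset + 5.0 s) of
    any scored respiratory event are excluded; movements deep inside an
    event are kept. The window shape comes from the time-locked EMG
    profile around event boundaries (leg activity peaks a few seconds
    before onset and after offset); the AASM whole-event ± 0.5 s rule is
    available as `respiratory.mode = "aasm2007"` for comparison. Overlap
    (not onset-in-window) semantics are the default because a movement
    straddling a window boundary is still respiratory-linked.

PLM runs are then maximal sequences of ≥ 4 consecutive retained movements
with every IMI in [5, 90] s, measured onset-to-onset; runs continue across
sleep–wake transitions. An out-of-range IMI breaks the run at the
offending movement (AASM-style); the WASM reading, where a movement
arriving < 5 s after the last is ignored, is `plm.short_imi = "ignore"`.

## Subject metrics

* **PLMS/h, PLMW/h** — run-member movements whose onset epoch is
  sleep/wake, per hour of sleep/wake. Undefined (NA) when the denominator
  is zero. Recordings under 2 h are flagged `reliable = FALSE`.
* **Periodicity index** — fraction of IMIs in [10, 90) s that sit in runs
  of ≥ 3 consecutive such intervals; near 1 for strongly periodic nights.
  The definition follows the convention of the index's originators, which
  the source paper cites without restating; bounds and run length are
  config keys. Whether sleep-only filtering should drop wake-spanning
  IMIs is ambiguous in the literature; the package filters movements by
  stage at onset and recomputes IMIs within the filtered set.
* **Night ratios** — events in the first half of the study over events in
  the second half; NA (never 0 or ∞) when either half is empty.
* **Heart-rate response** — for each run-member movement, instantaneous HR
  (60/RR) for ten cardiac cycles before and after onset, normalized by the
  cycle immediately preceding onset; delta = max(post) − min(pre), slope =
  delta / cycles between that min and max. R peaks come from a
  Pan-Tompkins-style energy detector (any detector meeting the R-peak
  tolerance would be conformant; this one is plumbing, not contribution).

## The synthetic generator: what it does and does not establish

`synth_spec()`/`synth_psg()` generate: Gaussian baseline noise with a
piecewise σ schedule and a ±10% 30-min sinusoidal drift; movement bursts
as 20–45 Hz band-limited noise (straddling the 33 Hz SNR+ crossover, so
boost tests are meaningful) under a trapezoidal envelope, isolated or in
periodic trains with jitter; < 200 ms myoclonus transients; a QRS-like
wavelet ECG at a set rate with a scalar leak coefficient into the EMG;
respiratory events with a leg burst planted at a fixed lag after each
offset; and a plausible hypnogram (wake onset, 90-min cycles, brief
awakenings). Every planted structure is returned as ground truth, and a
fixed seed makes the output byte-identical (the caller's RNG stream is
saved and restored).

Defaults state the intended world: 8 h at 100 Hz, 2 µV baseline, 25–30 µV
bursts of 1.5–3 s, 60 bpm ECG with 30 µV R peaks and leak 0.5. These are
typical surface-EMG figures for a quiet, well-instrumented night and are
not tuned to any test outcome.

What the generator does **not** emulate: real EMG spectra and amplitude
distributions, movement-to-movement morphology variation, arousals,
sleep-stage-dependent noise, electrode pops, or ECG morphology beyond a
smooth periodic wavelet. A green planted-burst test therefore establishes
that the detector mechanics are correct (thresholding, timing rules,
screening, run logic), not that clinical sensitivity on real
polysomnograms matches the published cohort figures — those depend on
recordings this package cannot ship.

## Numerical choices

* Intervals are half-open `[onset, offset)` in float seconds; sample
  indices are 0-based. A time `t` maps to sample `ceil(t·fs)` (with a
  1e-9 guard), so grid-aligned events are exact.
* Centered moving windows of even length W are left-biased
  (`[n − W/2, n + W/2 − 1]`) and shrink at the edges; the moving averages
  are cumulative-sum based and are verified against an O(N·W) brute-force
  oracle.
* The RLS warm-up (first `n_weights` samples, plus the advance in
  self-reference mode) is passed through unchanged; a constant-zero
  reference is a warned no-op.
* EDF output uses 1-s records, a symmetric physical range rounded up 1%
  from the channel extrema, and the full signed 16-bit digital range;
  round-trips are exact to one quantization step. Channels with differing
  rates are linearly interpolated onto the leg-EMG grid before
  cancellation — no FIR-design facility is available in the dependency
  set, and the canceller exploits QRS periodicity, not fine morphology.
* Candidates still open at end-of-signal or at a noise shutoff are closed
  at their last ψ-crossing and flagged rather than dropped.

## Known limitations

* Per-leg separate scoring is not implemented (combined-channel scoring
  was the design target).
* Arousal association and PLM-arousal indices are out of scope.
* The threshold equations are this package's declared form; they satisfy
  all published constraints but are not a transcription of the original
  displayed math, which is unavailable in the source text.
* The acceptance-grade sensitivity/specificity figures are properties of
  the synthetic world described above.

## A worked example

```{r example, eval = FALSE}
spec <- synth_spec(
  duration_h = 0.5, seed = 7,
  trains = data.frame(start_s = 300, count = 10, imi_s = 30,
                      duration_s = 1.5, amplitude_uv = 25, jitter_s = 1),
  hypnogram_stages = rep("S2", 60))
psg <- synth_psg(spec)
det <- detect_lm(psg$recording, psg$hypnogram)
r_peaks <- detect_r_peaks(psg$recording$traces$ecg)
compute_subject_metrics(det$events, psg$hypnogram,
                        psg$recording$duration_s, r_peaks = r_peaks)
```

All ten planted movements are recovered (`lm_count = 10`), they form one
periodic run (`plm_count = 10`, `periodicity_sleep = 1`), and the index is
10 movements / 0.5 h = 20 PLMS/h. See the README for the printed output.
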