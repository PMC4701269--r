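---
title: "Methods: pitch tracking, voicing, prosodic features and mood correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pitch tracking, voicing, prosodic features and mood correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicemark)
```

`voicemark` implements a complete speech-prosody monitoring chain:
per-frame F0 and pitch strength by sawtooth-spectrum matching, voiced
segmentation, per-segment features, per-recording summaries, chain
agreement statistics, and Spearman correlation of longitudinal summaries
with clinician-rated mood. This vignette records the model, its
assumptions, the numerical choices, and what the synthetic-data tests do
and do not establish.

## The pitch model and its assumptions

Voiced speech is modelled as a locally periodic signal whose spectrum
concentrates energy at harmonics of the fundamental with roughly
decaying amplitude, like a sawtooth. `estimate_pitch()` scores each
candidate fundamental `fc` by how well an idealised sawtooth template
matches the observed spectrum:

1. The frame's magnitude spectrum is interpolated (natural cubic spline)
   onto a grid uniform on the ERB auditory scale
   (`erb = 21.4·log10(1 + 0.00437·f)`, step 0.1 ERB from a quarter of
   the lowest candidate to Nyquist) and square-root compressed. The
   compression is an amplitude/loudness compression: it de-emphasises the
   strongest harmonics so that the full harmonic pattern, not just the
   spectral peak, drives the match.
2. The candidate's kernel has positive cosine lobes at its first and
   prime-numbered harmonics and negative half-weight valleys between
   them, with a `1/sqrt(f)` decay envelope. Restricting lobes to prime
   multiples prevents a candidate at `fc/2` or `fc/3` from inheriting
   the full score of `fc` (octave/sub-harmonic errors), because composite
   harmonics contribute to the valleys of the wrong candidate.
3. Pitch strength is the cosine similarity between the unit-normalised
   compressed spectrum and the unit-normalised kernel, guaranteeing
   values in [-1, 1] and invariance to positive amplitude scaling of the
   input. The frame F0 is the strength-maximising candidate on a
   1/96-octave grid, refined by parabolic interpolation in log frequency;
   the frame strength is the maximum and serves as the voicing
   confidence downstream.
4. Each candidate is analysed with the two power-of-two window sizes
   (Hann) bracketing its optimal window of eight pitch periods, blending
   the two strengths linearly in log window size. Windows are centred at
   `t = i·hop` from 0 and zero-padded at the signal edges; frames whose
   largest window contains only zeros are flagged missing (`f0 = NA`,
   strength 0) rather than dropped, keeping the track uniform.

Two deliberate differences from the widely used reference formulation of
this estimator: the kernel is normalised by its full Euclidean norm (a
true cosine similarity, so the [-1, 1] bound is exact) rather than by the
norm of its positive part, and spectra are computed at the output frame
rate rather than at a coarse half-window hop with temporal interpolation
of strengths. The first changes only the scale of strengths (thresholds
are swept and selected empirically anyway); the second makes each frame's
strength reflect its own window, which matters for frame-to-frame
variability features.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `f_min`, `f_max` | 75, 500 | Hz | adult conversational speech, both sexes |
| `hop` | 0.01 | s | 3000 frames per 30-s task; the text export stays small |
| `candidate_step` | 1/96 | octave | ~0.7% grid; parabolic refinement goes sub-grid |
| `erb_step` | 0.1 | ERB | auditory-uniform spectral sampling |
| strength `threshold` | swept | — | chosen per speaker on the specificity/sensitivity curve |
| `min_segment` | 0.02 | s | two frames, the minimum on which stdF0/jitter exist |
| energy/ZCR: `frame`, `energy_quantile`, `zcr_threshold` | 0.03 s, 0.5, 3000 /s | — | voiced speech crosses zero a few hundred times per second, noise thousands |
| `min_overlap` (matching) | 0.02 | s | two frames needed to recompute variability features |
| `grid_step` (confusion) | 0.001 | s | finer than any hop, so rounding cannot dominate counts |
| QIDS / YMRS cut-offs | 8 / 6 | score | standard clinical thresholds for depressive / hypomanic state |

Threshold selection (`choose_threshold()`) keeps points with specificity
> 0.9 and sensitivity > 0.6 and returns the most sensitive one (ties to
the smaller threshold). Specificity is favoured deliberately: analysing
an unvoiced stretch as voiced corrupts features, while missing a voiced
stretch only loses data.

## Statistics

*Features.* Per segment: arithmetic mean F0; sample standard deviation
(n−1); local jitter `mean|T(i+1)−T(i)|/mean T(i)` over frame periods
`T(i)=1/f0(i)` — the standard "local" relative jitter, computable from an
exported F0 track. Per recording: sample median, unscaled MAD (no 1.4826
factor — it is reported descriptively, not as a σ estimate), and moment
skewness `g1 = m3/m2^1.5` (needs ≥ 3 segments).

*Agreement.* Frame confusion rasterises both segmentations to a 1-ms
grid with the reference as truth. Matched segments are paired greedily
by descending overlap (one-to-one), and features are recomputed on the
intersection interval in both tracks from frames whose centres fall
inside it; agreement is Pearson's r with the usual t-based p (n−2 df).
Pearson (not rank) correlation is used here because feature agreement is
a calibration question — rank correlation is reserved for the ordinal
mood analysis.

*Kolmogorov–Smirnov.* `ks_compare()` computes
`D = sup|ECDF_a − ECDF_b|`; the p-value is exact by enumerating all
`choose(na+nb, na)` pooled reassignments when `na+nb ≤ 12` (valid under
ties), otherwise asymptotic via the Kolmogorov distribution with
effective size `na·nb/(na+nb)`.

*Spearman.* Pearson correlation of mid-ranks; exact two-sided p by full
`n!` enumeration for `n ≤ 9` (cheap, and longitudinal cohorts are small),
t approximation above. The mood ordinal is coded hypomanic = 1,
euthymic = 2, depressive = 3; any strictly increasing coding gives the
same rank correlation — 1/2/3 is for readability. Mixed-state sessions
(both scales above cut-off) are excluded with a warning rather than
coded: simultaneous depressive and manic symptoms do not sit on a single
mania–depression dimension.

## The synthetic-data generator

`synth_render()` turns an event script (voiced / unvoiced / silence)
into audio with exact ground truth. Voiced events are harmonic series
`Σ_k sin(2πk·φ(t))/k` (ten harmonics by default, capped below Nyquist —
matching the estimator's sawtooth assumption and giving a strong
positive control), with phase integrating a linear F0 contour. Period
jitter is injected at the cycle level: each period's F0 is multiplied by
`1 + ε`, `ε ~ N(0, jitter_level)` i.i.d., which is the construct the
downstream jitter statistic measures. Unvoiced events are white
Gaussian noise, silence is exact zeros; everything is seeded and
bit-reproducible, and event sample counts are allocated from the
cumulative timeline so the rendered total is exact.

The standard fixture (`synth_speech_script()`) emulates a 30-s read
-speech task: cycles of a voiced stretch (0.3–0.8 s, F0 drawn from
110–320 Hz with a ramp), a weaker noise burst (0.15–0.35 s, amplitude
0.1 versus 0.8 for speech) and a pause (0.2–0.5 s). Defaults mirror the
emulated acquisition: 48 kHz sampling, 30-s tasks, 10-ms hop.

What the generator does **not** emulate: formants and consonant
structure, breathiness/aspiration noise mixed into voicing, room
acoustics and environmental noise, microphone responses. Passing tests
therefore establish algorithmic correctness (the chain recovers known
truth under its own signal model), not field performance on real
recordings — in particular the clean fixture separates voiced from
unvoiced at much lower strength thresholds than noisy speech would.

The cohort generator (`synth_cohort()`) emulates a 15-session monitoring
study (2 depressive, 4 hypomanic, 9 euthymic assessments) in which the
MAD of mean F0 follows a monotone link with the mood ordinal: baseline
12 Hz, slope 4 Hz per ordinal step, 2.5 Hz session noise — a
within-patient effect clearly larger than session-to-session
variability, as a monitoring application presupposes. Scores are drawn
consistently with the scripted states; other summary statistics carry no
mood link, providing negative controls.

## Numerical choices and degenerate inputs

* Frame times start at 0; a track of duration `d` has `floor(d/hop)`
  frames. Segment bounds are frame centres ∓/± half a hop, clamped to
  the recording, so an interior run of n frames has length `n·hop`
  exactly while an edge-adjacent run loses half a hop to the clamp.
* Strict inequality (`strength > threshold`) decides voicing, so
  sweeping a threshold equal to every strength yields no segments.
* All-zero audio: every frame missing, strength 0, no segments from
  either detector; empty segment lists are legal everywhere downstream
  except where a statistic is undefined, which raises an explicit error
  (fewer than 3 matched pairs, zero variance, constant ordinal).
* Exact-p branches switch at `na+nb ≤ 12` (KS) and `n ≤ 9` (Spearman);
  enumeration tolerances use a `1e-12` slack when counting
  `|statistic| ≥ observed` to absorb floating-point ties.
* The parabolic refinement offset is clamped to half a candidate step,
  and refined strengths are clamped to [-1, 1].

## Problem sizes in the shipped tests

Unit tests run the tracker on 0.3–1-s signals, mostly at 16 kHz (the
estimator is rate-agnostic; lower rates keep the suite quick). The
acceptance-style checks use the full study conditions: a 30-s, 48-kHz
fixture for segmentation and payload checks, twenty 1-s seeded renders
for jitter recovery, and 200 seeded cohorts for the longitudinal sign
check.

## Known limitations

* **Jitter attenuation.** The estimator's analysis windows span about
  eight pitch periods, so frame-level F0 averages over many cycles and
  i.i.d. cycle-level period perturbation is substantially attenuated in
  the exported track: the measured local jitter recovers the injected
  level only up to a factor well below one (the jitter-recovery check in
  the acceptance suite quantifies this at 200 Hz). Measured jitter
  responds monotonically to the injected level and sits far above the
  clean-signal floor, so it remains usable as a relative, within-subject
  feature — but absolute cycle-level jitter would require waveform-level
  period marks, not an F0 track.
* Thresholds are speaker- and channel-dependent; the sweep must be
  redone per configuration.
* The exported track file truncates F0 to 0.01 Hz and strength to 0.001,
  which bounds but does not eliminate re-analysis differences after a
  round trip.
* The mood analysis treats sessions as exchangeable observations; it
  ignores serial dependence across a monitoring period.
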