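# voicemark

Speech prosody is modulated by mood: average fundamental frequency (F0),
its variability and cycle-to-cycle period perturbation (jitter) all shift
with depressive and (hypo)manic states in bipolar disorder. `voicemark` is
a desk-scale R toolkit for the full analysis chain behind that kind of
longitudinal speech monitoring: it turns a plain speech recording into a
compact per-frame feature file, detects voiced segments, computes per-segment
prosodic features and robust per-session summaries, quantifies agreement
between two analysis chains, and correlates session summaries with
clinician-rated mood states. It is aimed at researchers prototyping speech
biomarker pipelines who need every stage testable against synthetic ground
truth.

## The core method

**Pitch and pitch strength by sawtooth-spectrum matching.** For each
analysis frame the magnitude spectrum |X(f)| is interpolated onto a grid
uniform on the ERB auditory scale, `erb(f) = 21.4 log10(1 + 0.00437 f)`,
and square-root compressed, `L(f) = sqrt(|X(f)|)`. Each pitch candidate
`fc` on a log2-spaced grid (step 1/96 octave, 75–500 Hz by default)
carries a sawtooth-harmonic kernel `K_fc`: positive cosine lobes at the
first and prime-numbered harmonics of `fc`, negative valleys between them,
lobe weight decaying as `1/sqrt(f)`. The *pitch strength* of a candidate is
the cosine similarity

```
S(fc) = <K_fc, L> / (||K_fc|| ||L||)   in [-1, 1],
```

computed with the two power-of-two window sizes bracketing the candidate's
optimal window of eight pitch periods and blended linearly in log window
size. The frame F0 is the strength-maximising candidate refined by
parabolic interpolation; the frame strength is that maximum and acts as a
voicing confidence.

**Voicing, features, summaries.** Voiced segments are maximal runs of
frames with strength above a threshold chosen on a
specificity/sensitivity sweep (specificity > 0.9 and sensitivity > 0.6,
specificity being favoured); a reference detector based on short-time
energy and zero-crossing rate is included. Per segment the toolkit
computes mean F0, the F0 standard deviation, and local jitter
`mean|T(i+1) - T(i)| / mean T(i)` over frame periods `T(i) = 1/f0(i)`;
per recording it summarises each feature across segments by median,
unscaled MAD and moment skewness. Session summaries are correlated with
the clinician's mood ordinal (hypomania = 1 < euthymia = 2 < depression
= 3, from QIDS >= 8 and YMRS >= 6 cut-offs) by Spearman rank correlation
with exact small-sample p-values; chain agreement uses frame-level
sensitivity/specificity, Pearson correlation of features recomputed on
overlapping segment portions, and an exact/asymptotic two-sample
Kolmogorov–Smirnov test.

Every stage is exercised end-to-end against a seeded synthetic
running-speech generator (harmonic events with linear F0 contours and
controlled period jitter, noise bursts, silence) whose ground truth is
exact by construction.

## Worked example

```r
library(voicemark)
library(dplyr)

res   <- synth_render(synth_speech_script(dur = 10, seed = 42), seed = 42)
track <- estimate_pitch(res$audio)
track
#> # A pitch track: 1000 frames, hop 0.01 s, rate 48000 Hz
#> # A tibble: 1,000 x 3
#>    time    f0 strength
#>   <dbl> <dbl>    <dbl>
#> 1  0     284.    0.212
#> 2  0.01  285.    0.496
#> 3  0.02  285.    0.568
#> # i 997 more rows

curve <- sweep_threshold(track, res$truth_segments,
                         thresholds = seq(0.02, 0.6, length.out = 30))
glance(curve)
#> # A tibble: 1 x 4
#>   chosen_threshold sensitivity specificity admissible
#>              <dbl>       <dbl>       <dbl> <lgl>
#> 1             0.06           1       0.950 TRUE
```

On this clean fixture every reference-voiced frame is recovered
(sensitivity 1) while 95% of unvoiced frames are rejected at the chosen
pitch-strength threshold 0.06; real recordings need higher thresholds
because noise raises the strength floor. Continuing:

```r
segments <- segment_by_strength(track, threshold = 0.06)
segments |>
  segment_features(track = track) |>
  summarize_features()
#> # A tibble: 3 x 5
#>   feature    median      mad skewness n_segments
#>   <chr>       <dbl>    <dbl>    <dbl>      <int>
#> 1 mean_f0 231.      58.8        0.210         13
#> 2 std_f0    6.09     1.78       2.70          13
#> 3 jitter    0.00200  0.00138    2.01          13
```

The 13 voiced segments have a median mean-F0 of 231 Hz with a 59-Hz MAD
(the scripted contours span 110–320 Hz), a few Hz of within-segment F0
spread, and residual jitter of 0.2% on unjittered input. `autoplot(track,
segments = segments)` draws the F0 and strength traces with the detected
segments shaded; `longitudinal_report()` takes a stack of such summaries
plus an assessments table and returns the Spearman correlation of every
summary statistic with the mood ordinal.

A command-line interface over the whole chain (subcommands `synth`,
`track`, `segment`, `features`, `summarize`, `compare`, `sweep`, `mood`)
is available via `run_cli()` or the `inst/cli/voicemark` script.

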