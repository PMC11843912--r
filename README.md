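# courtbeat

Acoustic timing assessment for tennis: detect ball–racket **impacts** and
ground **rebounds** in court audio, validate them with two trained sound
classifiers, and turn the validated events into

* **rally rhythm** — shots per minute during a baseline rally, and
* **groundstroke executive timing** — the time between the ball's bounce and
  its impact on the strings,

with agreement statistics (ICC(3,1), Cohen's weighted kappa, Bland–Altman,
Spearman, Mann–Whitney, CV% by the root-mean-square method) for comparing
the acoustic measurements against a reference such as video analysis. It is
aimed at sports scientists and coaches who want objective temporal metrics
from a single commodity microphone.

## Method

Rally impacts are picked on the raw normalized waveform (|x| peaks > 0.4,
minimum separation 390 ms). With `n` near-player impacts over a span of `T`
seconds the rhythm module infers `2n − 1` total rally shots (one opponent
shot per same-player interval) and reports the instantaneous frequency
`120/Δt` per interval and the average `(2n − 1)/T × 60` shots/min.

Groundstroke candidates are picked on a zero-phase 5th-order Butterworth
band-pass (100–400 Hz) of the signal: impact candidates above 0.09 and
rebound candidates above 0.02 with 100 ms separation, rebounds searched
1.5–0.4 s before each impact. Because the rebound often sits at ambient
noise level, candidates are validated by classifiers trained on labeled
0.3 s segments:

* impact vs. noise — gradient-boosted trees (η = 0.1, 300 trees, depth 3);
* rebound vs. noise — soft-voting ensemble of boosted trees (η = 0.05, 500
  trees, depth 5), an RBF SVM (C = 1, γ = "scale") and a 100-unit ReLU/Adam
  perceptron.

Features per segment: per-bin spectrogram mean/sd/max (STFT, 320-sample Hann
window, zero-padded to 512), argmax-energy frequency, zero-crossing rate,
spectral centroid, 13 MFCCs, time-domain statistics, plus tonnetz, spectral
contrast and chroma for the rebound problem; ANOVA-F best-k selection.
Executive timing is `t_impact − t_rebound` per validated pair.

A deterministic synthetic court-audio generator (sharp broadband impact
bursts, 100–400 Hz rebound thumps, wind/voice/traffic/crowd ambient plus
non-ball transients) provides the labeled training bank — 509 noise, 442
rebound, 448 impact clips by default — and fully annotated scenes, so the
whole system trains and validates offline. See the methods vignette
(`vignettes/acoustic-timing.Rmd`) for the model, parameter and design
discussion.

## Worked example

```r
library(courtbeat)

# a rally scene: 8 near-player impacts spanning 23.03 s,
# 7 attenuated opponent impacts in between, wind ambient
scene <- render_scene(scene_preset("rally1", seed = 7))
peaks <- detect_rally_impacts(scene$clip)
rally_rhythm(peaks$time_s)
#> <rally_report> 8 near-player impacts (15 total shots inferred) in 23.03 s
#>   average 39.08 shots/min; instantaneous 36.5, 36.5, 36.5, 36.5, 36.5, 36.5, 36.5
```

8 detected near-player impacts over 23.03 s give 15 inferred rally shots and
an average rhythm of 39.08 shots/min; the instantaneous values are `120/Δt`
per same-player interval (3.29 s here, hence 36.5).

```r
# train the classifiers on the default synthetic bank and time groundstrokes
bank   <- gen_sample_bank(bank_spec(seed = 42))
bundle <- train_court_models(bank, seed = 1, cv = TRUE)
bundle$cv_reports$impact
#> <cv_report> 5-fold accuracies: 0.9792, 0.9792, 0.9740, 0.9948, 0.9947 (median 0.9792)
bundle$cv_reports$rebound
#> <cv_report> 5-fold accuracies: 0.9948, 0.9948, 1.0000, 1.0000, 1.0000 (median 1.0000)

drill  <- render_scene(scene_preset("g1", seed = 33, n_shots = 10,
                                    ambient_snr_db = 50))
events <- classify_events(drill$clip, bundle)
summarize_timing(executive_timing(events), ground_truth_n = 10)
#> <timing_summary> n = 10 (missing 0), median 0.808 s; IQR 0.065 s
```

Each of the ten shots is recovered as an impact/rebound pair; the median
executive timing of ~0.81 s matches the drill preset, and recovered timings
sit within a few milliseconds of the injected ground truth.

A thin command-line wrapper over the same functions ships in
`inst/cli/courtbeat.R` (`synth`, `train`, `detect`, `agree` subcommands).

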