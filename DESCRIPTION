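Package: courtbeat
Title: Acoustic Detection of Tennis Ball Impacts for Rally Rhythm and
    Groundstroke Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ball-racket impacts and ground rebounds in tennis court
    audio and converts them into rally rhythm (shots per minute) and
    groundstroke executive timing (seconds between the ball's ground rebound
    and its impact on the string bed). Candidate events are found by
    amplitude/interval peak picking (rally impacts on the raw normalized
    waveform; groundstroke candidates on a 100-400 Hz zero-phase Butterworth
    band-passed waveform) and validated by two trained sound classifiers: a
    gradient-boosted tree model for impact-versus-noise and a soft-voting
    ensemble (boosted trees, RBF support vector machine, single-hidden-layer
    ReLU perceptron) for rebound-versus-noise, trained on features extracted
    per segment (per-bin spectrogram statistics, zero-crossing rate, spectral
    centroid, MFCCs, time-domain statistics, plus tonnetz, spectral contrast
    and chroma) with ANOVA-F feature selection. Includes a deterministic
    synthetic court-audio generator with ground-truth annotations for
    training and validation, WAV input/output, five-fold cross-validation and
    grid search, and inter-method agreement statistics (ICC(3,1), Cohen's
    weighted kappa, Bland-Altman, Spearman, Mann-Whitney, CV% by the
    root-mean-square method).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
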