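Package: duosync
Title: Cross-Wavelet Analysis of Interpersonal Coordination in Musical Duos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying interpersonal coordination between two
    ensemble performers from beat onsets and 3-D motion-capture marker
    trajectories. Computes inter-beat-interval tempo summaries, tempo-scaled
    phrase-level period bands, Savitzky-Golay head velocities and quantity of
    motion, Morlet cross-wavelet power and phase difference between the
    performers' head-speed series, phrase-level band aggregates with
    leader-follower calls, and the associated mixed-effects model battery.
    Includes a synthetic duo-cohort generator with known ground truth
    (planted periodicities, lags, tempo drift, and an empathy-leadership
    association) so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
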