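# duosync

Cross-wavelet analysis of interpersonal coordination in musical duos.

## What this package is for

When a pianist and a singer perform together, their heads sway at periods
tied to the musical phrase hierarchy (half a bar up to four bars). `duosync`
quantifies that coordination from two kinds of input: **beat onsets** (score
beat → performed onset time) and **3-D motion-capture marker trajectories**.
It is written for movement scientists and music psychologists who want the
full chain — tempo, kinematics, wavelets, band statistics, mixed models — as
tested, composable functions rather than a one-off analysis script.

The core quantities come from the Morlet **cross-wavelet transform** of the
two performers' head-speed series, `W_xy(s, t) = W_x(s, t) · conj(W_y(s, t))`
with the pianist as first channel:

* `|W_xy|` — strength of joint oscillation at each time and period;
* `arg(W_xy) ∈ (−π, π]` — phase difference: positive in the in-phase regime
  means the pianist's oscillation is earlier in the cycle (pianist leads),
  negative means the singer leads; converted to milliseconds via
  `phase_ms = φ/(2π) · period · 1000`.

Power and phase are grand-averaged (arithmetic / circular mean respectively)
over tempo-scaled narrow bands centred on each phrase level's duration
`mean IBI × beats-per-bar × bars`, classified into leader–follower calls,
and fed to a battery of (mixed) linear models relating coordination to
phrase level, piece, take, musical section, quantity of motion and the
performers' empathic perspective-taking (EPT) scores.

A seeded synthetic-cohort generator (`simulate_cohort()`) plants known
periodicities, lags, tempo drift and an EPT–leadership slope, so every stage
is testable end to end without any recordings.

## Worked example

Simulate six duos whose singers lead by 0.02 s per EPT unit above the
cohort midrange (EPT 18), then run the full pipeline:

```r
library(duosync)

cohort <- simulate_cohort(
  cohort_spec(n_duos = 6, lead_slope = 0.02, noise_sd = 2, seed = 42),
  piece_template(n_bars = 40, fs = 24))
bundle <- analyze_cohort(cohort, pipeline_control(dj = 1/10))

bundle$dominant_table[, c("duo_id", "singer_ept", "dominant_level",
                          "mean_power", "phase_ms", "leadership")]
#>   duo_id singer_ept dominant_level mean_power phase_ms    leadership
#> 1  duo01         24       two_bars       2757   -119.8  singer_leads
#> 2  duo02         12       two_bars       2804    120.8 pianist_leads
#> 3  duo03          8       two_bars       2821    205.8 pianist_leads
#> 4  duo04         17       two_bars       2733     17.6 pianist_leads
#> 5  duo05         11       two_bars       2769    141.4 pianist_leads
#> 6  duo06         25       two_bars       2699   -142.0  singer_leads
```

Every session's dominant phrase level is the planted two-bar level, and the
signed phase (ms) tracks the planted lag: duos with high-EPT singers (24,
25) show negative phase — the singer's oscillation is earlier, the singer
leads — while low-EPT duos show the pianist ahead. The planted lags were
−120, +120, +200, +20, +140, −140 ms; the pipeline recovers them to a few
milliseconds.

The cohort-level regression of phase on the musicians' own EPT scores
recovers the planted slope (−20 ms of phase per singer-EPT unit):

```r
bundle$fits$phase_by_ept
#> <duo_model_fit> phase_ms ~ pianist_ept + singer_ept
#>          term estimate   ci_lo   ci_hi statistic df  p_value
#> 1 (Intercept)  363.598 352.735 374.461   106.518  3 1.82e-06
#> 2 pianist_ept    0.197  -0.522   0.916     0.871  3 4.48e-01
#> 3  singer_ept  -20.394 -20.968 -19.821  -113.213  3 1.52e-06
```

Only the singer's EPT carries the effect, as planted. The Bonferroni
threshold for a 24-model empathy battery is
`bonferroni_threshold(0.05, 24)` = 0.002083.

Individual stages are available separately — `read_beat_table()` /
`interpolate_missing_beats()` / `compute_tempo()` / `phrase_levels()` /
`make_bands()` for tempo, `sg_velocity()` / `speed()` /
`quantity_of_motion()` for kinematics, `morlet_cwt()` / `cross_wavelet()` /
`time_average_power()` for the wavelet core, `band_aggregate()` /
`dominant_level()` / `phase_to_leadership()` / `segment_aggregate()` for
coordination summaries, and `fit_model()` / `tukey_contrasts()` for the
models. `run_pipeline()` drives everything from a YAML or list config and
writes CSV tables plus a JSON metadata sidecar.

See the vignette (`vignettes/duo-coordination.Rmd`) for the methods account:
wavelet conventions, band construction, circular phase averaging, the
leadership quadrant scheme, the model battery with its OLS fallback, and
what the synthetic cohort does and does not demonstrate.

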