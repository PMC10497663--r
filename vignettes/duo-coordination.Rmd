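---
title: "Measuring leader–follower coordination in musical duos with cross-wavelet analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leader-follower coordination in musical duos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duosync)
```

## The problem

When two musicians — here a pianist and a singer in a voice-plus-piano (Lied)
duo — perform together, their body sway organises itself around the musical
structure: head motion oscillates at periods close to half a bar, one bar, two,
three and four bars. Two questions drive the analysis this package implements:

1. **How strongly** do the two performers' periodic head movements align, and
   at which phrase level is that alignment strongest?
2. **Who leads**: is one performer's oscillation systematically earlier in the
   cycle, and does that asymmetry relate to covariates such as the performers'
   empathic perspective-taking (EPT) scores?

Both questions are answered in the time–period plane with a Morlet
cross-wavelet transform (XWT) of the two performers' head-*speed* series.
Speed (the Euclidean norm of 3-D velocity) is used rather than position
because it does not depend on a performer's orientation in the capture volume.

## The measurement chain

### Tempo and phrase-level bands

Beat onsets (at the 1/8-note level) define inter-beat intervals (IBIs); beats
with no performed onset — rests, missed notes — are filled by linear
interpolation in beat index (`interpolate_missing_beats()`), with linear
*extrapolation* at track edges rather than refusal, flagged for auditability.
The mean IBI over a performance is the tempo. Each phrase level then has
duration

$$d_L = \overline{\mathrm{IBI}} \times \text{beats-per-bar} \times
\text{bars}(L), \qquad \text{bars} \in \{\tfrac12, 1, 2, 3, 4\},$$

so the bands are *tempo-adaptive*: every duo, piece and take gets its own
partition. `make_bands()` places a band $[d_L 2^{-h},\, d_L 2^{+h}]$ around
each duration with half-width $h$ in octaves, clips adjacent bands at the
geometric midpoint of neighbouring durations (bands may touch but never
overlap), and clips everything to the broadband period range. The half-width
default $h = 0.25$ octaves is a package choice: it is the widest symmetric
band on a log-period axis that keeps the half-bar and one-bar bands (one
octave apart) from colliding before the midpoint clip engages. The broadband
limits are configuration constants carried in the session manifest (the study
values are 1–26 s for the slow 12/8 piece and 0.2–6.2 s for the fast 2/8
piece); they are treated as given rather than re-derived because no margin
rule reproduces the printed endpoints from the printed IBI ranges.

### Kinematics

Positions are smoothed and differentiated in one pass with a Savitzky–Golay
filter (order 3, window 25 samples — the standard choice for 240 Hz optical
motion capture), via `signal::sgolayfilt(m = 1)`. The filter's boundary rows
fit the same polynomial over one-sided windows, so the velocity series keeps
the full input length and stays aligned with beat timestamps — section
boundaries can fall anywhere in a take. Exactness on polynomials up to the
filter order (including at the boundaries) is part of the test suite.

Quantity of motion (QoM) summarises overall movement energy: for each whole
second, the path length travelled (integral of speed) in mm, summed over the
14 head/upper-body markers of both performers. The per-second *path length*
reading of "sum of velocities per second" was chosen because it realises
"displacement per unit time" and is sampling-rate invariant; a
`mean_speed` mode is available as a config switch. The singer's extra hip
markers are rejected, not silently dropped.

### The cross-wavelet core

`morlet_cwt()` implements the standard FFT formulation of the continuous
wavelet transform with the complex Morlet mother wavelet
$\psi(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}$, unit-energy scale
normalisation, and scales $s = p / \lambda$ for Fourier period $p$ with
$\lambda = 4\pi/(\omega_0 + \sqrt{2 + \omega_0^2})$. Defaults
$\omega_0 = 6$ and $dj = 1/20$ sub-octaves follow common wavelet-analysis
practice; both are configurable and recorded in run metadata.

Numerical choices that matter:

* The wavelet's frequency response is evaluated at **all** frequencies — no
  analytic (Heaviside) cutoff and no admissibility correction term. At
  $\omega_0 = 6$ both terms are $\sim 10^{-8}$ of the peak; leaving them out
  makes the FFT path *mathematically identical* to time-domain convolution
  with $\psi$, which the test suite exploits by checking equivalence with a
  direct-convolution oracle to $10^{-8}$ relative error.
* Zero-padding goes to the next power of two **that also clears the largest
  wavelet's tail** ($8 s_{\max}$), so circular convolution equals linear
  convolution to machine precision rather than only approximately.
* The cone of influence (COI) — the period above which a coefficient is
  edge-contaminated, $p_{\mathrm{coi}}(t) = \lambda\,
  \min(t, T - t)/\sqrt2$ — is computed and stored but **not** used to mask
  averages by default, matching an analysis that averages across all
  timestamps; `coi_mask = TRUE` and per-call masks enable exclusion.
* Series are mean-centered but not variance-normalised by default
  (`standardize` flag). Absolute power levels therefore depend on signal
  units; only relative comparisons across bands/conditions are meaningful.

`cross_wavelet()` forms $W_{xy} = W_x \overline{W_y}$ with the pianist as
first channel. Power is $|W_{xy}|$ by default (squared available). The phase
difference $\arg W_{xy} \in (-\pi, \pi]$ is positive when the pianist's
oscillation is earlier in the cycle. Swapping the inputs negates the phase
and leaves power unchanged — the suite tests this antisymmetry.

### Aggregation and leadership calls

`band_aggregate()` grand-averages over all (period, time) cells of a band:
arithmetic mean for power, **circular (phasor) mean** for phase. Arithmetic
averaging of angles is simply wrong near $\pm\pi$, so the circular mean is
the default and the mean resultant length $R \in [0, 1]$ is reported as a
reliability diagnostic ($R \approx 0$ means the phase distribution is close
to uniform and the mean phase is uninformative); an arithmetic fallback
exists behind a flag for comparison. The aggregated phase is converted to
milliseconds using the **level duration** as the period,

$$\Delta t_{\mathrm{ms}} = \frac{\varphi}{2\pi}\, d_L \times 1000,$$

a choice that has to be made because a band-aggregated phase no longer has a
unique period; it is recorded in the output.

Leadership follows the quadrant scheme: $\varphi \in (0, \pi/2)\,\cup\,
(-\pi, -\pi/2)$ means the pianist leads, $\varphi \in [-\pi/2, 0)\,\cup\,
[\pi/2, \pi]$ the singer; $\varphi = 0$ is perfectly in sync; motion is
in-phase for $|\varphi| < \pi/2$ and out-of-phase beyond. The printed closed
intervals overlap at the boundary angles, so ties are resolved explicitly:
$\pm\pi/2$ and $\pi$ go to the upper interval (singer), and
$|\varphi| = \pi/2$ is labelled out-of-phase and flagged.

Peaks of the time-averaged power curve (`find_top_peaks()`) are strict local
maxima; plateaus count once at their left-most index, power ties break
toward the longer period, and "top three" means the three highest (or all,
if fewer exist). These conventions are package inventions — "peak" has no
canonical definition at this granularity — and are stated here because
Table-2-style occurrence counts depend on them.

### The model battery

`fit_model()` covers the battery the aggregate tables support:
`power ~ phrase_level/take`, `power ~ piece/take`,
`phase ~ piece/take`, `power/phase ~ EPT group`,
`power/phase ~ pianist EPT + singer EPT`,
`phase ~ singer EPT/section`, and
`QoM ~ pianist EPT + singer EPT + piece/take`. Nested `A/B` terms expand as
`A + A:B`. Models with a duo random intercept are fitted by REML
(`lmerTest`); when the random-intercept variance is below $10^{-3}$ of the
residual variance or the fit is singular, the model is automatically refit
by OLS and flagged — the same pragmatic fallback the underlying analysis
procedure uses. Any converging REML optimizer is acceptable; the package
asserts recovery and fallback *properties*, not optimizer equality.
Marginal/conditional $R^2$ use the Nakagawa variance decomposition; post-hoc
pairwise comparisons use Tukey-adjusted `emmeans` contrasts; the familywise
correction for a battery of $m$ models is Bonferroni, $\alpha/m$ (24 models
at $\alpha = 0.05$ gives the threshold 0.002083).

Factor baselines default to the four-bar level, take 0, and the slower piece,
all configurable through `model_spec()`.

## The synthetic cohort and what it does (not) show

Real duo recordings are not shipped; `simulate_cohort()` generates sessions
with known ground truth instead:

* **Beats**: IBIs follow $\mathrm{IBI}_0 (1 + \delta \sin 2\pi u)$ over the
  piece (default drift $\delta = 0.05$), with a seeded 5% of onsets blanked.
* **Motion**: front-head *velocity* is planted — a constant base speed plus
  sinusoidal components at phrase-level periods, directed along a fixed
  oblique unit vector, plus white Gaussian noise per axis; positions are the
  cumulative integral. Planting velocity (not position) puts the spectral
  ground truth exactly where the pipeline looks. Riding the oscillation on a
  base speed (default twice the summed amplitude) keeps the *speed* series
  linear in the planted sinusoid instead of rectified at half the period.
* **Leadership**: the singer's copy of the dominant component is delayed by
  $-\ell\,(\mathrm{EPT}_{\mathrm{singer}} - \overline{\mathrm{EPT}})$
  seconds with lead slope $\ell$ (default 0.02 s per EPT unit, which spans
  roughly $\pm 200$ ms of lead across the default EPT range 8–28 — the
  order of magnitude of head-motion asynchronies in slow repertoire).
  Positive planted lag means the pianist leads and maps to positive XWT
  phase.
* All randomness flows from one master seed; identical spec + seed gives
  byte-identical cohorts.

The default template is a short duple-meter piece: 2 beats per bar, base IBI
0.5 s (half bar 0.5 s … four bars 4 s), broadband 0.2–6.2 s, A/B/A′ form
with a piano-solo middle section, dominant component at two bars (10 mm/s)
plus a half-bar secondary (4 mm/s), noise 2 mm/s.

What passing tests on this cohort **do** show: the full chain — tempo
extraction with missing beats, SG speed, XWT, band aggregation, circular
phase averaging, ms conversion, model fitting — recovers planted periods,
lags, signs and slopes to a few milliseconds. What they do **not** show:
robustness to non-stationary tempo-following coupling, marker dropout,
broadband (1/f) movement noise, or biomechanically realistic motion. Those
are explicitly out of the generator's scope.

## Problem sizes and runtime choices

Simulation-heavy checks run at deliberately scaled-down study conditions,
chosen once as this package's test conditions: cohorts of 20–24 duos at
36–60 s per session and 16–60 Hz sampling (the planted periods are fully
oversampled at 8× Nyquist or better), scale resolution $dj = 1/10$ for bulk
cohort runs versus the 1/20 analysis default, and a 200-replicate null
cohort for the false-positive-rate check, each replicate measured on the
dominant band only (band restriction changes nothing: wavelet scales are
computed independently). At these sizes the whole suite runs in about a
minute on one core.

## Known limitations

* No wavelet *coherence* (smoothed, normalised cross-spectrum) and no
  simulation-based significance contours; power and phase are reported raw.
* Gap-free trajectories are required; marker-gap filling and rigid-body
  reconstruction are out of scope.
* The phase-to-ms conversion assumes the band's level duration as the
  period; within-band period spread is folded into the circular-mean
  diagnostic $R$, not into the ms value.
* Section aggregation assumes sections partition the piece in score beats
  and maps them to time through the (interpolated) beat track; sub-beat
  section boundaries are not representable.
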