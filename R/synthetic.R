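#' Planted oscillatory component for synthetic duo motion
#'
#' @param level phrase level the component lives at (one of
#'   \code{"half_bar"}, \code{"one_bar"}, \code{"two_bars"},
#'   \code{"three_bars"}, \code{"four_bars"}).
#' @param amplitude velocity amplitude in mm/s.
#' @param lag_s signed lag in seconds: positive = the pianist's oscillation is
#'   earlier in the cycle (pianist leads).
#' @param time_support optional \code{c(t0, t1)} seconds during which the
#'   component is active (half-open); \code{NULL} = whole recording.
#' @return Object of class \code{planted_component}.
#' @export
planted_component <- function(level, amplitude, lag_s = 0,
                              time_support = NULL) {
  level <- match.arg(level, PHRASE_LEVEL_NAMES)
  if (!is.numeric(amplitude) || amplitude < 0)
    stop_ds("amplitude must be non-negative")
  if (!is.null(time_support) &&
      (length(time_support) != 2L || time_support[1L] >= time_support[2L]))
    stop_ds("time_support must be c(t0, t1) with t0 < t1")
  structure(list(level = level, amplitude = amplitude, lag_s = lag_s,
                 time_support = time_support),
            class = "planted_component")
}

#' Generate a beat track with tempo drift and missing onsets
#'
#' Inter-beat intervals follow \code{base_ibi_s * (1 + drift_fraction *
#' sin(2*pi*u))} where \code{u} runs from 0 to 1 over the piece (a fixed
#' smooth tempo curve), then a seeded random subset of onsets is blanked.
#' The ground-truth complete onsets and their mean IBI are returned alongside.
#'
#' @param n_bars number of bars.
#' @param beats_per_bar beats per bar (1/8-note level).
#' @param base_ibi_s baseline inter-beat interval in seconds.
#' @param drift_fraction relative amplitude of the smooth tempo drift
#'   (default 0).
#' @param missing_rate probability in [0, 1) that a beat onset is blanked
#'   (default 0).
#' @param seed integer seed for the missingness draw.
#' @return List with \code{track} (a \code{\link{beat_track}} with missing
#'   onsets) and \code{truth} (complete \code{onsets_s}, \code{mean_ibi_s},
#'   \code{missing_beats}).
#' @export
gen_beat_track <- function(n_bars, beats_per_bar, base_ibi_s,
                           drift_fraction = 0, missing_rate = 0,
                           seed = NULL) {
  if (!is_count(n_bars) || n_bars < 1) stop_ds("n_bars must be a positive integer")
  if (!is_count(beats_per_bar) || beats_per_bar < 1)
    stop_ds("beats_per_bar must be a positive integer")
  if (base_ibi_s <= 0) stop_ds("base_ibi_s must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_ds("missing_rate must be in [0, 1)")
  if (abs(drift_fraction) >= 1)
    stop_ds("|drift_fraction| must be < 1 to keep intervals positive")
  n_beats <- n_bars * beats_per_bar
  u <- (seq_len(n_beats - 1L) - 0.5) / (n_beats - 1L)
  ibi <- base_ibi_s * (1 + drift_fraction * sin(2 * pi * u))
  onsets <- c(0, cumsum(ibi))
  miss <- with_seed(seed, runif(n_beats) < missing_rate)
  observed <- onsets
  observed[miss] <- NA_real_
  if (sum(!miss) < 2L)  # degenerate draw; keep the two end beats
    miss[c(1L, n_beats)] <- FALSE
  observed <- ifelse(miss, NA_real_, onsets)
  list(track = beat_track(seq_len(n_beats) - 1L, observed),
       truth = list(onsets_s = onsets, mean_ibi_s = mean(ibi),
                    missing_beats = which(miss) - 1L))
}

#' Generate motion-capture trajectories for one synthetic duo
#'
#' Front-head velocity is a constant base speed plus the planted sinusoidal
#' components, directed along a fixed oblique unit vector, plus white
#' Gaussian noise per axis; positions are obtained by cumulative integration.
#' The pianist's components are at phase zero; the singer's are delayed by
#' each component's \code{lag_s} (positive lag = pianist earlier = pianist
#' leads). Because the oscillation rides on the base speed, the scalar speed
#' series carries each planted period linearly (not rectified), exactly where
#' the wavelet analysis looks. Any further markers carry a low-amplitude
#' common drift plus noise.
#'
#' @param duration_s recording length in seconds (must be at least 3 times
#'   the longest planted period).
#' @param fs sampling rate in Hz (at least 8 times the highest planted
#'   frequency).
#' @param levels a \code{\link{phrase_levels}} object giving each level's
#'   period in seconds.
#' @param components list of \code{\link{planted_component}}s.
#' @param n_markers_per_performer markers per performer (default 1: just the
#'   front head).
#' @param noise_sd white velocity noise SD per axis in mm/s (default 0).
#' @param base_speed_mm_s constant base speed; default twice the summed
#'   component amplitude (keeps speed linear in the planted oscillation).
#' @param seed integer seed for the noise draw.
#' @return List with \code{pianist} and \code{singer} (lists of
#'   \code{\link{marker_trajectory}}), and \code{truth}: data frame of
#'   component \code{level}, \code{period_s}, \code{amplitude}, \code{lag_s}.
#' @export
gen_duo_motion <- function(duration_s, fs, levels, components,
                           n_markers_per_performer = 1, noise_sd = 0,
                           base_speed_mm_s = NULL, seed = NULL) {
  stopifnot(inherits(levels, "phrase_levels"))
  if (length(components) == 0L) stop_ds("need at least one planted component")
  if (inherits(components, "planted_component")) components <- list(components)
  if (noise_sd < 0) stop_ds("noise_sd must be non-negative")
  periods <- vapply(components, function(cp) {
    as.numeric(levels)[match(cp$level, PHRASE_LEVEL_NAMES)]
  }, numeric(1L))
  for (i in seq_along(components)) {
    cp <- components[[i]]
    if (abs(cp$lag_s) >= periods[i])
      stop_ds("component ", i, " (", cp$level, "): |lag_s| = ", abs(cp$lag_s),
              " s is not smaller than its period ", signif(periods[i], 4), " s")
    if (fs < 8 / periods[i])
      stop_ds("component ", i, " (", cp$level, "): fs = ", fs,
              " Hz undersamples its period ", signif(periods[i], 4),
              " s (need fs >= ", signif(8 / periods[i], 4), ")")
  }
  if (duration_s < 3 * max(periods))
    stop_ds("duration ", duration_s, " s is shorter than 3 x the longest ",
            "planted period (", signif(3 * max(periods), 4), " s)")
  amps <- vapply(components, `[[`, numeric(1L), "amplitude")
  if (is.null(base_speed_mm_s)) base_speed_mm_s <- max(2 * sum(amps), 1)
  n <- floor(duration_s * fs)
  tt <- (seq_len(n) - 1L) / fs
  u_dir <- c(1, 1, 1) / sqrt(3)
  comp_sum <- function(delay) {
    v <- rep(0, n)
    for (i in seq_along(components)) {
      cp <- components[[i]]
      w <- sin(2 * pi * (tt - if (delay) cp$lag_s else 0) / periods[i])
      if (!is.null(cp$time_support))
        w <- w * (tt >= cp$time_support[1L] & tt < cp$time_support[2L])
      v <- v + cp$amplitude * w
    }
    v
  }
  with_seed(seed, {
    make_performer <- function(performer, delayed) {
      scalar <- base_speed_mm_s + comp_sum(delayed)
      markers <- vector("list", n_markers_per_performer)
      drift <- 2 * sin(2 * pi * tt / max(duration_s / 2, 2 * max(periods)))
      for (m in seq_len(n_markers_per_performer)) {
        if (m == 1L) {
          vel <- outer(scalar, u_dir)
        } else {
          vel <- outer(drift, u_dir)
        }
        if (noise_sd > 0)
          vel <- vel + matrix(rnorm(3L * n, sd = noise_sd), ncol = 3L)
        pos <- apply(vel, 2L, cumsum) / fs
        markers[[m]] <- marker_trajectory(
          performer, MARKER_INVENTORY[m], fs, pos)
      }
      names(markers) <- MARKER_INVENTORY[seq_len(n_markers_per_performer)]
      markers
    }
    pianist <- make_performer("pianist", delayed = FALSE)
    singer <- make_performer("singer", delayed = TRUE)
    truth <- data.frame(
      level = vapply(components, `[[`, character(1L), "level"),
      period_s = periods, amplitude = amps,
      lag_s = vapply(components, `[[`, numeric(1L), "lag_s"))
    list(pianist = pianist, singer = singer, truth = truth,
         base_speed_mm_s = base_speed_mm_s, fs = fs, duration_s = n / fs)
  })
}

#' Cohort specification for the synthetic study
#'
#' @param n_duos number of duos (>= 2).
#' @param ept_range integer range \code{c(low, high)} singer and pianist EPT
#'   scores are drawn from (uniformly).
#' @param lead_slope seconds of singer-lead planted per EPT unit above the
#'   midrange: a duo whose singer scores \code{e} gets a singer-lead of
#'   \code{lead_slope * (e - mean(ept_range))} seconds at the dominant
#'   component (i.e. \code{lag_s} is minus that).
#' @param noise_sd velocity noise SD in mm/s.
#' @param seed integer master seed; all cohort randomness flows from it.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_duos = 24, ept_range = c(8, 28), lead_slope = 0.02,
                        noise_sd = 2, seed = 1) {
  if (!is_count(n_duos) || n_duos < 2) stop_ds("n_duos must be an integer >= 2")
  if (length(ept_range) != 2L || ept_range[1L] > ept_range[2L] ||
      ept_range[1L] < 0 || ept_range[2L] > 28)
    stop_ds("ept_range must be c(low, high) within 0..28")
  if (noise_sd < 0) stop_ds("noise_sd must be >= 0")
  structure(list(n_duos = as.integer(n_duos), ept_range = ept_range,
                 lead_slope = lead_slope, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default synthetic piece template
#'
#' A short duple-meter piece (2 beats per bar at the 1/8-note level, base IBI
#' 0.5 s) with an A / B / A' form whose middle section is a piano solo, and
#' planted components at the two-bar (dominant) and half-bar levels. The
#' broadband matches the faster study piece (0.2-6.2 s).
#'
#' @param n_bars number of bars (default 60, i.e. 60 s at the base tempo).
#' @param base_ibi_s baseline IBI (default 0.5 s).
#' @param fs motion sampling rate in Hz (default 60).
#' @param amplitudes named velocity amplitudes in mm/s for the dominant and
#'   secondary component.
#' @param dominant_level phrase level carrying the dominant (lagged)
#'   component (default \code{"two_bars"}).
#' @return List used by \code{\link{simulate_cohort}}: piece parameters,
#'   section layout and base components.
#' @export
piece_template <- function(n_bars = 60, base_ibi_s = 0.5, fs = 60,
                           amplitudes = c(dominant = 10, secondary = 4),
                           dominant_level = "two_bars") {
  dominant_level <- match.arg(dominant_level, PHRASE_LEVEL_NAMES)
  n_beats <- n_bars * 2L
  b <- round(n_beats * c(0, 1 / 3, 2 / 3, 1))
  sections <- section_set(label = c("A", "B", "A'"),
                          start_beat = b[1:3], end_beat = b[2:4],
                          solo_flag = c(FALSE, TRUE, FALSE))
  list(piece = "synthetic_lied", n_bars = n_bars, beats_per_bar = 2L,
       base_ibi_s = base_ibi_s, fs = fs,
       broadband = c(0.2, 6.2),
       drift_fraction = 0.05, missing_rate = 0.05,
       sections = sections,
       dominant_level = dominant_level,
       amplitudes = amplitudes,
       secondary_level = "half_bar")
}

#' Generate a synthetic duo cohort with planted ground truth
#'
#' Each duo receives pianist and singer EPT scores drawn uniformly from the
#' cohort's range; the singer-lead lag planted at the dominant component is
#' \code{lead_slope * (singer_EPT - midrange)} seconds (so the cohort carries
#' an exact linear EPT-leadership association). Every duo gets a manifest,
#' a drifting beat track with missing onsets, section annotations and marker
#' trajectories, all deterministically derived from the master seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param template a \code{\link{piece_template}}.
#' @param take take number recorded in the manifests (default 0).
#' @param n_markers_per_performer markers per performer (default 1).
#' @return Object of class \code{duo_cohort}: list with \code{sessions} (each
#'   a list \code{manifest}, \code{beats}, \code{sections},
#'   \code{trajectories}, \code{truth}) and a cohort-level ground-truth data
#'   frame \code{truth} (duo, EPT scores, planted singer-lead and lag).
#' @export
simulate_cohort <- function(spec, template = piece_template(), take = 0,
                            n_markers_per_performer = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  mid <- mean(spec$ept_range)
  levels <- phrase_levels(template$base_ibi_s, template$beats_per_bar)
  draws <- with_seed(spec$seed, {
    list(singer_ept = sample(spec$ept_range[1L]:spec$ept_range[2L],
                             spec$n_duos, replace = TRUE),
         pianist_ept = sample(spec$ept_range[1L]:spec$ept_range[2L],
                              spec$n_duos, replace = TRUE),
         sub_seeds = sample.int(.Machine$integer.max - 1L, 2L * spec$n_duos))
  })
  sessions <- vector("list", spec$n_duos)
  truth <- data.frame(duo_id = character(spec$n_duos),
                      singer_ept = integer(spec$n_duos),
                      pianist_ept = integer(spec$n_duos),
                      singer_lead_s = numeric(spec$n_duos),
                      lag_s = numeric(spec$n_duos),
                      mean_ibi_s = numeric(spec$n_duos),
                      stringsAsFactors = FALSE)
  for (d in seq_len(spec$n_duos)) {
    duo_id <- sprintf("duo%02d", d)
    s_ept <- draws$singer_ept[d]; p_ept <- draws$pianist_ept[d]
    singer_lead <- spec$lead_slope * (s_ept - mid)
    lag <- -singer_lead   # positive lag = pianist leads
    grp <- paste0(if (p_ept >= mid) "H" else "L",
                  if (s_ept >= mid) "H" else "L")
    manifest <- session_manifest(
      duo_id, template$piece, take, p_ept, s_ept, grp,
      template$beats_per_bar, template$broadband[1L], template$broadband[2L])
    bt <- gen_beat_track(template$n_bars, template$beats_per_bar,
                         template$base_ibi_s,
                         drift_fraction = template$drift_fraction,
                         missing_rate = template$missing_rate,
                         seed = draws$sub_seeds[2L * d - 1L])
    comps <- list(
      planted_component(template$dominant_level,
                        template$amplitudes[["dominant"]], lag_s = lag),
      planted_component(template$secondary_level,
                        template$amplitudes[["secondary"]], lag_s = 0))
    duration <- max(bt$truth$onsets_s)
    motion <- gen_duo_motion(duration, template$fs, levels, comps,
                             n_markers_per_performer = n_markers_per_performer,
                             noise_sd = spec$noise_sd,
                             seed = draws$sub_seeds[2L * d])
    sessions[[d]] <- list(manifest = manifest, beats = bt$track,
                          sections = template$sections,
                          trajectories = c(motion$pianist, motion$singer),
                          pianist = motion$pianist, singer = motion$singer,
                          truth = motion$truth)
    truth[d, ] <- list(duo_id, s_ept, p_ept, singer_lead, lag,
                       bt$truth$mean_ibi_s)
  }
  structure(list(sessions = sessions, truth = truth, spec = spec,
                 template = template),
            class = "duo_cohort")
}

#' @export
print.duo_cohort <- function(x, ...) {
  cat(sprintf(
    "<duo_cohort> %d duos, piece %s, lead_slope %g s/EPT, noise %g mm/s, seed %d\n",
    length(x$sessions), x$template$piece, x$spec$lead_slope, x$spec$noise_sd,
    x$spec$seed))
  invisible(x)
}

#' @rdname simulate_cohort
#' @export
gen_cohort <- simulate_cohort
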