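#' Top peaks of a time-averaged power curve
#'
#' A peak is a strict local maximum of power over the period grid (plateaus
#' count once, at their left-most index; curve ends cannot be peaks). Peaks
#' are ranked by power, ties broken toward the longer period, and the top
#' \code{k} returned.
#'
#' @param curve a \code{power_curve} from \code{\link{time_average_power}}, or
#'   any data frame with \code{period_s} and \code{power}.
#' @param k how many peaks to return (default 3).
#' @return Data frame with \code{period_s}, \code{power}, possibly zero rows.
#' @export
find_top_peaks <- function(curve, k = 3) {
  if (!all(c("period_s", "power") %in% names(curve)))
    stop_ds("curve needs period_s and power columns")
  p <- curve$power
  if (length(p) < 3L) stop_ds("curve must have at least 3 points")
  r <- rle(p)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  peak_idx <- integer(0)
  if (nr >= 3L) {
    for (j in 2:(nr - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        peak_idx <- c(peak_idx, starts[j])   # plateau takes the left-most index
    }
  }
  if (length(peak_idx) == 0L)
    return(curve[integer(0), c("period_s", "power")])
  found <- curve[peak_idx, c("period_s", "power")]
  ord <- order(-found$power, -found$period_s)   # ties -> longer period first
  out <- found[ord, , drop = FALSE][seq_len(min(k, nrow(found))), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Occurrence of power peaks by phrase level across sessions
#'
#' Assigns every supplied peak to the unique narrow band containing its
#' period (or to \code{"outside"}), then tabulates counts and percentages of
#' the total number of peaks across sessions.
#'
#' @param peaks_list list with one peaks data frame per session (from
#'   \code{\link{find_top_peaks}}).
#' @param bands_list list with the session's \code{band_spec} in the same
#'   order (bands are tempo-scaled, hence per session).
#' @return Data frame of class \code{peak_occurrence} with \code{level}
#'   (five phrase levels plus \code{"outside"}), \code{count}, \code{pct}.
#' @export
tabulate_peak_occurrence <- function(peaks_list, bands_list) {
  if (length(peaks_list) != length(bands_list))
    stop_ds("peaks_list and bands_list lengths differ")
  cats <- c(PHRASE_LEVEL_NAMES, "outside")
  counts <- setNames(numeric(length(cats)), cats)
  total <- 0L
  for (i in seq_along(peaks_list)) {
    pk <- peaks_list[[i]]
    if (nrow(pk) == 0L) next
    idx <- band_index(pk$period_s, bands_list[[i]])
    lvl <- ifelse(is.na(idx), "outside",
                  as.character(bands_list[[i]]$level[idx]))
    for (l in lvl) counts[l] <- counts[l] + 1
    total <- total + nrow(pk)
  }
  pct <- if (total > 0L) 100 * counts / total else counts * 0
  out <- data.frame(level = factor(cats, levels = cats),
                    count = as.integer(counts), pct = as.numeric(pct))
  class(out) <- c("peak_occurrence", "data.frame")
  out
}

#' Classify a phase difference into leadership and phase regime
#'
#' With the pianist as first channel, phase differences in (0, pi/2) and
#' (-pi, -pi/2) mean the pianist is leading; values in [pi/2, pi] and
#' [-pi/2, 0) mean the singer is leading; exactly 0 is perfectly in sync.
#' Motion is in-phase when |phase| < pi/2 and out-of-phase when
#' |phase| > pi/2; the boundary |phase| = pi/2 is labelled out-of-phase and
#' flagged.
#'
#' @param phase_rad numeric vector of phase differences in (-pi, pi].
#' @return Data frame with \code{phase_rad}, \code{leadership} (factor:
#'   \code{pianist_leads}, \code{singer_leads}, \code{in_sync}),
#'   \code{phase_regime} (factor: \code{in_phase}, \code{out_of_phase}) and
#'   logical \code{boundary} flagging |phase| = pi/2.
#' @export
#' @examples
#' phase_to_leadership(c(pi / 4, -3 * pi / 4, 0))
phase_to_leadership <- function(phase_rad) {
  if (any(!is.finite(phase_rad)) ||
      any(phase_rad <= -pi - 1e-12) || any(phase_rad > pi + 1e-12))
    stop_ds("phase must lie in (-pi, pi]")
  lead <- ifelse(
    phase_rad == 0, "in_sync",
    ifelse((phase_rad >= -pi / 2 & phase_rad < 0) | phase_rad >= pi / 2,
           "singer_leads", "pianist_leads"))
  regime <- ifelse(abs(phase_rad) < pi / 2, "in_phase", "out_of_phase")
  data.frame(
    phase_rad = phase_rad,
    leadership = factor(lead,
                        levels = c("pianist_leads", "singer_leads", "in_sync")),
    phase_regime = factor(regime, levels = c("in_phase", "out_of_phase")),
    boundary = abs(abs(phase_rad) - pi / 2) < 1e-12)
}

#' Convert a phase difference to signed milliseconds
#'
#' \code{phase_ms = phase_rad / (2*pi) * period_s * 1000}. Negative values
#' mean the singer leads in the in-phase regime.
#'
#' @param phase_rad phase difference(s) in radians.
#' @param period_s oscillation period(s) in seconds (the phrase-level
#'   duration when converting band aggregates).
#' @return Signed milliseconds.
#' @export
#' @examples
#' phase_to_ms(-pi / 2, 4)  # -1000 ms
phase_to_ms <- function(phase_rad, period_s) {
  if (any(period_s <= 0)) stop_ds("period_s must be positive")
  phase_rad / (2 * pi) * period_s * 1000
}

# circular (phasor) mean of angles; returns list(mean, resultant_length)
circular_mean <- function(phi) {
  z <- mean(exp(1i * phi))
  list(mean = wrap_phase(Arg(z)), R = Mod(z))
}

#' Band-aggregated cross-wavelet power and phase
#'
#' Grand averages over all cells of the field whose period lies in the band
#' (half-open \code{[low, high)}) and whose timestamp is selected by the mask:
#' the arithmetic mean of power, and the circular (phasor) mean of phase with
#' its mean resultant length as a reliability diagnostic. The mean phase is
#' converted to milliseconds using the band's level duration as the period,
#' and classified into a leadership call.
#'
#' @param field an \code{xwt_field}.
#' @param band one row of a \code{band_spec} (or a list with \code{level},
#'   \code{duration_s}, \code{period_low_s}, \code{period_high_s}).
#' @param mask optional logical vector over timestamps.
#' @param arithmetic_phase use the arithmetic mean of angles instead of the
#'   circular mean (comparison only; incorrect near +/-pi). Default
#'   \code{FALSE}.
#' @return One-row data frame of class \code{band_aggregate} with
#'   \code{level}, \code{duration_s}, \code{mean_power},
#'   \code{mean_phase_rad}, \code{resultant_length}, \code{phase_ms},
#'   \code{leadership}, \code{phase_regime}, \code{n_cells}.
#' @export
band_aggregate <- function(field, band, mask = NULL,
                           arithmetic_phase = FALSE) {
  stopifnot(inherits(field, "xwt_field"))
  band <- as.list(band)
  rows <- which(field$periods_s >= band$period_low_s &
                  field$periods_s < band$period_high_s)
  if (length(rows) == 0L)
    stop_ds("band [", signif(band$period_low_s, 4), ", ",
            signif(band$period_high_s, 4),
            ") s contains no period of the field's grid")
  nt <- ncol(field$power)
  if (is.null(mask)) mask <- rep(TRUE, nt)
  if (length(mask) != nt) stop_ds("mask length must match the time axis")
  if (!any(mask)) stop_ds("mask selects no timestamps")
  pw <- field$power[rows, mask, drop = FALSE]
  ph <- field$phase_rad[rows, mask, drop = FALSE]
  cm <- circular_mean(as.vector(ph))
  mean_phase <- if (arithmetic_phase) mean(ph) else cm$mean
  lead <- phase_to_leadership(mean_phase)
  out <- data.frame(
    level = as.character(band$level),
    duration_s = band$duration_s,
    mean_power = mean(pw),
    mean_phase_rad = mean_phase,
    resultant_length = cm$R,
    phase_ms = phase_to_ms(mean_phase, band$duration_s),
    leadership = lead$leadership,
    phase_regime = lead$phase_regime,
    n_cells = length(pw))
  class(out) <- c("band_aggregate", "data.frame")
  out
}

#' Aggregate an XWT field over all phrase-level bands
#'
#' @param field an \code{xwt_field}.
#' @param bands a \code{band_spec} from \code{\link{make_bands}}.
#' @param mask optional time mask, passed to \code{\link{band_aggregate}}.
#' @return Data frame with one \code{\link{band_aggregate}} row per level.
#' @export
aggregate_bands <- function(field, bands, mask = NULL) {
  out <- do.call(rbind, lapply(seq_len(nrow(bands)), function(i)
    band_aggregate(field, bands[i, ], mask = mask)))
  rownames(out) <- NULL
  out
}

#' Most dominant phrase level
#'
#' The phrase level whose band-aggregated power is largest; ties are broken
#' toward the shorter period and flagged.
#'
#' @param aggregates data frame of band aggregates (one row per level,
#'   ordered short to long) with \code{level} and \code{mean_power}.
#' @return The winning level as character, with attributes \code{tie}
#'   (logical) and \code{mean_power}.
#' @export
dominant_level <- function(aggregates) {
  if (nrow(aggregates) < 1L) stop_ds("no aggregates supplied")
  mp <- aggregates$mean_power
  best <- which(mp == max(mp))     # first = shortest period (rows ordered)
  structure(as.character(aggregates$level[best[1L]]),
            tie = length(best) > 1L, mean_power = max(mp))
}

# map score beats to time via the (complete) beat track, extrapolating
# linearly beyond the track the same way interpolate_missing_beats does
beat_to_time <- function(beats, track) {
  if (anyNA(track$onset_s)) stop_ds("beat track has missing onsets")
  bi <- track$beat_index; on <- track$onset_s
  out <- approx(bi, on, xout = beats, rule = 1)$y
  lo <- beats < bi[1L]
  if (any(lo))
    out[lo] <- on[1L] + (on[2L] - on[1L]) / (bi[2L] - bi[1L]) *
      (beats[lo] - bi[1L])
  nb <- length(bi)
  hiidx <- beats > bi[nb]
  if (any(hiidx))
    out[hiidx] <- on[nb] + (on[nb] - on[nb - 1L]) / (bi[nb] - bi[nb - 1L]) *
      (beats[hiidx] - bi[nb])
  out
}

#' Band aggregates per musical section and per solo/together grouping
#'
#' Sections are expressed in score beats (half-open \code{[start, end)}) and
#' mapped to time via the beat track; each section (and the union of solo
#' vs. together sections) then masks the field's timestamps for
#' \code{\link{aggregate_bands}}.
#'
#' @param field an \code{xwt_field}.
#' @param bands a \code{band_spec}.
#' @param sections a \code{section_set} (see \code{\link{section_set}}).
#' @param track a complete \code{\link{beat_track}} for the session.
#' @return List with \code{by_section} (aggregate rows with a \code{section}
#'   column) and \code{by_solo_together} (aggregate rows with a
#'   \code{grouping} column taking values \code{"solo"}, \code{"together"}).
#' @export
segment_aggregate <- function(field, bands, sections, track) {
  stopifnot(inherits(sections, "section_set"))
  t0 <- beat_to_time(sections$start_beat, track)
  t1 <- beat_to_time(sections$end_beat, track)
  masks <- lapply(seq_len(nrow(sections)), function(i)
    field$times_s >= t0[i] & field$times_s < t1[i])
  empty <- !vapply(masks, any, logical(1L))
  if (any(empty))
    stop_ds("section ", sections$label[which(empty)[1L]],
            " covers no timestamps of the recording")
  by_section <- do.call(rbind, lapply(seq_len(nrow(sections)), function(i) {
    agg <- aggregate_bands(field, bands, mask = masks[[i]])
    cbind(section = sections$label[i], agg)
  }))
  grp <- list(solo = Reduce(`|`, masks[sections$solo_flag],
                            rep(FALSE, length(field$times_s))),
              together = Reduce(`|`, masks[!sections$solo_flag],
                                rep(FALSE, length(field$times_s))))
  by_grp <- do.call(rbind, lapply(names(grp), function(g) {
    if (!any(grp[[g]])) return(NULL)
    cbind(grouping = g, aggregate_bands(field, bands, mask = grp[[g]]))
  }))
  rownames(by_section) <- NULL
  if (!is.null(by_grp)) rownames(by_grp) <- NULL
  list(by_section = by_section, by_solo_together = by_grp)
}
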