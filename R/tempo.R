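#' Beat track: score beats mapped to performed onset times
#'
#' A beat track pairs consecutive score-beat indices (counted at the 1/8-note
#' level) with performed onset times in seconds. Onsets may be missing where
#' the score holds a rest or the performer missed a note; missingness is kept
#' explicit so that \code{\link{interpolate_missing_beats}} can fill it in
#' while flagging which onsets are estimates.
#'
#' @param beat_index integer vector of consecutive score-beat indices.
#' @param onset_s numeric vector of onset times in seconds; \code{NA} marks a
#'   beat with no performed onset.
#' @param interpolated logical vector flagging onsets that were estimated
#'   rather than performed. Defaults to all \code{FALSE}.
#' @return An object of class \code{beat_track}: a data frame with columns
#'   \code{beat_index}, \code{onset_s}, \code{interpolated}.
#' @export
#' @examples
#' beat_track(0:3, c(0, 0.5, NA, 1.5))
beat_track <- function(beat_index, onset_s,
                       interpolated = rep(FALSE, length(beat_index))) {
  if (length(beat_index) != length(onset_s) ||
      length(beat_index) != length(interpolated))
    stop_ds("beat_index, onset_s and interpolated must have equal length")
  if (length(beat_index) == 0L) stop_ds("beat track is empty")
  if (anyNA(beat_index) || any(beat_index != round(beat_index)))
    stop_ds("beat_index must be integer-valued")
  if (any(diff(beat_index) != 1L))
    stop_ds("beat_index must be consecutive integers (gap after index ",
            beat_index[which(diff(beat_index) != 1L)[1L]], ")")
  pres <- onset_s[!is.na(onset_s)]
  if (any(diff(pres) < 0)) {
    bad <- which(diff(pres) < 0)[1L]
    stop_ds("onsets must be non-decreasing among present values (violated at ",
            "present onset #", bad + 1L, ")")
  }
  structure(
    data.frame(beat_index = as.integer(beat_index),
               onset_s = as.numeric(onset_s),
               interpolated = as.logical(interpolated)),
    class = c("beat_track", "data.frame"))
}

#' @export
print.beat_track <- function(x, ...) {
  n_miss <- sum(is.na(x$onset_s))
  cat("<beat_track> ", nrow(x), " beats [", x$beat_index[1L], "..",
      x$beat_index[nrow(x)], "], ", n_miss, " missing, ",
      sum(x$interpolated), " interpolated\n", sep = "")
  invisible(x)
}

#' Fill missing beat onsets by linear interpolation
#'
#' Interior gaps are filled by linear interpolation (in beat index) between the
#' nearest performed onsets; leading and trailing gaps are filled by linear
#' extrapolation from the two nearest performed onsets. Filled onsets are
#' flagged in \code{interpolated}. Exact on affine onset sequences and
#' idempotent (a complete track is returned unchanged).
#'
#' @param track a \code{\link{beat_track}}, possibly with missing onsets.
#' @return A complete \code{beat_track} with \code{interpolated} flags set.
#' @export
interpolate_missing_beats <- function(track) {
  stopifnot(inherits(track, "beat_track"))
  miss <- is.na(track$onset_s)
  if (!any(miss)) return(track)
  pres_i <- track$beat_index[!miss]
  pres_t <- track$onset_s[!miss]
  if (length(pres_i) < 2L)
    stop_ds("need at least two present onsets to interpolate")
  filled <- track$onset_s
  # interior gaps: linear interpolation in beat index
  interior <- miss & track$beat_index > min(pres_i) &
    track$beat_index < max(pres_i)
  if (any(interior))
    filled[interior] <- approx(pres_i, pres_t,
                               xout = track$beat_index[interior])$y
  # edge gaps: extrapolate from the two nearest present onsets
  lead <- miss & track$beat_index < min(pres_i)
  if (any(lead)) {
    slope <- (pres_t[2L] - pres_t[1L]) / (pres_i[2L] - pres_i[1L])
    filled[lead] <- pres_t[1L] + slope * (track$beat_index[lead] - pres_i[1L])
  }
  trail <- miss & track$beat_index > max(pres_i)
  if (any(trail)) {
    np <- length(pres_i)
    slope <- (pres_t[np] - pres_t[np - 1L]) / (pres_i[np] - pres_i[np - 1L])
    filled[trail] <- pres_t[np] + slope * (track$beat_index[trail] - pres_i[np])
  }
  out <- beat_track(track$beat_index, filled, track$interpolated | miss)
  if (any(diff(out$onset_s) <= 0))
    stop_ds("interpolated onsets are not strictly increasing")
  out
}

#' Tempo summary from a complete beat track
#'
#' The inter-beat interval (IBI) is the time between successive score beats;
#' its mean over a performance is the measure of musical tempo. The SD uses
#' the sample (n-1) denominator.
#'
#' @param track a complete \code{\link{beat_track}} (no missing onsets; run
#'   \code{\link{interpolate_missing_beats}} first if needed).
#' @return An object of class \code{tempo_summary}: list with
#'   \code{mean_ibi_s}, \code{sd_ibi_s}, \code{min_ibi_s}, \code{max_ibi_s}
#'   and \code{n_intervals}.
#' @export
#' @examples
#' compute_tempo(beat_track(0:4, seq(0, 2, by = 0.5)))
compute_tempo <- function(track) {
  stopifnot(inherits(track, "beat_track"))
  if (anyNA(track$onset_s))
    stop_ds("beat track has missing onsets; interpolate first")
  if (nrow(track) < 2L) stop_ds("need at least two onsets to compute tempo")
  ibi <- diff(track$onset_s)
  out <- list(mean_ibi_s = mean(ibi),
              sd_ibi_s = if (length(ibi) > 1L) sd(ibi) else 0,
              min_ibi_s = min(ibi), max_ibi_s = max(ibi),
              n_intervals = length(ibi))
  if (out$min_ibi_s <= 0)
    stop_ds("non-positive inter-beat interval encountered")
  structure(out, class = "tempo_summary")
}

#' @export
print.tempo_summary <- function(x, ...) {
  cat(sprintf("<tempo_summary> mean IBI %.4g s (SD %.3g, range %.3g-%.3g, n=%d)\n",
              x$mean_ibi_s, x$sd_ibi_s, x$min_ibi_s, x$max_ibi_s,
              x$n_intervals))
  invisible(x)
}

#' Phrase-level durations from the mean inter-beat interval
#'
#' Each hierarchical phrase level (half bar, one bar, two, three, four bars)
#' has a duration in seconds of \code{mean_ibi_s * beats_per_bar * bars}.
#'
#' @param tempo a \code{\link{tempo_summary}} or a single numeric mean IBI in
#'   seconds.
#' @param beats_per_bar positive integer; beats per bar counted at the
#'   1/8-note level (e.g. 12 for a 12/8 meter, 2 for 2/8).
#' @return An object of class \code{phrase_levels}: named numeric vector of
#'   durations in seconds over the five levels, with a \code{bars} attribute.
#' @export
#' @examples
#' phrase_levels(0.49, beats_per_bar = 2)  # half bar = 0.49 s, two bars = 1.96 s
phrase_levels <- function(tempo, beats_per_bar) {
  mean_ibi <- if (inherits(tempo, "tempo_summary")) tempo$mean_ibi_s
              else as.numeric(tempo)
  if (length(mean_ibi) != 1L || !is.finite(mean_ibi) || mean_ibi <= 0)
    stop_ds("mean IBI must be a single positive number")
  if (!is_count(beats_per_bar) || beats_per_bar < 1)
    stop_ds("beats_per_bar must be a positive integer")
  durations <- mean_ibi * beats_per_bar * PHRASE_LEVEL_BARS
  structure(durations, bars = PHRASE_LEVEL_BARS,
            mean_ibi_s = mean_ibi, beats_per_bar = as.integer(beats_per_bar),
            class = "phrase_levels")
}

#' @export
print.phrase_levels <- function(x, ...) {
  cat("<phrase_levels> durations (s):\n")
  print(setNames(as.numeric(x), names(PHRASE_LEVEL_BARS)))
  invisible(x)
}

#' Tempo-scaled narrow period bands around the phrase levels
#'
#' Builds one period band per phrase level: \code{[d * 2^-h, d * 2^h]} around
#' the level duration \code{d}, with \code{h} in octaves. Adjacent bands are
#' clipped at the geometric midpoint of neighbouring durations so that bands
#' never overlap (they may touch), and all bands are clipped to the broadband
#' period range.
#'
#' @param levels a \code{\link{phrase_levels}} object.
#' @param broadband numeric length-2, the broadband period range
#'   \code{c(low_s, high_s)} in seconds.
#' @param half_width_log2 positive half-width of each band in octaves
#'   (default 0.25).
#' @return Data frame of class \code{band_spec} with columns \code{level},
#'   \code{duration_s}, \code{period_low_s}, \code{period_high_s}.
#' @export
make_bands <- function(levels, broadband, half_width_log2 = 0.25) {
  stopifnot(inherits(levels, "phrase_levels"))
  if (length(broadband) != 2L || !all(is.finite(broadband)) ||
      broadband[1L] <= 0 || broadband[1L] >= broadband[2L])
    stop_ds("broadband must be c(low_s, high_s) with 0 < low < high")
  if (!is.numeric(half_width_log2) || length(half_width_log2) != 1L ||
      half_width_log2 <= 0)
    stop_ds("half_width_log2 must be a single positive number")
  d <- as.numeric(levels)
  nm <- names(PHRASE_LEVEL_BARS)
  outside <- d < broadband[1L] | d > broadband[2L]
  if (any(outside))
    stop_ds("phrase level ", nm[which(outside)[1L]], " (",
            signif(d[which(outside)[1L]], 4),
            " s) lies outside the broadband [", broadband[1L], ", ",
            broadband[2L], "] s")
  lo <- d * 2^(-half_width_log2)
  hi <- d * 2^(+half_width_log2)
  # clip neighbours at the geometric midpoint of adjacent durations
  gm <- sqrt(d[-length(d)] * d[-1L])
  hi[-length(d)] <- pmin(hi[-length(d)], gm)
  lo[-1L] <- pmax(lo[-1L], gm)
  lo <- pmax(lo, broadband[1L])
  hi <- pmin(hi, broadband[2L])
  out <- data.frame(level = factor(nm, levels = nm),
                    duration_s = d, period_low_s = lo, period_high_s = hi)
  class(out) <- c("band_spec", "data.frame")
  validate_band_spec(out, broadband)
  out
}

validate_band_spec <- function(bands, broadband = NULL) {
  with(bands, {
    if (any(period_low_s >= period_high_s))
      stop_ds("degenerate band for level ",
              level[which(period_low_s >= period_high_s)[1L]])
    if (any(duration_s < period_low_s | duration_s > period_high_s))
      stop_ds("band does not contain its level duration")
    if (any(period_low_s[-1L] < period_high_s[-length(period_high_s)] - 1e-12))
      stop_ds("bands overlap")
  })
  if (!is.null(broadband) &&
      (any(bands$period_low_s < broadband[1L] - 1e-12) ||
       any(bands$period_high_s > broadband[2L] + 1e-12)))
    stop_ds("bands exceed the broadband")
  invisible(bands)
}

# which band contains each period? half-open [low, high), topmost band closed.
# returns integer row index into `bands`, NA if outside all bands.
band_index <- function(period_s, bands) {
  idx <- rep(NA_integer_, length(period_s))
  n <- nrow(bands)
  for (i in seq_len(n)) {
    hit <- period_s >= bands$period_low_s[i] &
      (period_s < bands$period_high_s[i] |
         (i == n & period_s <= bands$period_high_s[i]))
    idx[hit] <- i
  }
  idx
}
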