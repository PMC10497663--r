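#' Session manifest
#'
#' Describes one recorded performance: which duo, piece and take, the two
#' performers' empathic perspective-taking (EPT) scores and group, the meter
#' (beats per bar at the 1/8-note level) and the broadband period range used
#' for the wavelet analysis.
#'
#' @param duo_id duo identifier.
#' @param piece piece identifier.
#' @param take non-negative integer take number (0 = pre-rehearsal).
#' @param pianist_ept,singer_ept integer EPT scores in 0..28.
#' @param ept_group one of \code{"LL"}, \code{"HH"}, \code{"LH"}, \code{"HL"}
#'   (pianist then singer, low/high split).
#' @param meter_beats_per_bar positive integer beats per bar at the 1/8-note
#'   level (12 for a 12/8 piece, 2 for a 2/8 piece).
#' @param broadband_low_s,broadband_high_s broadband period range in seconds,
#'   \code{0 < low < high}.
#' @return Object of class \code{session_manifest}.
#' @export
session_manifest <- function(duo_id, piece, take, pianist_ept, singer_ept,
                             ept_group, meter_beats_per_bar,
                             broadband_low_s, broadband_high_s) {
  if (!is_count(take) || take < 0) stop_ds("take must be an integer >= 0")
  for (nm in c("pianist_ept", "singer_ept")) {
    v <- get(nm)
    if (!is_count(v) || v < 0 || v > 28)
      stop_ds(nm, " must be an integer score in 0..28")
  }
  ept_group <- match.arg(ept_group, c("LL", "HH", "LH", "HL"))
  if (!is_count(meter_beats_per_bar) || meter_beats_per_bar < 1)
    stop_ds("meter_beats_per_bar must be a positive integer")
  if (!is.numeric(broadband_low_s) || !is.numeric(broadband_high_s) ||
      broadband_low_s <= 0 || broadband_low_s >= broadband_high_s)
    stop_ds("need 0 < broadband_low_s < broadband_high_s")
  structure(list(duo_id = as.character(duo_id), piece = as.character(piece),
                 take = as.integer(take),
                 pianist_ept = as.integer(pianist_ept),
                 singer_ept = as.integer(singer_ept),
                 ept_group = ept_group,
                 meter_beats_per_bar = as.integer(meter_beats_per_bar),
                 broadband_low_s = broadband_low_s,
                 broadband_high_s = broadband_high_s),
            class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf(
    "<session_manifest> duo %s, %s take %d | EPT p=%d s=%d (%s) | %d beats/bar | broadband %g-%g s\n",
    x$duo_id, x$piece, x$take, x$pianist_ept, x$singer_ept, x$ept_group,
    x$meter_beats_per_bar, x$broadband_low_s, x$broadband_high_s))
  invisible(x)
}

#' Section annotations for a piece
#'
#' Sections are half-open beat intervals \code{[start_beat, end_beat)} that
#' partition the piece: ordered, non-overlapping and contiguous, so every
#' beat belongs to exactly one section.
#'
#' @param label section labels (e.g. \code{"A"}, \code{"B"}, \code{"A'"}).
#' @param start_beat,end_beat integer beat bounds, half-open.
#' @param solo_flag logical, \code{TRUE} where the pianist plays solo.
#' @return Data frame of class \code{section_set}.
#' @export
section_set <- function(label, start_beat, end_beat, solo_flag) {
  n <- length(label)
  if (length(start_beat) != n || length(end_beat) != n ||
      length(solo_flag) != n)
    stop_ds("section fields must have equal length")
  if (any(end_beat <= start_beat))
    stop_ds("sections must have end_beat > start_beat")
  ord <- order(start_beat)
  if (any(ord != seq_len(n))) stop_ds("sections must be ordered by start_beat")
  if (n > 1L && any(start_beat[-1L] != end_beat[-n]))
    stop_ds("sections must be contiguous (every beat in exactly one section)")
  out <- data.frame(label = as.character(label),
                    start_beat = as.integer(start_beat),
                    end_beat = as.integer(end_beat),
                    solo_flag = as.logical(solo_flag))
  class(out) <- c("section_set", "data.frame")
  out
}

#' Read a long-format marker-trajectory table
#'
#' The file must have columns \code{time_s}, \code{performer}, \code{marker},
#' \code{x_mm}, \code{y_mm}, \code{z_mm}, with time strictly increasing and
#' uniformly sampled within each (performer, marker) group. Malformed input
#' is rejected, never repaired.
#'
#' @param path CSV (or TSV) file path.
#' @param jitter_tol maximum relative deviation of any sampling step from the
#'   nominal (median) step (default 1e-6).
#' @return Named list of \code{\link{marker_trajectory}} objects
#'   (\code{"<performer>.<marker>"}).
#' @export
read_marker_table <- function(path, jitter_tol = 1e-6) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("time_s", "performer", "marker", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop_ds("marker table must have columns ", paste(need, collapse = ", "))
  df$.row <- seq_len(nrow(df))
  groups <- split(df, list(df$performer, df$marker), drop = TRUE)
  out <- lapply(groups, function(g) {
    dt <- diff(g$time_s)
    if (any(dt <= 0)) {
      bad <- g$.row[which(dt <= 0)[1L] + 1L]
      stop_ds("time not strictly increasing for ", g$performer[1L], "/",
              g$marker[1L], " at input row ", bad)
    }
    step <- median(dt)
    jit <- abs(dt - step) / step
    if (any(jit > jitter_tol)) {
      bad <- which.max(jit)
      stop_ds("irregular sampling for ", g$performer[1L], "/", g$marker[1L],
              ": gap of ", signif(dt[bad], 8), " s after input row ",
              g$.row[bad], " (nominal step ", signif(step, 8), " s)")
    }
    marker_trajectory(g$performer[1L], g$marker[1L], fs = 1 / step,
                      xyz = as.matrix(g[, c("x_mm", "y_mm", "z_mm")]))
  })
  names(out) <- vapply(out, function(tr) paste0(tr$performer, ".", tr$marker),
                       character(1L))
  out
}

#' Write marker trajectories in the long CSV format read_marker_table reads
#'
#' @param trajs list of \code{\link{marker_trajectory}} objects.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_marker_table <- function(trajs, path) {
  if (inherits(trajs, "marker_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    n <- nrow(tr$xyz)
    data.frame(time_s = (seq_len(n) - 1L) / tr$fs,
               performer = tr$performer, marker = tr$marker,
               x_mm = tr$xyz[, 1L], y_mm = tr$xyz[, 2L], z_mm = tr$xyz[, 3L])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a beat-onset table
#'
#' The file must have columns \code{beat_index} (consecutive integers) and
#' \code{onset_s} (seconds; empty cells mark beats with no performed onset).
#' Missingness is preserved for \code{\link{interpolate_missing_beats}}.
#'
#' @param path CSV file path.
#' @return A \code{\link{beat_track}}.
#' @export
read_beat_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("beat_index", "onset_s") %in% names(df)))
    stop_ds("beat table must have columns beat_index, onset_s")
  beat_track(df$beat_index, as.numeric(df$onset_s))
}

#' Write a beat track as CSV
#' @param track a \code{\link{beat_track}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_beat_table <- function(track, path) {
  write.csv(as.data.frame(track)[, c("beat_index", "onset_s")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a section-annotation table
#'
#' Columns: \code{label}, \code{start_beat}, \code{end_beat},
#' \code{solo_flag} (logical or 0/1).
#'
#' @param path CSV file path.
#' @return A \code{\link{section_set}}.
#' @export
read_section_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_beat", "end_beat", "solo_flag")
  if (!all(need %in% names(df)))
    stop_ds("section table must have columns ", paste(need, collapse = ", "))
  section_set(df$label, df$start_beat, df$end_beat, as.logical(df$solo_flag))
}

#' Write result tables with a JSON run-metadata sidecar
#'
#' Each named data frame is written as \code{<name>.csv} in \code{out_dir};
#' \code{run_metadata.json} records the configuration, seed and package
#' version. Re-running with the same inputs, config and seed reproduces the
#' numeric columns byte-identically.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if missing).
#' @param config list of configuration values to record.
#' @param seed the seed used for the run, if any.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NULL) {
  if (!is.list(tables) || (length(tables) > 0L && is.null(names(tables))))
    stop_ds("tables must be a named list of data frames")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_ds("cannot create output directory ", out_dir)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(tables[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  meta <- list(package = "duosync",
               version = as.character(packageVersion("duosync")),
               seed = seed, config = config)
  mf <- file.path(out_dir, "run_metadata.json")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), mf)
  invisible(c(files, mf))
}
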