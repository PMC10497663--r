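#' Pipeline control parameters
#'
#' Collects every tunable of the analysis with its default: Morlet central
#' frequency \code{omega0 = 6}, scale resolution \code{dj = 1/20},
#' narrow-band half width 0.25 octaves, no COI masking of averages, no
#' variance standardisation, cross-wavelet power as the modulus (not
#' squared), quantity of motion as per-second path length, and the
#' Savitzky-Golay window/order (25 samples, order 3).
#'
#' @param omega0 Morlet central frequency.
#' @param dj sub-octaves per scale step.
#' @param band_half_width_log2 narrow-band half width in octaves.
#' @param coi_mask exclude cone-of-influence cells from averages?
#' @param standardize variance-standardise speed series before the CWT?
#' @param power_def \code{"modulus"} or \code{"squared"}.
#' @param qom_mode \code{"path_length"} or \code{"mean_speed"}.
#' @param sg_window,sg_polyorder Savitzky-Golay filter window and order.
#' @return Object of class \code{pipeline_control}.
#' @export
pipeline_control <- function(omega0 = 6, dj = 1 / 20,
                             band_half_width_log2 = 0.25,
                             coi_mask = FALSE, standardize = FALSE,
                             power_def = c("modulus", "squared"),
                             qom_mode = c("path_length", "mean_speed"),
                             sg_window = 25, sg_polyorder = 3) {
  structure(list(omega0 = omega0, dj = dj,
                 band_half_width_log2 = band_half_width_log2,
                 coi_mask = coi_mask, standardize = standardize,
                 power_def = match.arg(power_def),
                 qom_mode = match.arg(qom_mode),
                 sg_window = sg_window, sg_polyorder = sg_polyorder),
            class = "pipeline_control")
}

stage <- function(name, session_id, expr) {
  tryCatch(expr, error = function(e)
    stop_ds("stage ", name, " failed for session ", session_id, ": ",
            conditionMessage(e)))
}

#' Analyse one duo session end to end
#'
#' Runs the full per-session flow: interpolate missing beats, compute the
#' tempo summary, phrase-level durations and narrow bands; Savitzky-Golay
#' velocities and speeds of the two front-head markers; Morlet cross-wavelet
#' transform (pianist first channel); time-averaged power curve and its top
#' peaks; band aggregates with leadership calls and the dominant level;
#' per-section and solo/together aggregates; quantity of motion over all
#' non-hip markers.
#'
#' @param session list with \code{manifest} (\code{\link{session_manifest}}),
#'   \code{beats} (\code{\link{beat_track}}), \code{sections}
#'   (\code{\link{section_set}} or NULL), \code{pianist}, \code{singer}
#'   (named lists of \code{\link{marker_trajectory}}, including
#'   \code{front_head}).
#' @param control a \code{\link{pipeline_control}}.
#' @return List bundle with all per-session results.
#' @export
analyze_session <- function(session, control = pipeline_control()) {
  man <- session$manifest
  sid <- paste0(man$duo_id, "/", man$piece, "/t", man$take)
  beats <- stage("tempo.interpolate_missing_beats", sid,
                 interpolate_missing_beats(session$beats))
  tempo <- stage("tempo.compute_tempo", sid, compute_tempo(beats))
  levels <- stage("tempo.phrase_levels", sid,
                  phrase_levels(tempo, man$meter_beats_per_bar))
  broadband <- c(man$broadband_low_s, man$broadband_high_s)
  bands <- stage("tempo.make_bands", sid,
                 make_bands(levels, broadband, control$band_half_width_log2))
  heads <- lapply(list(pianist = session$pianist$front_head,
                       singer = session$singer$front_head),
                  function(tr) {
                    if (is.null(tr)) stop_ds("front_head marker missing")
                    speed(sg_velocity(tr, control$sg_window,
                                      control$sg_polyorder))
                  })
  grid <- stage("xwt.scale_grid", sid,
                scale_grid(broadband[1L], broadband[2L],
                           dj = control$dj, omega0 = control$omega0))
  field <- stage("xwt.cross_wavelet", sid,
                 cross_wavelet(heads$pianist, heads$singer, grid,
                               power_def = control$power_def,
                               standardize = control$standardize))
  mask <- NULL
  curve <- stage("xwt.time_average_power", sid,
                 time_average_power(field, coi_only = control$coi_mask))
  peaks <- stage("coordination.find_top_peaks", sid, find_top_peaks(curve))
  aggregates <- stage("coordination.aggregate_bands", sid,
                      aggregate_bands(field, bands, mask = mask))
  dominant <- stage("coordination.dominant_level", sid,
                    dominant_level(aggregates))
  segments <- if (!is.null(session$sections))
    stage("coordination.segment_aggregate", sid,
          segment_aggregate(field, bands, session$sections, beats)) else NULL
  all_markers <- c(session$pianist, session$singer)
  non_hip <- all_markers[!grepl("hip", vapply(all_markers, `[[`, character(1L),
                                              "marker"), ignore.case = TRUE)]
  qom <- stage("kinematics.quantity_of_motion", sid,
               quantity_of_motion(
                 lapply(non_hip, function(tr)
                   speed(sg_velocity(tr, control$sg_window,
                                     control$sg_polyorder))),
                 mode = control$qom_mode))
  list(manifest = man, tempo = tempo, levels = levels, bands = bands,
       field = field, curve = curve, peaks = peaks,
       aggregates = aggregates, dominant = dominant, segments = segments,
       qom = qom)
}

#' Analyse a cohort of sessions and fit the model battery
#'
#' Applies \code{\link{analyze_session}} to every session, assembles the
#' cohort tables (band aggregates, peak occurrences, dominant levels,
#' leadership calls, quantity of motion) and fits the model battery that the
#' tables support: power against phrase level (take nested, duo random
#' intercept with OLS fallback) and, at the dominant level, power and phase
#' against the performers' EPT scores.
#'
#' @param cohort a \code{duo_cohort} from \code{\link{simulate_cohort}}, or a
#'   plain list of session lists.
#' @param control a \code{\link{pipeline_control}}.
#' @param keep_fields keep each session's full XWT field in the result
#'   (default \code{FALSE}; they are large).
#' @return List with \code{sessions} (per-session bundles),
#'   \code{band_table}, \code{peak_table}, \code{dominant_table},
#'   \code{qom_table} and \code{fits}.
#' @export
analyze_cohort <- function(cohort, control = pipeline_control(),
                           keep_fields = FALSE) {
  sessions <- if (inherits(cohort, "duo_cohort")) cohort$sessions else cohort
  results <- lapply(sessions, function(s) {
    r <- analyze_session(s, control)
    if (!keep_fields) r$field <- NULL
    r
  })
  band_table <- do.call(rbind, lapply(results, function(r)
    cbind(duo_id = r$manifest$duo_id, piece = r$manifest$piece,
          take = r$manifest$take, pianist_ept = r$manifest$pianist_ept,
          singer_ept = r$manifest$singer_ept,
          ept_group = r$manifest$ept_group, r$aggregates)))
  peak_table <- tabulate_peak_occurrence(lapply(results, `[[`, "peaks"),
                                         lapply(results, `[[`, "bands"))
  dominant_table <- do.call(rbind, lapply(results, function(r) {
    dom <- r$dominant
    row <- r$aggregates[as.character(r$aggregates$level) ==
                          as.character(dom), ]
    data.frame(duo_id = r$manifest$duo_id, piece = r$manifest$piece,
               take = r$manifest$take, pianist_ept = r$manifest$pianist_ept,
               singer_ept = r$manifest$singer_ept,
               dominant_level = as.character(dom),
               mean_power = row$mean_power, phase_ms = row$phase_ms,
               mean_phase_rad = row$mean_phase_rad,
               leadership = as.character(row$leadership),
               phase_regime = as.character(row$phase_regime))
  }))
  qom_table <- do.call(rbind, lapply(results, function(r)
    data.frame(duo_id = r$manifest$duo_id, piece = r$manifest$piece,
               take = r$manifest$take, pianist_ept = r$manifest$pianist_ept,
               singer_ept = r$manifest$singer_ept,
               qom = mean(r$qom$values))))
  fits <- list()
  if (length(unique(band_table$duo_id)) >= 2L) {
    fits$power_by_level <- fit_model(
      model_spec("mean_power", "level", random_intercept = "duo_id",
                 baselines = list(level = "four_bars")),
      band_table)
  }
  # the per-musician EPT models need a few distinct duos to be identifiable
  if (nrow(dominant_table) >= 4L &&
      length(unique(dominant_table$singer_ept)) >= 2L &&
      length(unique(dominant_table$pianist_ept)) >= 2L) {
    fits$phase_by_ept <- fit_model(
      model_spec("phase_ms", c("pianist_ept", "singer_ept")),
      dominant_table)
    fits$power_by_ept <- fit_model(
      model_spec("mean_power", c("pianist_ept", "singer_ept")),
      dominant_table)
    fits$qom_by_ept <- fit_model(
      model_spec("qom", c("pianist_ept", "singer_ept")), qom_table)
  }
  rownames(band_table) <- NULL
  list(sessions = results, band_table = band_table, peak_table = peak_table,
       dominant_table = dominant_table, qom_table = qom_table, fits = fits,
       control = control)
}

#' Run the full pipeline from a declarative configuration
#'
#' One-command synthetic end-to-end run: simulates a cohort, analyses every
#' session, fits the cohort models and (optionally) writes all result tables
#' plus a JSON metadata sidecar. The configuration is a named list, or a
#' path to a YAML file with the same structure:
#' \preformatted{
#' cohort:           # passed to cohort_spec()
#'   n_duos: 6
#'   lead_slope: 0.02
#'   noise_sd: 2
#'   seed: 1
#' template:         # passed to piece_template() (optional)
#'   n_bars: 60
#' control:          # passed to pipeline_control() (optional)
#'   dj: 0.05
#' out_dir: results/ # optional; omit to skip writing
#' }
#'
#' @param config named list or YAML file path.
#' @return The \code{\link{analyze_cohort}} bundle, with the cohort truth
#'   table attached as \code{truth}, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_ds("config must be a named list or a YAML path")
  spec <- do.call(cohort_spec, config$cohort %||% list())
  template <- do.call(piece_template, config$template %||% list())
  control <- do.call(pipeline_control, config$control %||% list())
  cohort <- simulate_cohort(spec, template)
  bundle <- analyze_cohort(cohort, control)
  bundle$truth <- cohort$truth
  if (!is.null(config$out_dir)) {
    tables <- list(band_aggregates = bundle$band_table,
                   peak_occurrence = bundle$peak_table,
                   dominant_levels = bundle$dominant_table,
                   quantity_of_motion = bundle$qom_table,
                   ground_truth = bundle$truth)
    model_rows <- do.call(rbind, lapply(names(bundle$fits), function(nm) {
      f <- bundle$fits[[nm]]
      cbind(model = nm, engine = f$engine, fallback = f$fallback,
            r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional,
            f$coefficients)
    }))
    if (!is.null(model_rows)) tables$model_summaries <- model_rows
    write_results(tables, config$out_dir,
                  config = c(unclass(control),
                             list(cohort = unclass(spec))),
                  seed = spec$seed)
  }
  invisible(bundle)
}
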