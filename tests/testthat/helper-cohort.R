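# Lean per-duo leadership measurement: front-head speeds -> cross-wavelet
# restricted to one phrase-level band -> band-aggregated phase in ms.
# Composes only package functions; used where many duos must be measured.
measure_phase_ms <- function(session, level = "two_bars", dj = 1 / 10) {
  beats <- interpolate_missing_beats(session$beats)
  lv <- phrase_levels(compute_tempo(beats),
                      session$manifest$meter_beats_per_bar)
  bands <- make_bands(lv, c(session$manifest$broadband_low_s,
                            session$manifest$broadband_high_s))
  band <- bands[bands$level == level, ]
  sp_p <- speed(sg_velocity(session$pianist$front_head))
  sp_s <- speed(sg_velocity(session$singer$front_head))
  g <- scale_grid(band$period_low_s, band$period_high_s, dj = dj)
  f <- cross_wavelet(sp_p, sp_s, g)
  band_aggregate(f, band)$phase_ms
}
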