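make_curve <- function(power) data.frame(period_s = seq_along(power),
                                         power = power)

test_that("peak finding: monotone curves, plateaus, ranking and ties", {
  expect_equal(nrow(find_top_peaks(make_curve(1:6))), 0)
  expect_equal(nrow(find_top_peaks(make_curve(6:1))), 0)

  one <- find_top_peaks(make_curve(c(1, 5, 2)))
  expect_equal(one$period_s, 2)
  expect_equal(one$power, 5)

  # plateau counts once, at its left-most index
  plat <- find_top_peaks(make_curve(c(1, 4, 4, 4, 2, 3, 1)))
  expect_equal(plat$period_s, c(2, 6))

  # equal-power peaks: tie broken toward the longer period
  tie <- find_top_peaks(make_curve(c(1, 7, 1, 7, 1)), k = 1)
  expect_equal(tie$period_s, 4)

  expect_error(find_top_peaks(make_curve(c(1, 2))), "at least 3")
})

test_that("peaks of a planted two-component duo sit at the planted periods", {
  lv <- test_levels()
  m <- gen_duo_motion(40, 30, lv,
                      list(planted_component("one_bar", 10),
                           planted_component("two_bars", 5)))
  f <- cross_wavelet(speed(sg_velocity(m$pianist$front_head)),
                     speed(sg_velocity(m$singer$front_head)),
                     scale_grid(0.2, 6.2, dj = 1 / 20))
  pk <- find_top_peaks(time_average_power(f), k = 2)
  expect_equal(sort(pk$period_s), c(1, 2), tolerance = 2^(1 / 20) - 1 + 0.02)
  # amplitude order: the 1-bar component (amplitude 10) ranks first
  expect_lt(abs(log2(pk$period_s[1] / 1)), 1 / 20 + 0.03)
})

test_that("peak occurrence tabulation assigns bands and sums to 100%", {
  bands <- make_bands(test_levels(), c(0.2, 6.2))
  inside2 <- data.frame(period_s = c(1.9, 2.1), power = c(3, 2))
  t1 <- tabulate_peak_occurrence(list(inside2), list(bands))
  expect_equal(t1$pct[t1$level == "two_bars"], 100)

  mixed <- data.frame(period_s = c(2, 6.0), power = c(3, 2))
  t2 <- tabulate_peak_occurrence(list(mixed), list(bands))
  expect_equal(t2$pct[t2$level == "two_bars"], 50)
  expect_equal(t2$pct[t2$level == "outside"], 50)
  expect_equal(sum(t2$pct), 100, tolerance = 0.1)
})

test_that("band aggregation: constant phase, uniform phase, lagged sinusoid", {
  fs <- 16
  tt <- seq(0, 64 - 1 / fs, by = 1 / fs)
  nt <- length(tt)
  bands <- make_bands(test_levels(), c(0.2, 6.2))
  b2 <- bands[bands$level == "two_bars", ]

  g <- scale_grid(0.2, 6.2, dj = 1 / 10)
  rows <- sum(g$periods_s >= b2$period_low_s & g$periods_s < b2$period_high_s)
  field <- structure(list(
    power = matrix(3, length(g$periods_s), nt),
    phase_rad = matrix(pi / 4, length(g$periods_s), nt),
    periods_s = g$periods_s, times_s = tt,
    coi_s = rep(Inf, nt), fs = fs, power_def = "modulus",
    channels = c(first = "pianist", second = "singer")),
    class = "xwt_field")
  agg <- band_aggregate(field, b2)
  expect_equal(agg$mean_power, 3)
  expect_equal(agg$mean_phase_rad, pi / 4)
  expect_equal(agg$resultant_length, 1)
  expect_equal(agg$n_cells, rows * nt)

  # phases spread uniformly on the circle: resultant length collapses
  set.seed(2)
  field$phase_rad <- matrix(runif(length(g$periods_s) * nt, -pi, pi),
                            length(g$periods_s), nt)
  expect_lt(band_aggregate(field, b2)$resultant_length, 0.05)

  # real lagged pair: band mean phase recovers 2 pi tau / P
  P <- 2; tau <- 0.25
  x <- speed_fixture(10 + 4 * sin(2 * pi * tt / P), fs)
  y <- speed_fixture(10 + 4 * sin(2 * pi * (tt - tau) / P), fs, "singer")
  fxy <- cross_wavelet(x, y, g)
  agg2 <- band_aggregate(fxy, b2)
  expect_equal(agg2$mean_phase_rad, 2 * pi * tau / P, tolerance = 0.03)
  expect_equal(agg2$phase_ms, 1000 * tau, tolerance = 1000 * tau * 0.05)
  expect_equal(as.character(agg2$leadership), "pianist_leads")

  expect_error(band_aggregate(fxy, list(level = "x", duration_s = 9,
                                        period_low_s = 8, period_high_s = 10)),
               "no period")
})

test_that("dominant level takes the maximal power, ties to shorter period", {
  lvls <- c("half_bar", "one_bar", "two_bars", "three_bars", "four_bars")
  agg <- data.frame(level = factor(lvls, levels = lvls),
                    mean_power = c(5, 3, 1, 1, 1))
  expect_equal(as.character(dominant_level(agg)), "half_bar")
  agg$mean_power <- rep(2, 5)
  d <- dominant_level(agg)
  expect_equal(as.character(d), "half_bar")
  expect_true(attr(d, "tie"))
})

test_that("dominant level of a planted single-component duo is recovered", {
  lv <- test_levels()
  m <- gen_duo_motion(30, 24, lv,
                      list(planted_component("two_bars", 10)),
                      noise_sd = 1, seed = 6)
  f <- cross_wavelet(speed(sg_velocity(m$pianist$front_head)),
                     speed(sg_velocity(m$singer$front_head)),
                     scale_grid(0.2, 6.2))
  agg <- aggregate_bands(f, make_bands(lv, c(0.2, 6.2)))
  expect_equal(as.character(dominant_level(agg)), "two_bars")
})

test_that("the quadrant scheme matches the interval statement on a grid", {
  phi <- seq(-pi + 1e-9, pi, length.out = 1000)
  got <- phase_to_leadership(phi)
  want <- quadrant_oracle(phi)
  expect_equal(as.character(got$leadership), want$leadership)
  expect_equal(as.character(got$phase_regime), want$phase_regime)

  spot <- phase_to_leadership(c(pi / 4, -3 * pi / 4, 0))
  expect_equal(as.character(spot$leadership),
               c("pianist_leads", "pianist_leads", "in_sync"))
  expect_equal(as.character(spot$phase_regime),
               c("in_phase", "out_of_phase", "in_phase"))
})

test_that("negating the phase swaps leadership except at 0 and pi", {
  set.seed(14)
  phi <- runif(300, -pi + 1e-6, pi - 1e-6)
  phi <- phi[phi != 0 & abs(abs(phi) - pi / 2) > 1e-9]
  a <- phase_to_leadership(phi)$leadership
  b <- phase_to_leadership(-phi)$leadership
  swapped <- ifelse(a == "pianist_leads", "singer_leads",
                    ifelse(a == "singer_leads", "pianist_leads", "in_sync"))
  expect_equal(as.character(b), swapped)
})

test_that("phase-to-ms conversion is linear in phase and period", {
  expect_equal(phase_to_ms(-pi / 2, 4), -1000)
  expect_equal(phase_to_ms(0, 7.7), 0)
  expect_equal(phase_to_ms(pi, 1), 500)
  expect_error(phase_to_ms(1, -2), "positive")
})

test_that("section aggregates respect the weighted-mean identity", {
  lv <- test_levels()
  m <- gen_duo_motion(40, 24, lv,
                      list(planted_component("two_bars", 10)),
                      noise_sd = 0.5, seed = 3)
  gen <- gen_beat_track(40, 2, 0.5)
  f <- cross_wavelet(speed(sg_velocity(m$pianist$front_head)),
                     speed(sg_velocity(m$singer$front_head)),
                     scale_grid(0.2, 6.2, dj = 1 / 10))
  bands <- make_bands(lv, c(0.2, 6.2))

  whole <- section_set("all", 0, 80, FALSE)
  seg_whole <- segment_aggregate(f, bands, whole, gen$track)
  expect_equal(seg_whole$by_section$mean_power,
               aggregate_bands(f, bands)$mean_power, tolerance = 1e-12)

  halves <- section_set(c("A", "B"), c(0, 40), c(40, 80), c(FALSE, TRUE))
  seg <- segment_aggregate(f, bands, halves, gen$track)
  wA <- sum(f$times_s < 20); wB <- sum(f$times_s >= 20 & f$times_s < 40)
  pA <- seg$by_section$mean_power[seg$by_section$section == "A"]
  pB <- seg$by_section$mean_power[seg$by_section$section == "B"]
  expect_equal((wA * pA + wB * pB) / (wA + wB),
               aggregate_bands(f, bands)$mean_power, tolerance = 1e-10)

  solo <- seg$by_solo_together
  expect_equal(solo$mean_power[solo$grouping == "solo"], pB, tolerance = 1e-12)
})

test_that("a component confined to together sections raises together power", {
  lv <- test_levels()
  m <- gen_duo_motion(48, 24, lv,
                      list(planted_component("two_bars", 10,
                                             time_support = c(0, 24))),
                      noise_sd = 0.5, seed = 13)
  gen <- gen_beat_track(48, 2, 0.5)
  f <- cross_wavelet(speed(sg_velocity(m$pianist$front_head)),
                     speed(sg_velocity(m$singer$front_head)),
                     scale_grid(0.2, 6.2, dj = 1 / 10))
  bands <- make_bands(lv, c(0.2, 6.2))
  secs <- section_set(c("together", "solo"), c(0, 48), c(48, 96),
                      c(FALSE, TRUE))
  seg <- segment_aggregate(f, bands, secs, gen$track)
  st <- seg$by_solo_together
  b2 <- st$level == "two_bars"
  expect_gt(st$mean_power[b2 & st$grouping == "together"],
            st$mean_power[b2 & st$grouping == "solo"])
})
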