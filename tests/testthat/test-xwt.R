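test_that("scale grid is geometric with ratio 2^dj", {
  g <- scale_grid(0.2, 6.2, dj = 1 / 20)
  expect_true(all(diff(g$periods_s) > 0))
  expect_equal(diff(log2(g$periods_s)),
               rep(1 / 20, length(g$periods_s) - 1), tolerance = 1e-12)
  expect_equal(g$fourier_factor, 4 * pi / (6 + sqrt(38)))
})

test_that("CWT of the zero series is zero; sub-Nyquist periods are rejected", {
  fs <- 16
  x <- speed_fixture(rep(0, 128), fs)
  g <- scale_grid(0.5, 4)
  expect_equal(max(Mod(morlet_cwt(x, g)$coef)), 0)
  expect_error(morlet_cwt(speed_fixture(rnorm(128), fs), scale_grid(0.05, 4)),
               "Nyquist")
})

test_that("CWT power of a sinusoid peaks at its period", {
  fs <- 16
  tt <- seq(0, 256 - 1 / fs, by = 1 / fs)
  x <- speed_fixture(sin(2 * pi * tt / 8), fs)
  g <- scale_grid(2, 32, dj = 1 / 20)
  cw <- morlet_cwt(x, g)
  curve <- rowMeans(Mod(cw$coef)^2)
  peak_period <- g$periods_s[which.max(curve)]
  expect_lt(abs(log2(peak_period / 8)), 1 / 20 + 1e-9)
})

test_that("FFT CWT matches the direct convolution oracle", {
  set.seed(99)
  fs <- 16
  n <- 256   # the acceptance suite repeats this at length 512
  x <- rnorm(n)
  g <- scale_grid(0.5, 8, dj = 1 / 10)
  W_fft <- morlet_cwt(speed_fixture(x, fs), g)$coef
  W_dir <- cwt_convolution_oracle(x, fs, g$periods_s)
  rel <- Mod(W_fft - W_dir) / max(Mod(W_dir))
  expect_lt(max(rel), 1e-10)
})

test_that("cross-wavelet of a series with itself has zero phase, power |Wx|^2", {
  set.seed(4)
  fs <- 10
  x <- speed_fixture(rnorm(200), fs)
  g <- scale_grid(0.5, 5)
  f <- cross_wavelet(x, x, g)
  expect_equal(max(abs(f$phase_rad)), 0, tolerance = 1e-10)
  Wx <- morlet_cwt(x, g)$coef
  expect_equal(f$power, Mod(Wx)^2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("lagged sinusoids yield phase 2 pi tau / P at the period", {
  fs <- 16; P <- 4; tau <- P / 8
  tt <- seq(0, 64 - 1 / fs, by = 1 / fs)
  x <- speed_fixture(10 + 3 * sin(2 * pi * tt / P), fs)
  y <- speed_fixture(10 + 3 * sin(2 * pi * (tt - tau) / P), fs,
                     performer = "singer")
  f <- cross_wavelet(x, y, scale_grid(1, 8))
  row <- which.min(abs(f$periods_s - P))
  outside <- f$coi_s >= P
  ph <- f$phase_rad[row, outside]
  expect_equal(mean(ph), pi / 4, tolerance = 0.02 * pi / 4)
})

test_that("swapping channels negates phase and preserves power", {
  set.seed(12)
  fs <- 10
  x <- speed_fixture(rnorm(300), fs)
  y <- speed_fixture(rnorm(300), fs, performer = "singer")
  g <- scale_grid(0.5, 5)
  f_xy <- cross_wavelet(x, y, g)
  f_yx <- cross_wavelet(y, x, g)
  expect_equal(f_yx$power, f_xy$power, tolerance = 1e-12)
  expect_equal(wrap_unwrap <- sin(f_yx$phase_rad), -sin(f_xy$phase_rad),
               tolerance = 1e-9)
  expect_equal(cos(f_yx$phase_rad), cos(f_xy$phase_rad), tolerance = 1e-9)
})

test_that("mismatched inputs are rejected", {
  g <- scale_grid(0.5, 2)
  expect_error(cross_wavelet(speed_fixture(rnorm(100), 10),
                             speed_fixture(rnorm(90), 10), g), "length")
  expect_error(cross_wavelet(speed_fixture(rnorm(100), 10),
                             speed_fixture(rnorm(100), 20), g), "rates")
})

test_that("phase of independent noise has vanishing mean resultant length", {
  set.seed(7)
  fs <- 8
  g <- scale_grid(0.5, 2, dj = 1 / 4)
  r_short <- r_long <- numeric(3)
  for (i in 1:3) {
    mk <- function(n) cross_wavelet(speed_fixture(rnorm(n), fs),
                                    speed_fixture(rnorm(n), fs), g)
    f1 <- mk(128); f2 <- mk(4096)
    row <- which.min(abs(f1$periods_s - 1))
    r_short[i] <- Mod(mean(exp(1i * f1$phase_rad[row, ])))
    r_long[i] <- Mod(mean(exp(1i * f2$phase_rad[row, ])))
  }
  expect_lt(mean(r_long), mean(r_short))
  expect_lt(mean(r_long), 0.15)
})

test_that("time-averaged power obeys the complementary-mask identity", {
  set.seed(31)
  fs <- 10
  f <- cross_wavelet(speed_fixture(rnorm(400), fs),
                     speed_fixture(rnorm(400), fs), scale_grid(0.5, 5))
  full <- time_average_power(f)
  m1 <- seq_len(400) <= 150
  p1 <- time_average_power(f, mask = m1)
  p2 <- time_average_power(f, mask = !m1)
  expect_equal(full$power, (150 * p1$power + 250 * p2$power) / 400,
               tolerance = 1e-12)
  one <- time_average_power(f, mask = seq_len(400) == 7)
  expect_equal(one$power, f$power[, 7], tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(time_average_power(f, mask = rep(FALSE, 400)), "no timestamps")
})
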