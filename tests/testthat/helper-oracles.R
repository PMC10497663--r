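# Independent oracles and fixture builders used across the suite.

# Build a speed_series from raw values without going through the kinematics
# chain (for direct wavelet-level tests).
speed_fixture <- function(values, fs, performer = "pianist",
                          marker = "front_head") {
  structure(list(performer = performer, marker = marker, fs = fs,
                 values = values),
            class = "speed_series")
}

# Direct time-domain Morlet CWT by explicit convolution (quadratic cost):
#   W_n(s) = sum_m x_m * sqrt(dt/s) * Conj(psi((m - n) * dt / s))
# with psi(eta) = pi^(-1/4) * exp(i * omega0 * eta - eta^2 / 2).
# Deliberately shares no code with the package's FFT implementation.
cwt_convolution_oracle <- function(x, fs, periods, omega0 = 6) {
  dt <- 1 / fs
  n <- length(x)
  xc <- x - mean(x)
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods / ff
  W <- matrix(0i, nrow = length(scales), ncol = n)
  idx <- seq_len(n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    eta <- outer(idx, idx, function(m, nn) (m - nn) * dt / s)
    psi_conj <- pi^(-0.25) * exp(-1i * omega0 * eta - eta^2 / 2)
    W[j, ] <- sqrt(dt / s) * as.vector(crossprod(psi_conj, xc))
  }
  W
}

# Fig.-3 quadrant scheme, written directly from the interval statement
# (pianist leads on [0, pi/2] u [-pi, -pi/2]; singer on [pi/2, pi] u
# [-pi/2, 0]; tie rules: 0 in sync, +/-pi/2 and pi to the upper interval).
quadrant_oracle <- function(phi) {
  lead <- character(length(phi))
  for (i in seq_along(phi)) {
    p <- phi[i]
    lead[i] <-
      if (p == 0) "in_sync"
      else if (p >= pi / 2) "singer_leads"          # [pi/2, pi]
      else if (p > 0) "pianist_leads"               # (0, pi/2)
      else if (p >= -pi / 2) "singer_leads"         # [-pi/2, 0)
      else "pianist_leads"                          # (-pi, -pi/2)
  }
  regime <- ifelse(abs(phi) < pi / 2, "in_phase", "out_of_phase")
  data.frame(leadership = lead, phase_regime = regime)
}

# default phrase levels used by many tests: duple meter, IBI 0.5 s
# -> half bar 0.5 s, one bar 1 s, two 2 s, three 3 s, four 4 s
test_levels <- function(mean_ibi = 0.5, beats_per_bar = 2) {
  phrase_levels(mean_ibi, beats_per_bar)
}

# random 3-D rotation matrix from QR of a Gaussian matrix
random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
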