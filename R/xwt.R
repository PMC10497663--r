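#' Scale grid for the Morlet wavelet transform
#'
#' Builds a geometric grid of Fourier periods from \code{period_low_s} to
#' \code{period_high_s} with \code{dj} sub-octaves between consecutive scales.
#' Periods relate to wavelet scales via the Morlet Fourier factor
#' \code{4*pi / (omega0 + sqrt(2 + omega0^2))}.
#'
#' @param period_low_s,period_high_s broadband period range in seconds,
#'   0 < low < high.
#' @param dj scale resolution in octaves (default 1/20: 20 scales per octave).
#' @param omega0 central frequency of the Morlet mother wavelet (default 6,
#'   the usual admissibility/resolution compromise).
#' @return Object of class \code{scale_grid} with \code{periods_s},
#'   \code{scales_s}, \code{dj}, \code{omega0}, \code{fourier_factor}.
#' @export
scale_grid <- function(period_low_s, period_high_s, dj = 1 / 20, omega0 = 6) {
  if (!is.numeric(period_low_s) || !is.numeric(period_high_s) ||
      period_low_s <= 0 || period_low_s >= period_high_s)
    stop_ds("need 0 < period_low_s < period_high_s")
  if (dj <= 0) stop_ds("dj must be positive")
  if (omega0 <= 0) stop_ds("omega0 must be positive")
  n_oct <- log2(period_high_s / period_low_s)
  periods <- period_low_s * 2^(seq(0, n_oct, by = dj))
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  structure(list(periods_s = periods, scales_s = periods / ff,
                 dj = dj, omega0 = omega0, fourier_factor = ff),
            class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf(
    "<scale_grid> %d periods %.4g-%.4g s (dj=%.4g, omega0=%g)\n",
    length(x$periods_s), min(x$periods_s), max(x$periods_s), x$dj, x$omega0))
  invisible(x)
}

# Morlet wavelet in the frequency domain, evaluated at s*omega for all
# frequencies (no analytic cutoff, no admissibility correction term); this is
# the exact Fourier transform of pi^(-1/4) exp(i*omega0*eta - eta^2/2) up to
# the negligible correction, and matches a time-domain convolution with that
# wavelet to machine precision.
morlet_hat <- function(s_omega, omega0) {
  pi^(-0.25) * exp(-0.5 * (s_omega - omega0)^2)
}

# pad length: next power of two that also clears the largest wavelet tail,
# so circular FFT convolution equals linear convolution to ~1e-14
pad_length <- function(n, max_scale_samples) {
  L <- 2^ceiling(log2(n))
  while (L - n < 8 * max_scale_samples) L <- 2L * L
  L
}

as_speed_values <- function(x) {
  if (inherits(x, "speed_series")) list(values = x$values, fs = x$fs)
  else stop_ds("expected a speed_series")
}

#' Morlet continuous wavelet transform
#'
#' FFT-based CWT of a speed series on a geometric scale grid, with unit-energy
#' scale normalisation (Torrence-Compo convention): the series is
#' mean-centered (optionally variance-standardised), zero-padded, transformed,
#' multiplied per scale by \code{sqrt(2*pi*s/dt) * psi_hat(s*omega)} and
#' inverse-transformed. The cone of influence (the period below which a
#' coefficient is free of edge effects, per the e-folding time
#' \code{sqrt(2)*s}) is recorded per timestamp.
#'
#' @param x a \code{speed_series} (any zero-mean analysis signal works).
#' @param grid a \code{\link{scale_grid}}; its shortest period must be at
#'   least two sampling steps (Nyquist).
#' @param standardize divide the centered series by its SD before
#'   transforming (default \code{FALSE}).
#' @return Object of class \code{cwt_field}: complex \code{coef} matrix
#'   (periods in rows, times in columns), \code{periods_s}, \code{times_s},
#'   \code{coi_s}, \code{fs}, plus the grid parameters.
#' @export
morlet_cwt <- function(x, grid, standardize = FALSE) {
  sv <- as_speed_values(x)
  stopifnot(inherits(grid, "scale_grid"))
  vals <- sv$values; fs <- sv$fs; dt <- 1 / fs
  n <- length(vals)
  if (n < 2L) stop_ds("series must have length >= 2")
  if (min(grid$periods_s) < 2 * dt)
    stop_ds("requested period ", signif(min(grid$periods_s), 4),
            " s is below the Nyquist period ", signif(2 * dt, 4), " s")
  vals <- vals - mean(vals)
  if (standardize) {
    s0 <- sd(vals)
    if (s0 > 0) vals <- vals / s0
  }
  scales <- grid$scales_s
  L <- pad_length(n, max(scales) / dt)
  xpad <- c(vals, rep(0, L - n))
  xhat <- fft(xpad)
  k <- c(0:(L / 2), -((L / 2 - 1):1))
  omega <- 2 * pi * k / (L * dt)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    daughter <- sqrt(2 * pi * s / dt) * morlet_hat(s * omega, grid$omega0)
    W[j, ] <- (fft(xhat * daughter, inverse = TRUE) / L)[seq_len(n)]
  }
  times <- (seq_len(n) - 1L) * dt
  dmin <- pmax(pmin(times, times[n] - times), dt / 2)
  coi <- grid$fourier_factor / sqrt(2) * dmin
  structure(list(coef = W, periods_s = grid$periods_s, times_s = times,
                 coi_s = coi, fs = fs, dj = grid$dj, omega0 = grid$omega0,
                 fourier_factor = grid$fourier_factor,
                 standardize = standardize),
            class = "cwt_field")
}

#' Cross-wavelet transform of the two performers' speed series
#'
#' Computes \code{Wxy = Wx * Conj(Wy)} from the Morlet CWTs of the pianist
#' (first channel) and singer (second channel). The modulus of \code{Wxy}
#' measures the strength of joint oscillation at each time and period; its
#' argument is the phase difference. With the pianist first, a positive phase
#' in the in-phase regime means the pianist's oscillation is earlier in the
#' cycle (pianist leads); swapping the inputs negates the phase.
#'
#' @param x_pianist,y_singer \code{speed_series} of equal length and sampling
#'   rate.
#' @param grid a \code{\link{scale_grid}}.
#' @param power_def \code{"modulus"} (default) for \code{|Wxy|} or
#'   \code{"squared"} for \code{|Wxy|^2}.
#' @param standardize passed to \code{\link{morlet_cwt}} for both channels.
#' @return Object of class \code{xwt_field}: \code{power} and \code{phase_rad}
#'   matrices (periods in rows, times in columns; phase in (-pi, pi]),
#'   \code{periods_s}, \code{times_s}, \code{coi_s}, \code{channels}.
#' @export
cross_wavelet <- function(x_pianist, y_singer, grid,
                          power_def = c("modulus", "squared"),
                          standardize = FALSE) {
  power_def <- match.arg(power_def)
  sx <- as_speed_values(x_pianist); sy <- as_speed_values(y_singer)
  if (length(sx$values) != length(sy$values))
    stop_ds("series lengths differ (", length(sx$values), " vs ",
            length(sy$values), ")")
  if (!isTRUE(all.equal(sx$fs, sy$fs)))
    stop_ds("sampling rates differ (", sx$fs, " vs ", sy$fs, " Hz)")
  Wx <- morlet_cwt(x_pianist, grid, standardize = standardize)
  Wy <- morlet_cwt(y_singer, grid, standardize = standardize)
  Wxy <- Wx$coef * Conj(Wy$coef)
  power <- Mod(Wxy)
  if (power_def == "squared") power <- power^2
  structure(list(power = power, phase_rad = wrap_phase(Arg(Wxy)),
                 periods_s = Wx$periods_s, times_s = Wx$times_s,
                 coi_s = Wx$coi_s, fs = Wx$fs,
                 power_def = power_def,
                 channels = c(first = "pianist", second = "singer")),
            class = "xwt_field")
}

#' @export
print.xwt_field <- function(x, ...) {
  cat(sprintf(
    "<xwt_field> %d periods x %d times (%.4g-%.4g s periods, %.3g s, fs %g Hz)\n",
    nrow(x$power), ncol(x$power), min(x$periods_s), max(x$periods_s),
    max(x$times_s), x$fs))
  cat("  channels: first =", x$channels[["first"]],
      "/ second =", x$channels[["second"]],
      "| power =", x$power_def, "\n")
  invisible(x)
}

#' Time-averaged cross-wavelet power per period
#'
#' @param field an \code{xwt_field}.
#' @param mask optional logical vector over timestamps selecting which columns
#'   enter the average; must select at least one.
#' @param coi_only if \code{TRUE}, additionally restrict each period to
#'   timestamps outside the cone of influence.
#' @return Data frame of class \code{power_curve} with \code{period_s} and
#'   \code{power}.
#' @export
time_average_power <- function(field, mask = NULL, coi_only = FALSE) {
  stopifnot(inherits(field, "xwt_field") || inherits(field, "cwt_field"))
  pw <- if (inherits(field, "cwt_field")) Mod(field$coef)^2 else field$power
  nt <- ncol(pw)
  if (is.null(mask)) mask <- rep(TRUE, nt)
  if (length(mask) != nt) stop_ds("mask length must match the time axis")
  if (!any(mask)) stop_ds("mask selects no timestamps")
  if (coi_only) {
    valid <- outer(field$periods_s, field$coi_s, `<=`)
    valid[, !mask] <- FALSE
    if (any(rowSums(valid) == 0L))
      stop_ds("some periods have no timestamps outside the cone of influence")
    power <- rowSums(pw * valid) / rowSums(valid)
  } else {
    power <- rowMeans(pw[, mask, drop = FALSE])
  }
  out <- data.frame(period_s = field$periods_s, power = power)
  class(out) <- c("power_curve", "data.frame")
  out
}
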