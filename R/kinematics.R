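#' Marker trajectory: one marker's 3-D position series
#'
#' @param performer \code{"pianist"} or \code{"singer"}.
#' @param marker marker identifier (see the head/upper-body inventory in
#'   \code{duosync:::MARKER_INVENTORY}).
#' @param fs sampling rate in Hz.
#' @param xyz numeric matrix with n rows and 3 columns (x, y, z) in mm; no
#'   missing samples are allowed (gap filling is out of scope).
#' @return Object of class \code{marker_trajectory}.
#' @export
marker_trajectory <- function(performer, marker, fs, xyz) {
  performer <- match.arg(performer, c("pianist", "singer"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_ds("fs must be a single positive number")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop_ds("xyz must have three columns")
  if (anyNA(xyz) || any(!is.finite(xyz)))
    stop_ds("trajectory has missing or non-finite samples (marker ", marker, ")")
  colnames(xyz) <- c("x_mm", "y_mm", "z_mm")
  structure(list(performer = performer, marker = as.character(marker),
                 fs = fs, xyz = xyz),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %s/%s: %d samples @ %g Hz (%.3g s)\n",
              x$performer, x$marker, nrow(x$xyz), x$fs, nrow(x$xyz) / x$fs))
  invisible(x)
}

#' Savitzky-Golay velocity of a marker trajectory
#'
#' Smooths each position axis and differentiates it in one pass with a
#' Savitzky-Golay filter (local least-squares polynomial fit), scaled by the
#' sampling rate to mm/s. Boundary samples are computed from the same
#' polynomial fit over one-sided windows, so the output has the full input
#' length and stays aligned with beat timestamps.
#'
#' @param traj a \code{\link{marker_trajectory}}.
#' @param window odd filter window length in samples (default 25).
#' @param polyorder polynomial order (default 3; must be < window).
#' @return Object of class \code{velocity_series}: list with \code{performer},
#'   \code{marker}, \code{fs}, and an n-by-3 \code{vxyz} matrix in mm/s.
#' @export
sg_velocity <- function(traj, window = 25, polyorder = 3) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (!is_count(window) || window %% 2 != 1 || window < 3)
    stop_ds("window must be an odd integer >= 3")
  if (!is_count(polyorder) || polyorder < 1 || polyorder >= window)
    stop_ds("polyorder must be a positive integer smaller than window")
  n <- nrow(traj$xyz)
  if (n < window)
    stop_ds("series of length ", n, " is shorter than the filter window (",
            window, ")")
  vxyz <- apply(traj$xyz, 2L, function(col)
    signal::sgolayfilt(col, p = polyorder, n = window, m = 1, ts = 1 / traj$fs))
  colnames(vxyz) <- c("vx", "vy", "vz")
  structure(list(performer = traj$performer, marker = traj$marker,
                 fs = traj$fs, vxyz = vxyz),
            class = "velocity_series")
}

#' Scalar speed: Euclidean norm of a 3-D velocity series
#'
#' Speed is used as the analysis signal because, unlike position, it does not
#' depend on the performer's orientation in the capture volume.
#'
#' @param vel a \code{velocity_series} from \code{\link{sg_velocity}}, or an
#'   n-by-3 numeric matrix of velocities in mm/s.
#' @param performer,marker,fs metadata, required only when \code{vel} is a
#'   bare matrix.
#' @return Object of class \code{speed_series}: list with \code{performer},
#'   \code{marker}, \code{fs} and non-negative \code{values} in mm/s.
#' @export
speed <- function(vel, performer = NULL, marker = NULL, fs = NULL) {
  if (inherits(vel, "velocity_series")) {
    m <- vel$vxyz; performer <- vel$performer
    marker <- vel$marker; fs <- vel$fs
  } else {
    m <- as.matrix(vel)
    if (is.null(fs)) stop_ds("fs is required when vel is a bare matrix")
  }
  if (ncol(m) != 3L) stop_ds("velocity must have three columns")
  if (any(!is.finite(m))) stop_ds("velocity has non-finite values")
  structure(list(performer = performer, marker = marker, fs = fs,
                 values = sqrt(rowSums(m^2))),
            class = "speed_series")
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf("<speed_series> %s/%s: %d samples @ %g Hz, mean %.3g mm/s\n",
              x$performer %||% "?", x$marker %||% "?", length(x$values),
              x$fs, mean(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantity of motion per second
#'
#' QoM summarises the overall movement energy of the duo: for each whole
#' second of the recording, the path length travelled (integral of speed, in
#' mm) is summed over all supplied markers and performers. Only the 14
#' head/upper-body markers per performer enter this analysis; the singer's
#' extra hip markers must be excluded upstream and trigger an error here.
#'
#' @param speeds list of \code{speed_series} (all with identical sampling rate
#'   and length).
#' @param mode \code{"path_length"} (default): mm travelled per second;
#'   \code{"mean_speed"}: mean speed per second in mm/s.
#' @return Object of class \code{qom_series}: numeric vector, one value per
#'   whole second (length \code{floor(duration_s)}).
#' @export
quantity_of_motion <- function(speeds, mode = c("path_length", "mean_speed")) {
  mode <- match.arg(mode)
  if (inherits(speeds, "speed_series")) speeds <- list(speeds)
  if (length(speeds) == 0L) stop_ds("no speed series supplied")
  ok <- vapply(speeds, inherits, logical(1L), "speed_series")
  if (!all(ok)) stop_ds("speeds must be a list of speed_series")
  markers <- vapply(speeds, function(s) s$marker %||% "", character(1L))
  hips <- grepl("hip", markers, ignore.case = TRUE)
  if (any(hips))
    stop_ds("hip markers must be excluded from quantity of motion: ",
            paste(unique(markers[hips]), collapse = ", "))
  fs <- speeds[[1L]]$fs
  n <- length(speeds[[1L]]$values)
  same <- vapply(speeds, function(s)
    isTRUE(all.equal(s$fs, fs)) && length(s$values) == n, logical(1L))
  if (!all(same)) stop_ds("all speed series must share fs and length")
  n_sec <- floor(n / fs)
  if (n_sec < 1L) stop_ds("recording shorter than one second")
  total <- Reduce(`+`, lapply(speeds, `[[`, "values"))
  sec <- findInterval(seq_len(n) - 1L, fs * seq_len(n_sec))  # 0-based bins
  keep <- sec < n_sec
  bins <- factor(sec[keep], levels = 0:(n_sec - 1L))
  sums <- vapply(split(total[keep], bins), sum, numeric(1L))
  values <- if (mode == "path_length") sums / fs
            else sums / as.numeric(table(bins))
  structure(list(values = unname(values), mode = mode, fs = fs,
                 n_markers = length(speeds)),
            class = "qom_series")
}

#' @export
print.qom_series <- function(x, ...) {
  cat(sprintf("<qom_series> %d s, %d markers, mode %s, mean %.4g\n",
              length(x$values), x$n_markers, x$mode, mean(x$values)))
  invisible(x)
}
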