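#' Create a circular detector ring
#'
#' Places `n_detectors` point detectors equally spaced on a circle centred on
#' the imaging grid.
#'
#' @param n_detectors Number of detector positions (>= 1).
#' @param radius Ring radius in mm.
#' @param start_angle Angle of the first detector in radians (default 0).
#' @return A `pat_ring` with fields `n_detectors`, `radius`, `angles`
#'   (strictly increasing, spanning less than 2*pi) and `full_view = TRUE`.
#' @examples
#' ring <- make_detector_ring(80, 22)
#' diff(ring$angles)[1] * 180 / pi  # 4.5 degrees
#' @export
make_detector_ring <- function(n_detectors, radius, start_angle = 0) {
  n_detectors <- as.integer(n_detectors)
  if (is.na(n_detectors) || n_detectors < 1L)
    stop("n_detectors must be >= 1", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be positive", call. = FALSE)
  angles <- start_angle + (seq_len(n_detectors) - 1) * 2 * pi / n_detectors
  structure(
    list(n_detectors = n_detectors, radius = radius, angles = angles,
         full_view = TRUE),
    class = "pat_ring"
  )
}

#' Cartesian detector positions
#'
#' @param ring A `pat_ring`.
#' @return `n_detectors x 2` matrix of (x, y) positions in mm.
#' @export
ring_positions <- function(ring) {
  stopifnot(inherits(ring, "pat_ring"))
  cbind(ring$radius * cos(ring$angles), ring$radius * sin(ring$angles))
}

#' @export
print.pat_ring <- function(x, ...) {
  cat(sprintf("<pat_ring> %d detectors on a %g mm radius circle\n",
              x$n_detectors, x$radius))
  invisible(x)
}

#' Acquisition settings for time-resolved detection
#'
#' @param c Speed of sound in m/s; assumed homogeneous.
#' @param n_samples Time samples recorded per detector position.
#' @param dt Sampling period in seconds.
#' @param t0 Time of the first sample in seconds (time origin at the
#'   excitation pulse).
#' @return A `pat_acquisition`. The maximum resolvable frequency is
#'   `1/(2*dt)`.
#' @export
acquisition_settings <- function(c = 1500, n_samples = 512, dt = 50e-9, t0 = 0) {
  n_samples <- as.integer(n_samples)
  if (!is.finite(c) || c <= 0) stop("speed of sound must be positive", call. = FALSE)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  structure(
    list(c = c, n_samples = n_samples, dt = dt, t0 = t0,
         f_nyquist = 1 / (2 * dt)),
    class = "pat_acquisition"
  )
}

#' @export
print.pat_acquisition <- function(x, ...) {
  cat(sprintf(
    "<pat_acquisition> c = %g m/s, %d samples @ %g ns (Nyquist %.4g MHz)\n",
    x$c, x$n_samples, x$dt * 1e9, x$f_nyquist / 1e6))
  invisible(x)
}

#' Bandlimited transducer model
#'
#' Models the detector as a zero-phase band-pass with a Gaussian amplitude
#' response whose -6 dB edges sit at `fc * (1 -/+ fractional_bandwidth / 2)`.
#' The maximum detectable frequency is the upper edge
#' `fc * (1 + fractional_bandwidth / 2)`.
#'
#' @param center_frequency Centre frequency in Hz.
#' @param fractional_bandwidth Fractional -6 dB bandwidth (e.g. 0.7 for 70%).
#' @return A `pat_transducer` with derived fields `f_min`, `f_max` (Hz).
#' @examples
#' tr <- transducer_model(2.25e6, 0.7)
#' tr$f_max / 1e6  # 3.0375 MHz
#' @export
transducer_model <- function(center_frequency = 2.25e6,
                             fractional_bandwidth = 0.7) {
  fc <- center_frequency; bw <- fractional_bandwidth
  if (!is.finite(fc) || fc <= 0) stop("center frequency must be positive", call. = FALSE)
  if (!is.finite(bw) || bw <= 0 || bw >= 2)
    stop("fractional bandwidth must lie in (0, 2)", call. = FALSE)
  f_min <- fc * (1 - bw / 2)
  f_max <- fc * (1 + bw / 2)
  stopifnot(f_min > 0, f_min < f_max)
  structure(
    list(center_frequency = fc, fractional_bandwidth = bw,
         f_min = f_min, f_max = f_max),
    class = "pat_transducer"
  )
}

#' @export
print.pat_transducer <- function(x, ...) {
  cat(sprintf("<pat_transducer> fc = %g MHz, %g%% bandwidth (band %.4g-%.4g MHz)\n",
              x$center_frequency / 1e6, 100 * x$fractional_bandwidth,
              x$f_min / 1e6, x$f_max / 1e6))
  invisible(x)
}
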