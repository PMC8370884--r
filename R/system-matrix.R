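#' Build the discretized acoustic system matrix
#'
#' Constructs the sparse linear operator `A` mapping a vectorised initial
#' pressure image (column-major, `NP = nx*ny` pixels) to a vectorised
#' sinogram (`NM = n_detectors * n_samples`, detector-major with time
#' contiguous within a detector). Row `(d, k)` holds a discretized
#' circular-mean (circular Radon) projection: each pixel contributes to the
#' two time bins bracketing its acoustic arrival time `|r_pixel - r_d| / c`,
#' with linear temporal splitting and an arc-length weight proportional to
#' `dx^2 / (2 pi r c dt)` (cylindrical spreading).
#'
#' The detected pressure is the time-derivative of the circular mean of the
#' source, so a spectral derivative along the time axis is always composed
#' with the geometric matrix; this is what gives the adjoint (backprojection)
#' its ramp-filtered character. When a transducer model is supplied its
#' flat-top band limit (-6 dB at the maximum detectable frequency, DC
#' removed) is composed as well. Forward and adjoint applications include
#' the full temporal response, so the adjoint identity holds for the
#' composed operator.
#'
#' @param grid A `pat_grid` (the image grid the operator acts on).
#' @param ring A `pat_ring`.
#' @param acquisition A `pat_acquisition`. The time window must cover the
#'   whole field of view from every detector.
#' @param transducer Optional `pat_transducer` band-pass model.
#' @return A `pat_sysmat` operator with a sparse `Matrix` core; `dim()`
#'   returns `c(NM, NP)`.
#' @examples
#' g <- make_grid(32, 32, 0.6)
#' A <- build_system_matrix(g, make_detector_ring(16, 22),
#'                          acquisition_settings())
#' dim(A)
#' @export
build_system_matrix <- function(grid, ring, acquisition, transducer = NULL) {
  stopifnot(inherits(grid, "pat_grid"), inherits(ring, "pat_ring"),
            inherits(acquisition, "pat_acquisition"))
  if (!is.null(transducer)) {
    stopifnot(inherits(transducer, "pat_transducer"))
    if (transducer$f_max > acquisition$f_nyquist)
      stop("transducer upper band edge exceeds the Nyquist frequency",
           call. = FALSE)
  }
  half_diag <- sqrt(sum((grid$extent / 2)^2))
  if (ring$radius < half_diag)
    warning("detector ring radius is smaller than the grid half-diagonal; ",
            "detectors lie inside the field of view", call. = FALSE)
  c_mm_per_s <- acquisition$c * 1e3          # mm/s
  t_max <- acquisition$t0 + (acquisition$n_samples - 1) * acquisition$dt
  reach <- c_mm_per_s * t_max
  if (reach < ring$radius + half_diag)
    stop("time window does not cover the field of view from every detector",
         call. = FALSE)

  co <- grid_coords(grid)
  px <- rep(co$x, times = grid$ny)
  py <- rep(co$y, each = grid$nx)
  np <- grid$nx * grid$ny
  ns <- acquisition$n_samples
  pos <- ring_positions(ring)

  # each pixel's footprint along the radial direction spans dx/c seconds;
  # its weight is spread over the time bins it overlaps (box kernel), which
  # suppresses the thin-ring aliasing a 2-bin split would introduce
  w_bins <- grid$dx / c_mm_per_s / acquisition$dt
  ii <- list(); jj <- list(); ww <- list()
  for (d in seq_len(ring$n_detectors)) {
    r <- sqrt((px - pos[d, 1])^2 + (py - pos[d, 2])^2)    # mm
    tc <- (r / c_mm_per_s - acquisition$t0) / acquisition$dt  # fractional bin
    amp <- grid$dx^2 /
      (2 * pi * pmax(r, grid$dx / 2) * c_mm_per_s * acquisition$dt)
    lo <- tc - w_bins / 2
    hi <- tc + w_bins / 2
    k0 <- floor(lo)
    base <- (d - 1L) * ns
    for (m in 0:(ceiling(w_bins) + 1L)) {
      k <- k0 + m
      ov <- pmin(hi, k + 1) - pmax(lo, k)
      sel <- which(ov > 0 & k + 1L >= 1L & k + 1L <= ns)
      if (!length(sel)) next
      ii[[length(ii) + 1L]] <- base + k[sel] + 1L
      jj[[length(jj) + 1L]] <- sel
      ww[[length(ww) + 1L]] <- amp[sel] * ov[sel] / w_bins
    }
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(ww),
    dims = c(ring$n_detectors * ns, np)
  )
  # temporal response: the thermoacoustic derivative always, composed with
  # the transducer's flat-top band limit when one is modelled
  H <- derivative_response(acquisition)
  if (!is.null(transducer)) H <- H * bandpass_response(transducer, acquisition)
  structure(
    list(A = A, grid = grid, ring = ring, acquisition = acquisition,
         transducer = transducer, H = H),
    class = "pat_sysmat"
  )
}

#' @export
dim.pat_sysmat <- function(x) dim(x$A)

#' @export
print.pat_sysmat <- function(x, ...) {
  cat(sprintf("<pat_sysmat> %d x %d, %d nonzeros%s\n",
              nrow(x$A), ncol(x$A), Matrix::nnzero(x$A),
              if (is.null(x$transducer)) "" else ", bandlimited"))
  invisible(x)
}

# Signed DFT frequencies (Hz) of one trace
dft_freqs <- function(acquisition) {
  n <- acquisition$n_samples
  fs <- 1 / acquisition$dt
  f <- (seq_len(n) - 1) / n * fs
  ifelse(f <= fs / 2, f, f - fs)
}

# Transducer amplitude response on the DFT grid: a zero-phase flat-top
# low-pass (10th-order Butterworth magnitude) with its -6 dB point at the
# maximum detectable frequency fc*(1 + bw/2), DC removed exactly. The
# response is essentially unity through the passband (gain at fc > 0.99)
# and rolls off steeply above f_max.
bandpass_response <- function(transducer, acquisition) {
  fa <- abs(dft_freqs(acquisition))
  ord <- 10
  f6 <- transducer$f_max / 3^(1 / (2 * ord))   # |H| = 0.5 at f_max
  H <- 1 / sqrt(1 + (fa / f6)^(2 * ord))
  H[1] <- 0                                    # kill DC exactly
  H
}

# Thermoacoustic time-derivative on the DFT grid (the detected pressure is
# the time-derivative of the circular mean of the source): i*2*pi*f,
# non-dimensionalised by dt. Complex and antisymmetric; the adjoint applies
# the conjugate response.
derivative_response <- function(acquisition) {
  1i * 2 * pi * dft_freqs(acquisition) * acquisition$dt
}

# filter an NM-length sinogram vector (detector-major) with a (possibly
# complex) DFT response H; conjugate = TRUE applies the adjoint filter
filter_traces_vec <- function(y, H, n_samples, conjugate = FALSE) {
  Y <- matrix(y, nrow = n_samples)
  Yf <- stats::mvfft(Y) * (if (conjugate) Conj(H) else H)
  as.vector(Re(stats::mvfft(Yf, inverse = TRUE)) / n_samples)
}

# internal operator interface: plain matrices and pat_sysmat both work,
# so solvers can be exercised against dense oracles
op_forward <- function(op, xvec) {
  if (inherits(op, "pat_sysmat")) {
    y <- as.vector(op$A %*% xvec)
    filter_traces_vec(y, op$H, op$acquisition$n_samples)
  } else {
    as.vector(op %*% xvec)
  }
}

op_adjoint <- function(op, yvec) {
  if (inherits(op, "pat_sysmat")) {
    yvec <- filter_traces_vec(yvec, op$H, op$acquisition$n_samples,
                              conjugate = TRUE)
    as.vector(Matrix::crossprod(op$A, yvec))
  } else {
    as.vector(crossprod(op, yvec))
  }
}

op_ncol <- function(op) if (inherits(op, "pat_sysmat")) ncol(op$A) else ncol(op)
op_nrow <- function(op) if (inherits(op, "pat_sysmat")) nrow(op$A) else nrow(op)

# deterministic power-iteration estimate of ||A||^2 = lambda_max(A'A)
operator_norm_sq <- function(op, n_iter = 20) {
  np <- op_ncol(op)
  v <- sin(seq_len(np))                     # fixed, aperiodic start
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(n_iter)) {
    w <- op_adjoint(op, op_forward(op, v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(0)
    v <- w / lam
  }
  lam
}

#' Construct a sinogram object
#'
#' @param values `n_detectors x n_samples` numeric matrix of pressure traces.
#' @param ring A `pat_ring`.
#' @param acquisition A `pat_acquisition`.
#' @param transducer Optional `pat_transducer` the data were filtered with.
#' @param noise Optional list `list(snr_db =, seed =)` recording added noise;
#'   `NULL` marks the data clean.
#' @return A `pat_sinogram`.
#' @export
sinogram <- function(values, ring, acquisition, transducer = NULL, noise = NULL) {
  values <- as.matrix(values)
  stopifnot(inherits(ring, "pat_ring"), inherits(acquisition, "pat_acquisition"),
            all(is.finite(values)),
            nrow(values) == ring$n_detectors,
            ncol(values) == acquisition$n_samples)
  structure(list(values = values, ring = ring, acquisition = acquisition,
                 transducer = transducer, noise = noise),
            class = "pat_sinogram")
}

#' @export
print.pat_sinogram <- function(x, ...) {
  cat(sprintf("<pat_sinogram> %d detectors x %d samples, %s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$noise)) "clean"
              else sprintf("AWGN %g dB (seed %s)", x$noise$snr_db,
                           x$noise$seed)))
  invisible(x)
}

# sinogram matrix <-> NM vector (detector-major, time contiguous)
sino_vec <- function(s) {
  if (inherits(s, "pat_sinogram")) as.vector(t(s$values)) else as.vector(s)
}

vec_sino <- function(v, ring, acquisition, ...) {
  sinogram(t(matrix(v, nrow = acquisition$n_samples)), ring, acquisition, ...)
}

#' Apply the forward model
#'
#' Computes `b = A x`: simulates the time traces a detector ring would record
#' from an initial pressure image.
#'
#' @param A A `pat_sysmat`.
#' @param image A `pat_pressure_image` on the operator's grid (or a plain
#'   matrix/vector of matching size).
#' @return A `pat_sinogram`.
#' @export
forward_project <- function(A, image) {
  stopifnot(inherits(A, "pat_sysmat"))
  x <- img_vec(image)
  if (length(x) != ncol(A$A))
    stop("image size does not match the system matrix", call. = FALSE)
  if (inherits(image, "pat_pressure_image") &&
      !isTRUE(all.equal(image$grid$extent, A$grid$extent)))
    stop("image grid does not match the operator's grid", call. = FALSE)
  vec_sino(op_forward(A, x), A$ring, A$acquisition, transducer = A$transducer)
}

#' Apply the adjoint operator
#'
#' Computes the backprojection image `A' b` (without any reconstruction
#' post-processing).
#'
#' @param A A `pat_sysmat`.
#' @param sino A `pat_sinogram` (or NM-length vector).
#' @return A `pat_pressure_image` on the operator's grid.
#' @export
adjoint_project <- function(A, sino) {
  stopifnot(inherits(A, "pat_sysmat"))
  y <- sino_vec(sino)
  if (length(y) != nrow(A$A))
    stop("sinogram size does not match the system matrix", call. = FALSE)
  vec_img(op_adjoint(A, y), A$grid)
}

#' Filter a sinogram with the transducer band-pass
#'
#' Applies the zero-phase band limit of a transducer model along the time
#' axis of every trace: a flat-top response (unit gain through the passband,
#' gain at `fc` above 0.99 of the passband maximum) whose -6 dB roll-off
#' sits at the maximum detectable frequency `fc * (1 + bw/2)`, with the DC
#' component removed exactly.
#'
#' @param sino A `pat_sinogram`.
#' @param transducer A `pat_transducer`.
#' @return The filtered `pat_sinogram` (transducer recorded in metadata).
#' @export
apply_transducer_response <- function(sino, transducer) {
  stopifnot(inherits(sino, "pat_sinogram"), inherits(transducer, "pat_transducer"))
  if (transducer$f_max > sino$acquisition$f_nyquist)
    stop("transducer upper band edge exceeds the Nyquist frequency: aliasing",
         call. = FALSE)
  H <- bandpass_response(transducer, sino$acquisition)
  v <- filter_traces_vec(sino_vec(sino), H, sino$acquisition$n_samples)
  vec_sino(v, sino$ring, sino$acquisition, transducer = transducer,
           noise = sino$noise)
}

#' Add calibrated white Gaussian noise
#'
#' Adds iid Gaussian noise with standard deviation
#' `rms(signal) / 10^(snr_db / 20)` (amplitude-ratio dB over the whole
#' sinogram), reproducibly for a given seed.
#'
#' @param sino A `pat_sinogram`; must not be identically zero.
#' @param snr_db Target data SNR in dB, or `Inf` for a clean pass-through.
#' @param seed Integer seed for the noise realisation.
#' @return A `pat_sinogram` with the noise record attached.
#' @export
add_awgn <- function(sino, snr_db, seed = 0L) {
  stopifnot(inherits(sino, "pat_sinogram"))
  if (is.infinite(snr_db)) return(sino)
  rms <- sqrt(mean(sino$values^2))
  if (rms == 0)
    stop("SNR is undefined for an all-zero sinogram", call. = FALSE)
  sigma <- rms / 10^(snr_db / 20)
  noise <- with_local_seed(seed,
    matrix(stats::rnorm(length(sino$values), sd = sigma),
           nrow = nrow(sino$values)))
  sinogram(sino$values + noise, sino$ring, sino$acquisition,
           transducer = sino$transducer,
           noise = list(snr_db = snr_db, seed = as.integer(seed)))
}

#' Simulate a measurement while avoiding the inverse crime
#'
#' Runs the forward model on the fine grid the phantom was rasterised on,
#' filters with the transducer, adds calibrated noise, and returns the
#' sinogram together with a *coarse-grid* system matrix for inversion. The
#' data-generating and inverting operators are deliberately different
#' discretisations so that reconstruction quality is not an artefact of
#' inverting the identical discrete model.
#'
#' @param phantom_fine A `pat_pressure_image` on the fine grid.
#' @param ring A `pat_ring`.
#' @param acquisition A `pat_acquisition`.
#' @param transducer Optional `pat_transducer`.
#' @param snr_db Data SNR in dB (`Inf` for clean data).
#' @param noise_seed Seed for the noise realisation.
#' @param recon_grid A `pat_grid` for reconstruction, usually coarser. Using
#'   the fine grid itself is allowed but flagged with a warning.
#' @return List with elements `sinogram` (a `pat_sinogram`) and `A`
#'   (the coarse-grid `pat_sysmat`).
#' @export
simulate_measurement <- function(phantom_fine, ring, acquisition,
                                 transducer = NULL, snr_db = Inf,
                                 noise_seed = 0L, recon_grid) {
  stopifnot(inherits(phantom_fine, "pat_pressure_image"),
            inherits(recon_grid, "pat_grid"))
  fine <- phantom_fine$grid
  if (fine$nx == recon_grid$nx && fine$ny == recon_grid$ny &&
      isTRUE(all.equal(fine$dx, recon_grid$dx)))
    warning("forward and reconstruction grids are identical: inverse crime",
            call. = FALSE)
  A_fine <- build_system_matrix(fine, ring, acquisition, transducer)
  b <- forward_project(A_fine, phantom_fine)
  if (is.finite(snr_db)) b <- add_awgn(b, snr_db, seed = noise_seed)
  A_coarse <- build_system_matrix(recon_grid, ring, acquisition, transducer)
  list(sinogram = b, A = A_coarse)
}
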