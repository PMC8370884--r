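# Shared fixtures: everything is generated in code at test time.

# small acquisition: full 512-sample window so geometry examples stay exact
acq512 <- function() acquisition_settings(c = 1500, n_samples = 512,
                                          dt = 50e-9, t0 = 0)

# a small PAT operator: 32 x 32 grid (19.2 mm FOV), n detectors at 22 mm
small_op <- function(n_det = 16, nx = 32, transducer = transducer_model()) {
  build_system_matrix(make_grid(nx, nx, 19.2 / nx),
                      make_detector_ring(n_det, 22),
                      acq512(), transducer)
}

# centred disk pressure image (radius mm) on a given grid
disk_image <- function(grid, radius, amplitude = 1000) {
  co <- grid_coords(grid)
  d2 <- outer(co$x^2, co$y^2, `+`)
  pressure_image(grid, (d2 <= radius^2) * amplitude, role = "ground_truth")
}

# brute-force 1-D proximal oracle: argmin_z 0.5 (z - t)^2 + tau * p(z)
# with p(z) = a * max(-z, 0) + b * max(z, 0), on a fine lattice around t
prox_oracle <- function(t, a, b, tau, n = 40001) {
  z <- seq(t - 1.5 * (abs(t) + a + b + 1), t + 1.5 * (abs(t) + a + b + 1),
           length.out = n)
  f <- 0.5 * (z - t)^2 + tau * (a * pmax(-z, 0) + b * pmax(z, 0))
  z[which.min(f)]
}

# exhaustive binary least-squares minimizer over all {0, u1}^np patterns
enumerate_binary <- function(A, b, u1 = 1) {
  np <- ncol(A)
  best <- Inf
  best_x <- NULL
  for (k in 0:(2^np - 1)) {
    x <- as.numeric(intToBits(k)[seq_len(np)]) * u1
    r <- sum((A %*% x - b)^2)
    if (r < best) { best <- r; best_x <- x }
  }
  list(x = best_x, residual = sqrt(best))
}

# random binary mask on a grid (seeded)
random_mask <- function(grid, p = 0.3, seed = 1) {
  with_seed(seed, binary_mask(grid,
    matrix(stats::runif(grid$nx * grid$ny) < p, grid$nx, grid$ny) * 1,
    provenance = "ground_truth"))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
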