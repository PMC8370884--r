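test_that("system matrix shapes follow detectors x samples by pixels", {
  A <- small_op(n_det = 16, nx = 32)
  expect_equal(dim(A), c(16 * 512, 32 * 32))
})

test_that("forward and adjoint are exact adjoints of each other", {
  A <- small_op(n_det = 8, nx = 24)
  errs <- with_seed(11, replicate(20, {
    x <- rnorm(ncol(A$A)); y <- rnorm(nrow(A$A))
    ax <- binpat:::op_forward(A, x)
    aty <- binpat:::op_adjoint(A, y)
    abs(sum(ax * y) - sum(x * aty)) /
      (sqrt(sum(ax^2)) * sqrt(sum(y^2)) + 1e-300)
  }))
  expect_lt(max(errs), 1e-10)
})

test_that("a central point source arrives at the time-of-flight sample", {
  # 22 mm / 1500 m/s / 50 ns = 293.3 samples
  g <- make_grid(21, 21, 0.1)
  A <- build_system_matrix(g, make_detector_ring(1, 22), acq512())
  x <- matrix(0, 21, 21); x[11, 11] <- 1
  b <- forward_project(A, pressure_image(g, x))
  trace <- b$values[1, ]
  # zero-phase filtering rings ahead of the arrival; almost all energy must
  # still sit at the time of flight
  expect_lt(sum(trace[seq_len(260)]^2) / sum(trace^2), 0.01)
  peak <- which.max(abs(trace))
  expect_gte(peak, 291)
  expect_lte(peak, 296)
  centroid <- sum(seq_along(trace) * trace^2) / sum(trace^2)
  expect_equal(centroid, 293.3, tolerance = 0.02)
})

test_that("the forward model is linear", {
  A <- small_op(n_det = 4, nx = 16)
  g <- A$grid
  expect_true(all(forward_project(A, pressure_image(g, matrix(0, 16, 16)))$values == 0))
  x1 <- with_seed(3, matrix(rnorm(256), 16, 16))
  b1 <- forward_project(A, pressure_image(g, x1))$values
  b2 <- forward_project(A, pressure_image(g, 2 * x1))$values
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
})

test_that("point-source traces shift with distance to the detector", {
  g <- make_grid(41, 41, 0.1)
  A <- build_system_matrix(g, make_detector_ring(1, 22), acq512())
  centroid_of <- function(i) {
    x <- matrix(0, 41, 41); x[i, 21] <- 1
    tr <- forward_project(A, pressure_image(g, x))$values[1, ]
    sum(seq_along(tr) * tr^2) / sum(tr^2)
  }
  # detector sits at +x; moving the source 1 mm toward it advances the
  # arrival by 1 mm / (c dt) = 13.3 samples
  shift <- centroid_of(21) - centroid_of(31)
  expect_equal(shift, 10 * 0.1 / (1.5 * 0.05), tolerance = 1)
})

test_that("transducer response has the stated upper band edge and kills DC", {
  tr <- transducer_model(2.25e6, 0.7)
  expect_equal(tr$f_max, 3.0375e6)
  expect_equal(tr$f_min, 1.4625e6)

  acq <- acq512()
  ring <- make_detector_ring(2, 22)
  const <- sinogram(matrix(1, 2, 512), ring, acq)
  filt <- apply_transducer_response(const, tr)
  expect_lt(max(abs(filt$values)), 1e-6)

  # response at the -6 dB point is one half of the passband maximum
  # (nearest DFT bin; the roll-off is steep, so allow the bin offset)
  H <- binpat:::bandpass_response(tr, acq)
  f <- abs(binpat:::dft_freqs(acq))
  i6 <- which.min(abs(f - tr$f_max))
  expect_equal(H[i6] / max(H), 0.5, tolerance = 0.03)

  # a tone at the centre frequency passes essentially unattenuated
  fbin <- round(2.25e6 * 512 * 50e-9) / (512 * 50e-9)   # nearest DFT bin
  tone <- sinogram(matrix(rep(sin(2 * pi * fbin * (0:511) * 50e-9), each = 2),
                          2, 512, byrow = FALSE), ring, acq)
  tonef <- apply_transducer_response(tone, tr)
  gain <- sqrt(mean(tonef$values^2)) / sqrt(mean(tone$values^2))
  expect_gte(gain / max(H), 0.99)
  expect_lte(gain / max(H), 1.0 + 1e-6)

  expect_error(
    apply_transducer_response(const, transducer_model(8e6, 0.7)),
    "Nyquist")
})

test_that("added noise realises the requested SNR reproducibly", {
  A <- small_op(n_det = 32, nx = 24)
  ph <- disk_image(A$grid, 4)
  b <- forward_project(A, ph)
  bn <- add_awgn(b, 30, seed = 7)
  realized <- 20 * log10(sqrt(mean(b$values^2)) /
                           sqrt(mean((bn$values - b$values)^2)))
  expect_gt(realized, 29.5)
  expect_lt(realized, 30.5)

  expect_identical(bn$values, add_awgn(b, 30, seed = 7)$values)
  expect_false(identical(bn$values, add_awgn(b, 30, seed = 8)$values))
  expect_identical(add_awgn(b, Inf)$values, b$values)

  zero <- sinogram(matrix(0, 32, 512), A$ring, A$acquisition)
  expect_error(add_awgn(zero, 30), "all-zero")
})

test_that("a centred disk yields identical traces under the grid symmetry", {
  # the square pixel grid is symmetric under quarter turns, so detectors
  # 90 degrees apart must record identical traces
  A <- small_op(n_det = 4, nx = 32)
  b <- forward_project(A, disk_image(A$grid, 3))
  ref <- b$values[1, ]
  for (d in 2:4)
    expect_lt(max(abs(b$values[d, ] - ref)) / max(abs(ref)), 1e-10)
})

test_that("simulate_measurement separates forward and inversion grids", {
  fine <- make_grid(64, 64, 0.3)
  coarse <- make_grid(32, 32, 0.6)
  ph <- disk_image(fine, 4)
  ring <- make_detector_ring(8, 22)
  sim <- simulate_measurement(ph, ring, acq512(), transducer_model(),
                              snr_db = 40, noise_seed = 1,
                              recon_grid = coarse)
  expect_equal(dim(sim$sinogram$values), c(8, 512))
  expect_equal(dim(sim$A), c(8 * 512, 32 * 32))
  expect_equal(sim$sinogram$noise$snr_db, 40)

  clean <- simulate_measurement(ph, ring, acq512(), NULL, snr_db = Inf,
                                recon_grid = coarse)
  expect_null(clean$sinogram$noise)

  expect_warning(
    simulate_measurement(disk_image(coarse, 4), ring, acq512(), NULL,
                         snr_db = Inf, recon_grid = coarse),
    "inverse crime")
})

test_that("system matrix rows are sparse arcs", {
  A <- small_op(n_det = 8, nx = 32)
  np <- ncol(A$A)
  row_nnz <- diff(Matrix::t(A$A)@p)  # nonzeros per row
  r_max <- 22 + sqrt(2) * 19.2 / 2
  circumference_px <- 2 * pi * r_max / A$grid$dx
  expect_lt(max(row_nnz) / np, 4 * circumference_px / np)
})
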