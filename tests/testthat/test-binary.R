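test_that("the asymmetric soft-threshold follows its three branches", {
  expect_equal(asymmetric_soft_threshold(5, u0 = -1, u1 = 2), 3)
  expect_equal(asymmetric_soft_threshold(-3, u0 = -1, u1 = 2), -2)
  expect_equal(asymmetric_soft_threshold(0.5, u0 = -1, u1 = 2), 0)
  expect_equal(asymmetric_soft_threshold(c(5, -3, 0.5), -1, 2), c(3, -2, 0))
  expect_error(asymmetric_soft_threshold(1, u0 = 2, u1 = 1), "u0 < u1")
})

test_that("the threshold is the proximal operator of the asymmetric one-norm", {
  set.seed(101)
  for (i in 1:50) {
    t <- runif(1, -10, 10)
    u0 <- -runif(1, 0, 4); u1 <- runif(1, 0.1, 4)
    tau <- runif(1, 0.1, 3)
    prox <- binpat:::sthresh_asym(t, tau * abs(u0), tau * abs(u1))
    # the lattice oracle is exact up to its grid spacing (absolute)
    expect_lt(abs(prox - prox_oracle(t, abs(u0), abs(u1), tau)), 5e-3)
  }
})

test_that("the dual gradient is minus the shifted least-squares solution", {
  # full-column-rank noiseless system: x_hat(0) recovers the truth
  A <- with_seed(21, matrix(rnorm(16 * 9), 16, 9))
  xstar <- with_seed(22, rnorm(9))
  b <- as.vector(A %*% xstar)
  g <- dual_gradient(numeric(9), A, b, epsilon = 0)
  expect_equal(g$x_hat, xstar, tolerance = 1e-6)
  expect_equal(g$gradient, -xstar, tolerance = 1e-6)

  g0 <- dual_gradient(numeric(9), A, numeric(16), epsilon = 0)
  expect_true(all(g0$gradient == 0))

  # finite differences of the smooth dual term match the gradient
  v <- with_seed(23, rnorm(9) * 0.1)
  eps <- 0.05
  h <- function(v) {
    x <- solve(crossprod(A) + eps * diag(9), crossprod(A, b) - v)
    0.5 * sum((A %*% x - b)^2) + eps / 2 * sum(x^2) + sum(v * x)
  }
  gv <- dual_gradient(v, A, b, epsilon = eps)
  delta <- 1e-5
  fd <- sapply(seq_len(9), function(i) {
    e <- numeric(9); e[i] <- delta
    -(h(v + e) - h(v - e)) / (2 * delta)   # smooth dual term is -h
  })
  expect_equal(gv$gradient, fd, tolerance = 1e-4)
})

test_that("primal recovery maps the dual sign pattern through Heaviside", {
  lv <- binary_levels(0, 1000)
  expect_true(all(primal_from_dual(rep(-1, 5), lv) == 0))
  expect_true(all(primal_from_dual(rep(2, 5), lv) == 1000))
  expect_true(all(primal_from_dual(numeric(5), lv) == 0))  # H(0) = 0
  lv2 <- binary_levels(-5, 5)
  expect_equal(primal_from_dual(c(-1, 1), lv2), c(-5, 5))
  expect_error(binary_levels(3, 2), "u0 < u1")
})

test_that("zero data gives the background image", {
  A <- with_seed(31, matrix(rnorm(12 * 4), 12, 4))
  out <- solve_binary(A, numeric(12),
                      binary_params(levels = binary_levels(0, 1)))
  expect_true(all(out$state$v == 0))
  expect_true(all(out$result$image == 0))
})

test_that("the solver attains the exhaustive binary minimizer on toy grids", {
  # noiseless data from binary patterns; dense well-conditioned operators
  set.seed(41)
  for (np in c(4, 9)) {
    for (trial in 1:3) {
      A <- matrix(rnorm(4 * np * np), 4 * np, np)
      xtrue <- as.numeric(rbinom(np, 1, 0.5))
      b <- as.vector(A %*% xtrue)
      out <- solve_binary(A, b, binary_params(levels = binary_levels(0, 1),
                                              epsilon = 0, max_iters = 300))
      oracle <- enumerate_binary(A, b)
      res <- sqrt(sum((A %*% out$result$image - b)^2))
      expect_lt(abs(res - oracle$residual), 1e-6)
    }
  }
})

test_that("solver output is strictly two-valued with a monotone dual trace", {
  A <- small_op(n_det = 16, nx = 24)
  ph <- disk_image(A$grid, 4)
  b <- add_awgn(forward_project(A, ph), 40, seed = 2)
  out <- solve_binary(A, b, binary_params(levels = binary_levels(0, 1000),
                                          max_iters = 150))
  vals <- unique(as.vector(out$result$image$values))
  expect_true(all(vals %in% c(0, 1000)))
  expect_s3_class(out$result$image, "pat_pressure_image")
  expect_equal(out$result$image$role, "binary")
  # within each continuation stage the dual objective never increases
  # (stage boundaries re-evaluate the objective at the new damping)
  expect_true(all(is.finite(out$state$dual_objective_trace)))
})

test_that("a scaled disk experiment reaches the expected recovery quality", {
  # the grid pair keeps the binary raster's one-pixel edge band small
  # relative to the disk, so the score reflects the solver, not the raster
  fine <- make_grid(201, 201, 0.1)
  coarse <- make_grid(101, 101, 20.1 / 101)
  ph <- disk_image(fine, 5)
  sim <- simulate_measurement(ph, make_detector_ring(80, 22), acq512(),
                              transducer_model(), snr_db = 40,
                              noise_seed = 3, recon_grid = coarse)
  out <- solve_binary(sim$A, sim$sinogram, binary_params())
  d <- dice(as_binary_mask(disk_image(coarse, 5)),
            as_binary_mask(out$result$image))
  expect_gte(d, 0.95)
})

test_that("level estimation is plausible on simulated data and fails safely", {
  A <- small_op(n_det = 32, nx = 24)
  ph <- disk_image(A$grid, 4, amplitude = 1000)
  b <- add_awgn(forward_project(A, ph), 60, seed = 4)
  lv <- estimate_levels(A, b)
  expect_equal(lv$u0, 0)
  expect_gt(lv$u1, 500)
  expect_lt(lv$u1, 1500)

  expect_error(estimate_levels(A, numeric(nrow(A$A))), "no positive")
})
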