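test_that("Dice coefficient counts overlap correctly", {
  g <- make_grid(10, 10, 1)
  m <- function(idx) {
    v <- matrix(0, 10, 10); v[idx] <- 1
    binary_mask(g, v, provenance = "ground_truth")
  }
  a <- m(1:10)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(m(1:10), m(11:20)), 0)
  expect_equal(dice(m(1:4), m(3:6)), 0.5)  # 2*2 / (4+4)
  expect_error(dice(m(integer(0)), m(integer(0))), "undefined")

  # symmetry and range on random pairs
  for (s in 1:5) {
    x <- random_mask(g, 0.4, seed = s)
    y <- random_mask(g, 0.4, seed = s + 100)
    expect_equal(dice(x, y), dice(y, x))
    expect_gte(dice(x, y), 0)
    expect_lte(dice(x, y), 1)
    expect_equal(dice(x, x), 1)
  }
})

test_that("clip-and-mean segmentation follows the stated protocol", {
  g <- make_grid(10, 10, 1)
  v <- matrix(0, 10, 10); v[1:4] <- 1      # mean of clipped image = 0.04
  img <- pressure_image(g, v)
  mask <- segment_threshold_mean(img)
  expect_equal(sum(mask$values), 4)
  expect_true(all(mask$values[1:4] == 1))

  neg <- pressure_image(g, matrix(-1, 10, 10))
  expect_warning(mneg <- segment_threshold_mean(neg), "empty")
  expect_equal(sum(mneg$values), 0)

  # binary-solver output: the mask is exactly the upper level set
  bin <- pressure_image(g, v * 1000, role = "binary")
  expect_equal(segment_threshold_mean(bin)$values, v)
})

test_that("two-class k-means segmentation is exact and deterministic", {
  g <- make_grid(10, 10, 1)
  v <- matrix(0, 10, 10); v[1:30] <- 1
  img <- pressure_image(g, v)
  km <- segment_kmeans2(img)
  expect_equal(km$values, v)
  expect_identical(segment_kmeans2(img)$values, segment_kmeans2(img)$values)

  # well-separated Gaussian mixture: assignments match generating labels
  labels <- with_seed(50, matrix(rbinom(400, 1, 0.3), 20, 20))
  noise <- with_seed(51, matrix(rnorm(400, sd = 0.1), 20, 20))
  gm <- pressure_image(make_grid(20, 20, 1), labels + noise)
  seg <- segment_kmeans2(gm)
  expect_gte(mean(seg$values == labels), 0.99)

  expect_error(segment_kmeans2(pressure_image(g, matrix(1, 10, 10))),
               "two distinct")
})

test_that("error overlays partition disagreement into FP and FN", {
  g <- make_grid(10, 10, 1)
  t_ <- random_mask(g, 0.3, seed = 9)
  r_ <- random_mask(g, 0.3, seed = 10)

  same <- error_overlay(t_, t_)
  expect_equal(sum(same$fp_map), 0)
  expect_equal(sum(same$fn_map), 0)

  comp <- binary_mask(g, 1 - t_$values, provenance = "ground_truth")
  oc <- error_overlay(t_, comp)
  expect_equal(oc$fp_map, 1 - t_$values)
  expect_equal(oc$fn_map, t_$values)

  o <- error_overlay(t_, r_)
  expect_true(all(o$fp_map * o$fn_map == 0))        # disjoint
  expect_equal(sum(o$fp_map) + sum(o$fn_map),
               o$n_true + o$n_recon - 2 * o$n_intersect)
  expect_equal(o$dice, 2 * o$n_intersect / (o$n_true + o$n_recon))

  png_path <- tempfile(fileext = ".png")
  error_overlay(t_, r_, path = png_path)
  expect_true(file.exists(png_path))
  expect_equal(dim(png::readPNG(png_path))[1:2], c(10, 10))
})

test_that("line profiles sample the image bilinearly in physical units", {
  g <- make_grid(64, 64, 0.25)
  const <- pressure_image(g, matrix(7, 64, 64))
  pr <- line_profile(const, c(-5, 0), c(5, 0), n_points = 50)
  expect_true(all(abs(pr$value - 7) < 1e-12))
  expect_equal(nrow(pr), 50)
  expect_equal(max(pr$distance_mm), 10)

  disk <- disk_image(g, 3, amplitude = 1000)
  pr2 <- line_profile(disk, c(-6, 0), c(6, 0), n_points = 241)
  plateau <- sum(pr2$value > 500) * (12 / 240)
  expect_lt(abs(plateau - 6), 2 * g$dx + 0.1)

  rev <- line_profile(disk, c(6, 0), c(-6, 0), n_points = 241)
  expect_equal(rev$value, rev(pr2$value), tolerance = 1e-12)

  expect_error(line_profile(disk, c(-50, 0), c(0, 0)), "outside")
})

test_that("benchmark tables cover the factorial design deterministically", {
  spec <- disks_spec(n_disks = 2, radius_range = c(2, 3), rng_seed = 1)
  fine <- make_grid(64, 64, 0.3)
  coarse <- make_grid(32, 32, 0.6)
  tab <- benchmark_table(list(disks = spec), detector_counts = 16,
                         snr_list = 40, methods = c("bp", "tikhonov"),
                         seeds = 1, fine_grid = fine, recon_grid = coarse,
                         lambda_grids = list(tikhonov = c(0.01, 0.03)))
  expect_equal(nrow(tab), 1L)
  expect_named(tab, c("phantom", "n_detectors", "snr_db", "bp", "tikhonov"))
  expect_true(all(is.finite(c(tab$bp, tab$tikhonov))))

  tab2 <- benchmark_table(list(disks = spec), detector_counts = 16,
                          snr_list = 40, methods = c("bp", "tikhonov"),
                          seeds = 1, fine_grid = fine, recon_grid = coarse,
                          lambda_grids = list(tikhonov = c(0.01, 0.03)))
  expect_identical(tab, tab2)
})

test_that("tidiers return well-formed tibbles", {
  A <- with_seed(61, matrix(rnorm(30 * 9), 30, 9))
  b <- with_seed(62, rnorm(30))
  rec <- tikhonov_solve(A, b, recon_params("tikhonov", lambda = 0.1))
  td <- generics::tidy(rec)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "objective"))
  gl <- generics::glance(rec)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$method, "tikhonov")

  out <- solve_binary(A, b, binary_params(levels = binary_levels(0, 1),
                                          max_iters = 50))
  expect_named(generics::tidy(out$state), c("iteration", "dual_objective"))
  expect_equal(generics::glance(out$state)$u1, 1)
})
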