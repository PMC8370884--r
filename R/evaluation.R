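#' Binary segmentation mask
#'
#' @param grid A `pat_grid`.
#' @param values Logical or `{0,1}` numeric `nx x ny` matrix.
#' @param provenance How the mask arose: `"ground_truth"`,
#'   `"threshold_mean"`, `"kmeans2"` or `"binary_solver"`.
#' @return A `pat_binary_mask` with strictly `{0,1}` values.
#' @export
binary_mask <- function(grid, values,
                        provenance = c("ground_truth", "threshold_mean",
                                       "kmeans2", "binary_solver")) {
  stopifnot(inherits(grid, "pat_grid"))
  provenance <- match.arg(provenance)
  values <- as.matrix(values) * 1
  if (!all(dim(values) == c(grid$nx, grid$ny)))
    stop("mask dimensions must match the grid", call. = FALSE)
  if (!all(values %in% c(0, 1)))
    stop("mask values must be exactly {0, 1}", call. = FALSE)
  structure(list(grid = grid, values = values, provenance = provenance),
            class = "pat_binary_mask")
}

#' @export
print.pat_binary_mask <- function(x, ...) {
  cat(sprintf("<pat_binary_mask> [%s] %d x %d, %d foreground pixels\n",
              x$provenance, x$grid$nx, x$grid$ny, sum(x$values)))
  invisible(x)
}

#' Coerce to a binary mask
#'
#' A two-valued `pat_pressure_image` maps its upper level to foreground; a
#' `pat_binary_mask` passes through.
#'
#' @param x Object to coerce.
#' @return A `pat_binary_mask`.
#' @export
as_binary_mask <- function(x) {
  if (inherits(x, "pat_binary_mask")) return(x)
  if (inherits(x, "pat_pressure_image")) {
    lv <- sort(unique(as.vector(x$values)))
    if (length(lv) > 2L)
      stop("image is not two-valued; segment it first", call. = FALSE)
    prov <- if (x$role == "binary") "binary_solver" else "ground_truth"
    return(binary_mask(x$grid, x$values == max(lv) & x$values > min(lv),
                       provenance = prov))
  }
  stop("cannot coerce to a binary mask", call. = FALSE)
}

#' Dice similarity coefficient
#'
#' `DC = 2 |true & recon| / (|true| + |recon|)`: the overlap between two
#' segmentations, symmetric in its arguments and in `[0, 1]`.
#'
#' @param mask_true,mask_recon `pat_binary_mask`s (or coercible objects) on
#'   the same grid.
#' @return The Dice coefficient. Two empty masks raise an error (0/0 is
#'   undefined), rather than silently scoring 0.
#' @export
dice <- function(mask_true, mask_recon) {
  mt <- as_binary_mask(mask_true); mr <- as_binary_mask(mask_recon)
  if (!all(dim(mt$values) == dim(mr$values)))
    stop("masks are on different grids", call. = FALSE)
  nt <- sum(mt$values); nr <- sum(mr$values)
  if (nt + nr == 0)
    stop("Dice is undefined for two empty masks", call. = FALSE)
  2 * sum(mt$values * mr$values) / (nt + nr)
}

#' Segment by clipping and mean thresholding
#'
#' The comparator-segmentation protocol for grey-valued reconstructions:
#' negative values are clipped to zero, and pixels strictly greater than the
#' mean of the clipped image become foreground.
#'
#' @param image A `pat_pressure_image` (or `pat_recon`).
#' @return A `pat_binary_mask` with provenance `"threshold_mean"`. A
#'   constant image yields an empty foreground with a warning.
#' @export
segment_threshold_mean <- function(image) {
  if (inherits(image, "pat_recon")) image <- image$image
  stopifnot(inherits(image, "pat_pressure_image"))
  v <- pmax(image$values, 0)
  thr <- mean(v)
  fg <- v > thr
  if (!any(fg))
    warning("constant (or all-negative) image: empty foreground", call. = FALSE)
  binary_mask(image$grid, fg, provenance = "threshold_mean")
}

#' Segment by two-class k-means on intensities
#'
#' One-dimensional k-means with two classes on the pixel intensities;
#' foreground is the higher-centroid class. Initial centroids are the
#' minimum and maximum intensity, which makes the clustering deterministic
#' (the seed argument is accepted for interface stability but does not
#' influence the result).
#'
#' @param image A `pat_pressure_image` (or `pat_recon`).
#' @param seed Unused; retained for call-site compatibility.
#' @return A `pat_binary_mask` with provenance `"kmeans2"`.
#' @export
segment_kmeans2 <- function(image, seed = 0L) {
  if (inherits(image, "pat_recon")) image <- image$image
  stopifnot(inherits(image, "pat_pressure_image"))
  v <- as.vector(image$values)
  if (length(unique(v)) < 2L)
    stop("k-means segmentation needs at least two distinct values",
         call. = FALSE)
  km <- stats::kmeans(v, centers = matrix(c(min(v), max(v))), iter.max = 100)
  fg <- km$cluster == which.max(km$centers)
  binary_mask(image$grid, matrix(fg, image$grid$nx, image$grid$ny),
              provenance = "kmeans2")
}

#' False-positive / false-negative overlay
#'
#' Compares a reconstructed mask to the truth: `fp = recon \ true`,
#' `fn = true \ recon`. Optionally renders an RGB overlay (green = false
#' positive, pink = false negative, white = true positive) to a PNG file.
#'
#' @param mask_true,mask_recon `pat_binary_mask`s on the same grid.
#' @param path Optional PNG output path.
#' @return A `pat_metrics` report: `dice`, pixel counts, and `fp_map` /
#'   `fn_map` matrices (disjoint by construction).
#' @export
error_overlay <- function(mask_true, mask_recon, path = NULL) {
  mt <- as_binary_mask(mask_true); mr <- as_binary_mask(mask_recon)
  if (!all(dim(mt$values) == dim(mr$values)))
    stop("masks are on different grids", call. = FALSE)
  fp <- (mr$values == 1) & (mt$values == 0)
  fn <- (mt$values == 1) & (mr$values == 0)
  tp <- (mt$values == 1) & (mr$values == 1)
  rep <- structure(
    list(dice = if (sum(mt$values) + sum(mr$values) > 0) dice(mt, mr) else NA_real_,
         n_true = sum(mt$values), n_recon = sum(mr$values),
         n_intersect = sum(tp),
         fp_map = fp * 1, fn_map = fn * 1, tp_map = tp * 1, grid = mt$grid,
         method = mr$provenance),
    class = "pat_metrics")
  if (!is.null(path)) write_overlay_png(rep, path)
  rep
}

#' @export
print.pat_metrics <- function(x, ...) {
  cat(sprintf(
    "<pat_metrics> dice = %.4f  (|true| = %d, |recon| = %d, FP = %d, FN = %d)\n",
    x$dice, x$n_true, x$n_recon, sum(x$fp_map), sum(x$fn_map)))
  invisible(x)
}

# RGB overlay: white TP, green FP, pink FN, black background. PNG rows run
# top-to-bottom, so the y axis is flipped for display.
write_overlay_png <- function(rep, path) {
  flip <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  fpm <- flip(rep$fp_map); fnm <- flip(rep$fn_map); tpm <- flip(rep$tp_map)
  img <- array(0, dim = c(nrow(fpm), ncol(fpm), 3))
  img[, , 1] <- fnm + tpm            # red: FN (pink) + TP (white)
  img[, , 2] <- fpm + tpm            # green: FP + TP
  img[, , 3] <- 0.7 * fnm + tpm      # blue channel makes FN pink, TP white
  png::writePNG(pmin(img, 1), path)
  invisible(path)
}

#' Sample an image along a line segment
#'
#' Bilinearly interpolates the image at `n_points` equally spaced positions
#' between two physical endpoints (mm), attaching physical coordinates.
#'
#' @param image A `pat_pressure_image`.
#' @param p_start,p_end Numeric `(x, y)` endpoints in mm, inside the FOV.
#' @param n_points Number of samples along the segment.
#' @return A tibble with columns `distance_mm`, `x_mm`, `y_mm`, `value`.
#' @export
line_profile <- function(image, p_start, p_end, n_points = 200) {
  stopifnot(inherits(image, "pat_pressure_image"),
            length(p_start) == 2L, length(p_end) == 2L, n_points >= 2)
  co <- grid_coords(image$grid)
  rng_x <- range(co$x); rng_y <- range(co$y)
  for (p in list(p_start, p_end)) {
    if (p[1] < rng_x[1] || p[1] > rng_x[2] || p[2] < rng_y[1] || p[2] > rng_y[2])
      stop("profile endpoint lies outside the field of view", call. = FALSE)
  }
  t <- seq(0, 1, length.out = n_points)
  xs <- p_start[1] + t * (p_end[1] - p_start[1])
  ys <- p_start[2] + t * (p_end[2] - p_start[2])
  # bilinear interpolation on the pixel-centre lattice
  fi <- (xs - co$x[1]) / image$grid$dx
  fj <- (ys - co$y[1]) / image$grid$dx
  i0 <- pmin(pmax(floor(fi), 0), image$grid$nx - 2)
  j0 <- pmin(pmax(floor(fj), 0), image$grid$ny - 2)
  wi <- fi - i0; wj <- fj - j0
  v <- image$values
  idx <- function(i, j) v[cbind(i + 1, j + 1)]
  val <- (1 - wi) * (1 - wj) * idx(i0, j0) +
    wi * (1 - wj) * idx(i0 + 1, j0) +
    (1 - wi) * wj * idx(i0, j0 + 1) +
    wi * wj * idx(i0 + 1, j0 + 1)
  tibble::tibble(
    distance_mm = t * sqrt(sum((p_end - p_start)^2)),
    x_mm = xs, y_mm = ys, value = val
  )
}

#' Factorial benchmark of reconstruction methods
#'
#' Runs the full simulate / reconstruct / segment / score pipeline over the
#' cross product of phantoms, detector counts, noise levels, methods and
#' seeds, and reports mean Dice per cell in a wide table (one row per
#' phantom x detector count x SNR, one column per method). Comparator
#' methods are segmented by clipping at zero and thresholding at the mean;
#' the binary solver's output is scored directly on its upper level set.
#' `lambda` for the regularized comparators is chosen per cell by a Dice
#' sweep, mirroring heuristic selection against the figure of merit.
#'
#' @param phantom_specs Named list of `pat_phantom_spec`s.
#' @param detector_counts Integer vector of ring sizes.
#' @param snr_list Data SNRs in dB.
#' @param methods Subset of `c("bp", "tikhonov", "l1", "binary")`.
#' @param seeds Noise seeds; Dice is averaged over them.
#' @param fine_grid,recon_grid Forward and inversion grids.
#' @param ring_radius Ring radius in mm.
#' @param acquisition A `pat_acquisition`.
#' @param transducer A `pat_transducer` (or `NULL`).
#' @param lambda_grids Named list of relative lambda grids per regularized
#'   method; absolute values are `grid * ||A||^2`.
#' @param binary_max_iters Outer iteration budget for the binary solver.
#' @return A tibble; reconstruction failures leave `NA` in their cell and
#'   the run continues.
#' @export
benchmark_table <- function(phantom_specs, detector_counts = 80,
                            snr_list = c(30, 40, 60),
                            methods = c("bp", "tikhonov", "l1", "binary"),
                            seeds = 1L,
                            fine_grid = make_grid(402, 402, 0.05),
                            recon_grid = make_grid(201, 201, 0.1),
                            ring_radius = 22,
                            acquisition = acquisition_settings(),
                            transducer = transducer_model(),
                            lambda_grids = list(
                              tikhonov = c(0.002, 0.005, 0.01, 0.02, 0.05),
                              l1 = c(1, 3, 10, 30, 100)),
                            binary_max_iters = 250) {
  stopifnot(is.list(phantom_specs), length(phantom_specs) > 0)
  if (is.null(names(phantom_specs)))
    names(phantom_specs) <- paste0("phantom", seq_along(phantom_specs))
  methods <- match.arg(methods, c("bp", "tikhonov", "l1", "binary"),
                       several.ok = TRUE)
  rows <- list()
  for (pname in names(phantom_specs)) {
    spec <- phantom_specs[[pname]]
    phantom <- generate_phantom(fine_grid, spec)
    truth <- as_binary_mask(
      generate_phantom(recon_grid, spec))  # truth on the recon grid
    for (nd in detector_counts) {
      ring <- make_detector_ring(nd, ring_radius)
      for (snr in snr_list) {
        per_seed <- matrix(NA_real_, nrow = length(seeds),
                           ncol = length(methods),
                           dimnames = list(NULL, methods))
        for (s in seq_along(seeds)) {
          sim <- simulate_measurement(phantom, ring, acquisition, transducer,
                                      snr_db = snr, noise_seed = seeds[s],
                                      recon_grid = recon_grid)
          nsq <- operator_norm_sq(sim$A)
          for (m in methods) {
            per_seed[s, m] <- tryCatch({
              if (m == "bp") {
                dice(truth, segment_threshold_mean(backproject(sim$A, sim$sinogram)))
              } else if (m == "binary") {
                sol <- solve_binary(sim$A, sim$sinogram,
                                    binary_params(max_iters = binary_max_iters))
                dice(truth, as_binary_mask(sol$result$image))
              } else {
                sw <- sweep_lambda(sim$A, sim$sinogram, method = m,
                                   lambda_grid = lambda_grids[[m]] * nsq,
                                   truth = truth)
                sw$best_dice
              }
            }, error = function(e) NA_real_)
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phantom = pname, n_detectors = nd, snr_db = snr,
          !!!as.list(colMeans(per_seed)))
      }
    }
  }
  do.call(rbind, rows)
}
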