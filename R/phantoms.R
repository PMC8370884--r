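#' Phantom specifications
#'
#' A phantom spec fully determines a rasterisation: the same spec on the same
#' grid is bit-identical on repeated calls. Three families are provided:
#'
#' * `derenzo_spec()` - a Derenzo-style resolution phantom: six angular
#'   sectors of disks with per-sector radii, arranged on triangular lattices
#'   with centre-to-centre spacing twice the disk diameter.
#' * `vessel_spec()` - a procedural branching vessel tree drawn as thick
#'   polylines, vessel width decaying with branch depth.
#' * `disks_spec()` - a seeded set of random non-overlapping disks (useful
#'   for parameter-recovery studies).
#'
#' @param amplitude Absorber level in Pa (background is 0). The default
#'   1000 Pa (1 kPa) is the initial pressure rise used throughout the
#'   in-silico study design.
#' @param sector_radii Disk radii per angular sector, mm, largest first.
#' @param r_inner Radial distance of the innermost disk row from the grid
#'   centre, mm.
#' @param r_outer All disks must lie within this radius, mm.
#' @param rng_seed Integer seed (vessel and disks families).
#' @return A `pat_phantom_spec`.
#' @name phantom_specs
NULL

#' @rdname phantom_specs
#' @export
derenzo_spec <- function(amplitude = 1000,
                         sector_radii = c(1.2, 1.0, 0.8, 0.6, 0.45, 0.3),
                         r_inner = 3, r_outer = 9) {
  stopifnot(is.finite(amplitude), amplitude >= 0,
            length(sector_radii) == 6L, all(sector_radii > 0),
            r_inner > 0, r_outer > r_inner)
  structure(list(family = "derenzo", amplitude = amplitude,
                 sector_radii = sector_radii, r_inner = r_inner,
                 r_outer = r_outer),
            class = "pat_phantom_spec")
}

#' @rdname phantom_specs
#' @param root_width Trunk vessel width (diameter), mm.
#' @param depth Number of branching generations (0 gives a single segment).
#' @param decay Multiplicative width decay per generation.
#' @param segment_length Mean branch segment length, mm.
#' @export
vessel_spec <- function(amplitude = 1000, root_width = 0.9, depth = 4,
                        decay = 0.75, segment_length = 4.5, rng_seed = 1) {
  stopifnot(is.finite(amplitude), amplitude >= 0, root_width > 0,
            depth >= 0, decay > 0, decay < 1, segment_length > 0)
  structure(list(family = "vessel", amplitude = amplitude,
                 root_width = root_width, depth = as.integer(depth),
                 decay = decay, segment_length = segment_length,
                 rng_seed = as.integer(rng_seed)),
            class = "pat_phantom_spec")
}

#' @rdname phantom_specs
#' @param n_disks Number of disks.
#' @param radius_range Min and max disk radius, mm.
#' @param placement_radius Disk centres drawn uniformly within this radius, mm.
#' @export
disks_spec <- function(amplitude = 1000, n_disks = 6,
                       radius_range = c(0.8, 2.0), placement_radius = 7,
                       rng_seed = 1) {
  stopifnot(is.finite(amplitude), amplitude >= 0, n_disks >= 1,
            length(radius_range) == 2L, all(radius_range > 0),
            radius_range[1] <= radius_range[2], placement_radius > 0)
  structure(list(family = "disks", amplitude = amplitude,
                 n_disks = as.integer(n_disks), radius_range = radius_range,
                 placement_radius = placement_radius,
                 rng_seed = as.integer(rng_seed)),
            class = "pat_phantom_spec")
}

#' @export
print.pat_phantom_spec <- function(x, ...) {
  cat(sprintf("<pat_phantom_spec> family = %s, amplitude = %g Pa\n",
              x$family, x$amplitude))
  invisible(x)
}

# run expr with a private, restored RNG stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# disk centres (x, y, r) of the Derenzo layout; deterministic
derenzo_disks <- function(spec) {
  out <- list()
  for (s in seq_len(6L)) {
    rd <- spec$sector_radii[s]
    theta <- (s - 1) * pi / 3 + pi / 6        # sector axis
    sp <- 4 * rd                               # centre spacing = 2 * diameter
    k <- 1L
    repeat {
      rho <- spec$r_inner + (k - 1) * sp * cos(pi / 6)
      if (rho + rd > spec$r_outer) break
      toff <- (seq_len(k) - (k + 1) / 2) * sp
      # keep disks inside the 60-degree wedge with a half-spacing margin
      keep <- abs(toff) + rd <= rho * tan(pi / 6) - rd
      if (k == 1L) keep <- TRUE
      ax <- c(cos(theta), sin(theta)); tx <- c(-sin(theta), cos(theta))
      for (t in toff[keep]) {
        out[[length(out) + 1L]] <- c(rho * ax + t * tx, rd)
      }
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}

rasterize_disks <- function(grid, disks, amplitude) {
  co <- grid_coords(grid)
  vals <- matrix(0, grid$nx, grid$ny)
  for (i in seq_len(nrow(disks))) {
    cx <- disks[i, 1]; cy <- disks[i, 2]; r <- disks[i, 3]
    ix <- which(abs(co$x - cx) <= r)
    iy <- which(abs(co$y - cy) <= r)
    if (!length(ix) || !length(iy)) next
    dx2 <- outer((co$x[ix] - cx)^2, (co$y[iy] - cy)^2, `+`)
    vals[ix, iy][dx2 <= r^2] <- amplitude
  }
  vals
}

#' Generate a Derenzo-style resolution phantom
#'
#' Rasterises six angular sectors of disks of decreasing radius on a
#' triangular lattice (pixel-centre-inside test, no anti-aliasing), giving a
#' strictly two-level image with background 0 and disks at the spec
#' amplitude.
#'
#' @param grid A `pat_grid`.
#' @param spec A `derenzo_spec()`.
#' @return A `pat_pressure_image` with role `"ground_truth"`.
#' @export
generate_derenzo <- function(grid, spec = derenzo_spec()) {
  stopifnot(inherits(grid, "pat_grid"), inherits(spec, "pat_phantom_spec"))
  if (spec$family != "derenzo") stop("spec family must be 'derenzo'", call. = FALSE)
  disks <- derenzo_disks(spec)
  # disks must fit the field of view and not overlap
  half_fov <- min(grid$extent) / 2
  if (any(sqrt(disks[, 1]^2 + disks[, 2]^2) + disks[, 3] > half_fov))
    stop("Derenzo disks exceed the field of view", call. = FALSE)
  if (nrow(disks) > 1L) {
    dmat <- as.matrix(stats::dist(disks[, 1:2]))
    rsum <- outer(disks[, 3], disks[, 3], `+`)
    diag(dmat) <- Inf
    if (any(dmat < rsum)) stop("Derenzo disks overlap", call. = FALSE)
  }
  vals <- rasterize_disks(grid, disks, spec$amplitude)
  pressure_image(grid, vals, role = "ground_truth")
}

#' Generate a branching vessel-tree phantom
#'
#' Draws a seeded recursive binary tree of vessel segments (two children per
#' branch, width multiplied by `decay` each generation, random turn angles
#' between 15 and 40 degrees) rasterised as thick polylines. The result is a
#' connected, strictly two-level curvilinear structure emulating sparse
#' vasculature.
#'
#' @param grid A `pat_grid`.
#' @param spec A `vessel_spec()`; the seed fully determines the tree.
#' @return A `pat_pressure_image` with role `"ground_truth"`.
#' @export
generate_vessel_tree <- function(grid, spec = vessel_spec()) {
  stopifnot(inherits(grid, "pat_grid"), inherits(spec, "pat_phantom_spec"))
  if (spec$family != "vessel") stop("spec family must be 'vessel'", call. = FALSE)
  half_fov <- min(grid$extent) / 2 * 0.92
  segs <- with_local_seed(spec$rng_seed, {
    acc <- list()
    grow <- function(p, heading, width, len, depth_left) {
      q <- p + len * c(cos(heading), sin(heading))
      # clip growth at the field-of-view boundary
      q <- pmin(pmax(q, -half_fov), half_fov)
      acc[[length(acc) + 1L]] <<- c(p, q, width)
      if (depth_left == 0L) return(invisible())
      for (sgn in c(-1, 1)) {
        turn <- sgn * stats::runif(1, 15, 40) * pi / 180
        grow(q, heading + turn, width * spec$decay,
             len * stats::runif(1, 0.75, 0.95), depth_left - 1L)
      }
    }
    root <- c(-0.75 * half_fov, 0)
    grow(root, stats::runif(1, -0.3, 0.3), spec$root_width,
         spec$segment_length, spec$depth)
    acc
  })
  co <- grid_coords(grid)
  vals <- matrix(0, grid$nx, grid$ny)
  for (sg in segs) {
    p <- sg[1:2]; q <- sg[3:4]; hw <- sg[5] / 2
    lo <- pmin(p, q) - hw; hi <- pmax(p, q) + hw
    ix <- which(co$x >= lo[1] & co$x <= hi[1])
    iy <- which(co$y >= lo[2] & co$y <= hi[2])
    if (!length(ix) || !length(iy)) next
    d <- q - p; L2 <- sum(d^2)
    X <- outer(co$x[ix] - p[1], rep(1, length(iy)))
    Y <- outer(rep(1, length(ix)), co$y[iy] - p[2])
    t <- if (L2 > 0) pmin(pmax((X * d[1] + Y * d[2]) / L2, 0), 1) else 0
    dist2 <- (X - t * d[1])^2 + (Y - t * d[2])^2
    vals[ix, iy][dist2 <= hw^2] <- spec$amplitude
  }
  if (spec$amplitude > 0 && !any(vals > 0))
    stop("vessel spec produced an empty phantom", call. = FALSE)
  pressure_image(grid, vals, role = "ground_truth")
}

#' Generate a random-disks phantom
#'
#' Seeded union of non-overlapping disks with uniformly drawn centres and
#' radii; used for randomized parameter-recovery studies.
#'
#' @param grid A `pat_grid`.
#' @param spec A `disks_spec()`.
#' @return A `pat_pressure_image` with role `"ground_truth"`.
#' @export
generate_disks <- function(grid, spec = disks_spec()) {
  stopifnot(inherits(grid, "pat_grid"), inherits(spec, "pat_phantom_spec"))
  if (spec$family != "disks") stop("spec family must be 'disks'", call. = FALSE)
  disks <- with_local_seed(spec$rng_seed, {
    acc <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(acc) < spec$n_disks && tries < 1000L) {
      tries <- tries + 1L
      r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * spec$placement_radius
      cand <- c(rad * cos(ang), rad * sin(ang), r)
      ok <- !nrow(acc) ||
        all(sqrt((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2) >
              acc[, 3] + cand[3] + 0.2)
      if (ok) acc <- rbind(acc, cand)
    }
    acc
  })
  if (!nrow(disks)) stop("could not place any disks", call. = FALSE)
  vals <- rasterize_disks(grid, disks, spec$amplitude)
  pressure_image(grid, vals, role = "ground_truth")
}

#' Generate a phantom from any spec
#'
#' Dispatches on the spec family.
#' @param grid A `pat_grid`.
#' @param spec A `pat_phantom_spec`.
#' @return A `pat_pressure_image`.
#' @export
generate_phantom <- function(grid, spec) {
  switch(spec$family,
         derenzo = generate_derenzo(grid, spec),
         vessel = generate_vessel_tree(grid, spec),
         disks = generate_disks(grid, spec),
         stop("unknown phantom family: ", spec$family, call. = FALSE))
}
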