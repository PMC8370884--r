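#' Create an imaging grid
#'
#' Defines a regular Cartesian pixel grid with a centred physical coordinate
#' system. Pixel `(i, j)` has its centre at `origin + ((i-1)*dx, (j-1)*dx)`;
#' the origin is chosen so that the field of view is symmetric about (0, 0).
#' All physical lengths are in millimetres.
#'
#' @param nx,ny Number of pixels along x and y (each at least 2).
#' @param dx Pixel pitch in mm (isotropic).
#' @return A `pat_grid` object with fields `nx`, `ny`, `dx`, `origin`
#'   (physical coordinate of the centre of pixel (1, 1), mm) and `extent`
#'   (physical size `c(nx*dx, ny*dx)` in mm).
#' @examples
#' g <- make_grid(402, 402, 0.05)
#' g$extent  # 20.1 x 20.1 mm
#' @export
make_grid <- function(nx, ny, dx) {
  if (length(nx) != 1L || length(ny) != 1L || length(dx) != 1L)
    stop("nx, ny and dx must be scalars", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L)
    stop("grid dimensions must be integers >= 2", call. = FALSE)
  if (!is.finite(dx) || dx <= 0)
    stop("pixel pitch dx must be positive", call. = FALSE)
  structure(
    list(
      nx = nx, ny = ny, dx = dx,
      origin = c(-(nx - 1) / 2 * dx, -(ny - 1) / 2 * dx),
      extent = c(nx * dx, ny * dx)
    ),
    class = "pat_grid"
  )
}

#' Physical pixel-centre coordinates of a grid
#'
#' @param grid A `pat_grid`.
#' @return List with numeric vectors `x` (length `nx`) and `y` (length `ny`)
#'   of pixel-centre coordinates in mm.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "pat_grid"))
  list(
    x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx,
    y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dx
  )
}

#' @export
print.pat_grid <- function(x, ...) {
  cat(sprintf("<pat_grid> %d x %d pixels, dx = %g mm, extent %g x %g mm\n",
              x$nx, x$ny, x$dx, x$extent[1], x$extent[2]))
  invisible(x)
}

#' Construct a pressure image
#'
#' Wraps a 2-D field of initial pressure values on an imaging grid. Element
#' `values[i, j]` corresponds to pixel-centre `(x[i], y[j])` of the grid.
#' Images are vectorised column-major (pixel `p = i + (j-1)*nx`) wherever a
#' flat vector is exchanged with a system matrix.
#'
#' @param grid A `pat_grid`.
#' @param values Numeric `nx x ny` matrix, finite everywhere. Units Pa
#'   (or normalised a.u.).
#' @param role One of `"ground_truth"`, `"reconstruction"`, `"binary"`.
#'   A `"binary"` image must take at most two distinct values.
#' @return A `pat_pressure_image`.
#' @export
pressure_image <- function(grid, values,
                           role = c("reconstruction", "ground_truth", "binary")) {
  stopifnot(inherits(grid, "pat_grid"))
  role <- match.arg(role)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nx, grid$ny)))
    stop(sprintf("values must be %d x %d to match the grid", grid$nx, grid$ny),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("pressure values must be finite everywhere", call. = FALSE)
  if (role == "binary" && length(unique(as.vector(values))) > 2L)
    stop("a binary image may take at most two distinct values", call. = FALSE)
  structure(list(grid = grid, values = values, role = role),
            class = "pat_pressure_image")
}

#' @export
print.pat_pressure_image <- function(x, ...) {
  v <- range(x$values)
  cat(sprintf("<pat_pressure_image> [%s] %d x %d, values in [%g, %g]\n",
              x$role, x$grid$nx, x$grid$ny, v[1], v[2]))
  invisible(x)
}

# flatten / unflatten between image matrices and system-matrix pixel order
img_vec <- function(image) {
  if (inherits(image, "pat_pressure_image")) as.vector(image$values)
  else as.vector(image)
}

vec_img <- function(v, grid, role = "reconstruction") {
  pressure_image(grid, matrix(v, nrow = grid$nx, ncol = grid$ny), role = role)
}
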