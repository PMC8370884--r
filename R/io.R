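#' Write / read a pressure image as float TIFF with a YAML sidecar
#'
#' Images are stored as single-channel 32-bit float TIFF. TIFF payloads are
#' normalised to `[0, 1]`; the affine scale back to physical units, the grid
#' geometry and provenance metadata live in a `<path>.yaml` sidecar, so a
#' read round-trip restores physical values to float32 precision.
#'
#' @param image A `pat_pressure_image`.
#' @param path Output `.tif` path; the sidecar is written next to it.
#' @param metadata Optional named list merged into the sidecar (e.g. method,
#'   lambda, iterations, residual).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, metadata = list()) {
  stopifnot(inherits(image, "pat_pressure_image"))
  v <- image$values
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(t((v - lo) / scale), path, bits.per.sample = 32L)
  meta <- c(list(nx = image$grid$nx, ny = image$grid$ny, dx_mm = image$grid$dx,
                 role = image$role, value_offset = lo, value_scale = scale),
            metadata)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  raw <- t(tiff::readTIFF(path))
  grid <- make_grid(meta$nx, meta$ny, meta$dx_mm)
  pressure_image(grid, raw * meta$value_scale + meta$value_offset,
                 role = meta$role)
}

#' Write / read a binary mask as 8-bit PNG
#'
#' @param mask A `pat_binary_mask`.
#' @param path Output `.png` path; grid geometry goes to a YAML sidecar.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pat_binary_mask"))
  png::writePNG(t(mask$values), path)
  yaml::write_yaml(list(nx = mask$grid$nx, ny = mask$grid$ny,
                        dx_mm = mask$grid$dx, provenance = mask$provenance),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  v <- t(png::readPNG(path))
  binary_mask(make_grid(meta$nx, meta$ny, meta$dx_mm), v > 0.5,
              provenance = meta$provenance)
}

#' Sinogram container
#'
#' Sinograms are stored as a portable two-file container: a tab-separated
#' value matrix (`n_detectors` rows x `n_samples` columns, full `%.17g`
#' precision so values round-trip bit-exactly) and a `<path>.yaml` sidecar
#' carrying the acquisition metadata (`c_mps`, `dt_s`, `t0_s`, `radius_mm`,
#' `angles_rad`, transducer `fc_hz` / `fbw`, and the noise record
#' `snr_db` / `seed` when present). Externally acquired data can be imported
#' by writing the same pair of files.
#'
#' @param sino A `pat_sinogram`.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "pat_sinogram"))
  txt <- apply(sino$values, 1, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(txt, path)
  meta <- list(
    n_detectors = sino$ring$n_detectors,
    n_samples = sino$acquisition$n_samples,
    c_mps = sino$acquisition$c,
    dt_s = sino$acquisition$dt,
    t0_s = sino$acquisition$t0,
    radius_mm = sino$ring$radius,
    angles_rad = as.numeric(sino$ring$angles)
  )
  if (!is.null(sino$transducer)) {
    meta$fc_hz <- sino$transducer$center_frequency
    meta$fbw <- sino$transducer$fractional_bandwidth
  }
  if (!is.null(sino$noise)) {
    meta$snr_db <- sino$noise$snr_db
    meta$seed <- sino$noise$seed
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(path)) stop("no such sinogram file: ", path, call. = FALSE)
  if (!file.exists(meta_path))
    stop("sinogram metadata sidecar missing: ", meta_path, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  required <- c("n_detectors", "n_samples", "c_mps", "dt_s", "t0_s",
                "radius_mm", "angles_rad")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("sinogram metadata incomplete; missing attributes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vals <- do.call(rbind, lapply(readLines(path), function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  ring <- make_detector_ring(meta$n_detectors, meta$radius_mm,
                             start_angle = meta$angles_rad[1])
  acq <- acquisition_settings(c = meta$c_mps, n_samples = meta$n_samples,
                              dt = meta$dt_s, t0 = meta$t0_s)
  tr <- if (!is.null(meta$fc_hz)) transducer_model(meta$fc_hz, meta$fbw) else NULL
  noise <- if (!is.null(meta$snr_db))
    list(snr_db = meta$snr_db, seed = meta$seed) else NULL
  sinogram(vals, ring, acq, transducer = tr, noise = noise)
}

#' Write a reconstruction with its sidecar diagnostics
#'
#' Image as float TIFF (+ YAML sidecar recording method, lambda, iterations
#' and residual), objective trace as CSV.
#'
#' @param recon A `pat_recon`.
#' @param stem Output path stem; writes `<stem>.tif`, `<stem>.tif.yaml`,
#'   `<stem>_trace.csv`.
#' @return Character vector of the files written, invisibly.
#' @export
write_recon <- function(recon, stem) {
  stopifnot(inherits(recon, "pat_recon"))
  tif <- paste0(stem, ".tif")
  write_image(recon$image, tif,
              metadata = list(method = recon$params$method,
                              lambda = recon$params$lambda,
                              iterations = recon$iterations,
                              residual_norm = recon$residual_norm,
                              converged = recon$converged))
  trace_csv <- paste0(stem, "_trace.csv")
  utils::write.csv(
    data.frame(iteration = seq_along(recon$objective_trace) - 1L,
               objective = recon$objective_trace),
    trace_csv, row.names = FALSE)
  invisible(c(tif, paste0(tif, ".yaml"), trace_csv))
}
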