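SINOGRAM_SCHEMA_VERSION <- "1.0"

#' Read and write sinogram containers
#'
#' Sinograms and sinogram series are stored in a versioned single-file
#' container (R serialization) holding the value array plus every projection
#' geometry field as named attributes. Files written by a newer schema
#' version are refused with an explicit error.
#'
#' @param x a [sinogram()] or [sinogram_series()].
#' @param path file path (conventionally `.sino.rds`).
#' @return `read_sinogram()` returns the stored object; `write_sinogram()`
#'   returns `path` invisibly.
#' @export
write_sinogram <- function(x, path) {
  stopifnot(inherits(x, "sinogram") || inherits(x, "sinogram_series"))
  payload <- list(
    schema = "kwia-sinogram",
    schema_version = SINOGRAM_SCHEMA_VERSION,
    kind = class(x)[1],
    values = x$values,
    view_angles = x$view_angles,
    frame_interval = x$frame_interval,
    geometry = unclass(x$geometry)
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema, "kwia-sinogram"))
    stop("not a kwia sinogram container: ", path)
  if (is.null(payload$schema_version) ||
      payload$schema_version > SINOGRAM_SCHEMA_VERSION)
    stop("sinogram container schema version ",
         payload$schema_version %||% "<missing>",
         " is not supported (expected <= ", SINOGRAM_SCHEMA_VERSION, ")")
  gl <- payload$geometry
  if (is.null(gl$n_detectors) || is.null(gl$beam_type))
    stop("malformed sinogram container: missing geometry attributes")
  g <- projection_geometry(gl$beam_type, gl$n_detectors, gl$detector_spacing,
                           gl$n_views_per_rotation, gl$start_angle,
                           gl$source_to_detector, gl$source_to_isocenter)
  if (identical(payload$kind, "sinogram_series")) {
    sinogram_series(payload$values, g, payload$frame_interval,
                    payload$view_angles)
  } else {
    sinogram(payload$values, g, payload$view_angles)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dynamic series as 4D NIfTI
#'
#' Pixel spacing (mm) and frame interval (s) are carried in the NIfTI pixdim.
#'
#' @param series a [dynamic_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series_nifti <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$data)
  arr <- array(series$data, c(d[1], d[2], 1, d[3]))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$pixel_spacing, series$pixel_spacing, 1,
                           series$frame_interval)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_series_nifti
#' @export
read_series_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  nt <- if (length(d) >= 4) d[4] else 1
  dynamic_series(array(as.numeric(img), c(d[1], d[2], nt)),
                 pixel_spacing = pd[1],
                 frame_interval = if (length(pd) >= 4) pd[4] else 1)
}

#' Write time density curves as CSV
#'
#' Long format: `frame, time_s, <one column per curve>`.
#'
#' @param curves a named list of [time_density_curve()] objects sharing a
#'   frame grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tdc_csv <- function(curves, path) {
  stopifnot(length(curves) >= 1)
  n <- length(curves[[1]]$values)
  dt <- curves[[1]]$frame_interval
  df <- data.frame(frame = seq_len(n), time_s = seq_len(n) * dt)
  for (nm in names(curves)) df[[nm]] <- curves[[nm]]$values
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a study configuration from YAML
#'
#' Validates the file fully before any compute: phantom preset, dose levels,
#' ring presets per dose, kernel parameters, seed and ROI definitions. See
#' `system.file("extdata", "digital_phantom.yaml", package = "kwia")` for the
#' documented schema.
#'
#' @param path YAML file path.
#' @return A validated `study_config` list for [run_study()].
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("phantom", "doses", "seed")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("study config missing fields: ", paste(miss, collapse = ", "))
  if (!identical(cfg$phantom, "forbild-head"))
    stop("unknown phantom preset '", cfg$phantom, "'")
  for (d in cfg$doses) {
    if (is.null(d$fraction) || d$fraction <= 0 || d$fraction > 1)
      stop("each dose entry needs a fraction in (0, 1]")
    for (rp in d$ring_presets %||% list()) ring_preset(rp)  # must exist
  }
  kern <- cfg$kernel %||% list()
  cfg$kernel <- kernel_spec(kern$kb_beta %||% 16.25, kern$width %||% 7,
                            kern$oversampling %||% 2)
  cfg$n_emitted <- as.numeric(cfg$n_emitted %||% 4.8e6)  # yaml reads 4.8e6 as text
  structure(cfg, class = "study_config")
}
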