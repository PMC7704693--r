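#' Projection geometry description
#'
#' Bookkeeping for a 2D CT acquisition geometry. For parallel beams,
#' `n_views_per_rotation` counts projections over a full rotation exactly as a
#' scanner would report them; the number of *distinct* parallel angles over a
#' half rotation is `n_views_per_rotation / 2` (opposing views are redundant).
#' For fan beams, views cover the full rotation and the source distances are
#' required for rebinning.
#'
#' @param beam_type `"parallel"` or `"fan"`.
#' @param n_detectors number of detector channels.
#' @param detector_spacing detector pitch in mm (arc length at the detector for
#'   fan beams).
#' @param n_views_per_rotation projections acquired per rotation.
#' @param start_angle first view angle in radians, counter-clockwise from +x.
#' @param source_to_detector,source_to_isocenter source distances in mm
#'   (fan beam only).
#' @return An object of class `projection_geometry`.
#' @examples
#' g <- projection_geometry("parallel", n_detectors = 728,
#'                          detector_spacing = 0.75,
#'                          n_views_per_rotation = 1152)
#' g$nyquist_complete
#' @export
projection_geometry <- function(beam_type = c("parallel", "fan"),
                                n_detectors, detector_spacing,
                                n_views_per_rotation, start_angle = 0,
                                source_to_detector = NA_real_,
                                source_to_isocenter = NA_real_) {
  beam_type <- match.arg(beam_type)
  if (n_detectors <= 0 || n_views_per_rotation <= 0)
    stop("n_detectors and n_views_per_rotation must be positive")
  if (detector_spacing <= 0) stop("detector_spacing must be positive")
  if (beam_type == "fan" &&
      (!is.finite(source_to_detector) || !is.finite(source_to_isocenter)))
    stop("fan-beam geometry requires source_to_detector and source_to_isocenter")
  g <- structure(list(
    beam_type = beam_type,
    n_detectors = as.integer(n_detectors),
    detector_spacing = detector_spacing,
    n_views_per_rotation = as.integer(n_views_per_rotation),
    start_angle = start_angle,
    source_to_detector = source_to_detector,
    source_to_isocenter = source_to_isocenter
  ), class = "projection_geometry")
  # Nyquist criterion for radial sampling: N_proj >= (pi/2) N_detector,
  # counted per rotation.
  g$nyquist_complete <- g$n_views_per_rotation >= (pi / 2) * g$n_detectors
  g
}

#' Number of distinct parallel view angles over a half rotation
#' @param geometry a [projection_geometry()].
#' @return Integer view count over 180 degrees.
#' @export
n_parallel_views <- function(geometry) {
  stopifnot(inherits(geometry, "projection_geometry"))
  geometry$n_views_per_rotation %/% 2L
}

#' View angles for a parallel-beam acquisition
#'
#' Evenly spaced over `[start, start + pi)`; a half rotation samples every
#' distinct parallel projection exactly once.
#' @param geometry a parallel-beam [projection_geometry()].
#' @return Numeric vector of angles in radians.
#' @export
parallel_view_angles <- function(geometry) {
  nv <- n_parallel_views(geometry)
  geometry$start_angle + (seq_len(nv) - 1) * pi / nv
}

#' Sinogram container
#'
#' A stack of attenuation line integrals (dimensionless) indexed
#' `[view, detector]` together with its acquisition geometry.
#'
#' @param values numeric matrix `[view, detector]`.
#' @param geometry a [projection_geometry()].
#' @param view_angles per-view angles in radians; defaults to
#'   [parallel_view_angles()] for parallel beams.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, view_angles = NULL) {
  stopifnot(is.matrix(values), inherits(geometry, "projection_geometry"))
  if (!all(is.finite(values))) stop("sinogram values must all be finite")
  if (ncol(values) != geometry$n_detectors)
    stop("sinogram has ", ncol(values), " detector columns; geometry expects ",
         geometry$n_detectors)
  if (is.null(view_angles)) {
    if (geometry$beam_type == "parallel") {
      view_angles <- parallel_view_angles(geometry)
    } else {
      nv <- geometry$n_views_per_rotation
      view_angles <- geometry$start_angle + (seq_len(nv) - 1) * 2 * pi / nv
    }
  }
  if (nrow(values) != length(view_angles))
    stop("number of views does not match view_angles")
  if (geometry$beam_type == "parallel") {
    rel <- (view_angles - view_angles[1]) %% (2 * pi)
    if (any(rel > pi + 1e-9))
      stop("parallel-beam view angles must span a half rotation without duplication")
  }
  structure(list(values = values, geometry = geometry,
                 view_angles = view_angles), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %s beam, %d views x %d detectors (pitch %.3g mm)\n",
              x$geometry$beam_type, nrow(x$values), ncol(x$values),
              x$geometry$detector_spacing))
  invisible(x)
}

#' Time-ordered series of parallel-beam sinograms
#'
#' @param values 3D array `[view, detector, frame]`.
#' @param geometry a [projection_geometry()].
#' @param frame_interval time between frames in seconds.
#' @param view_angles optional per-view angles.
#' @return Object of class `sinogram_series`.
#' @export
sinogram_series <- function(values, geometry, frame_interval,
                            view_angles = NULL) {
  stopifnot(length(dim(values)) == 3, frame_interval > 0)
  first <- sinogram(values[, , 1], geometry, view_angles)
  structure(list(values = values, geometry = geometry,
                 view_angles = first$view_angles,
                 frame_interval = frame_interval),
            class = "sinogram_series")
}

n_frames <- function(x) dim(x$values)[3]

#' Extract one frame of a sinogram series
#' @param series a [sinogram_series()].
#' @param frame frame index.
#' @return A [sinogram()].
#' @export
sinogram_frame <- function(series, frame) {
  sinogram(series$values[, , frame], series$geometry, series$view_angles)
}

#' Reconstructed dynamic image series
#'
#' @param data 3D array `[x, y, frame]` of attenuation maps (mm^-1).
#' @param pixel_spacing pixel size in mm.
#' @param frame_interval frame interval in seconds.
#' @return Object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, pixel_spacing, frame_interval) {
  stopifnot(length(dim(data)) == 3, pixel_spacing > 0, frame_interval > 0)
  structure(list(data = data, pixel_spacing = pixel_spacing,
                 frame_interval = frame_interval), class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %d x %d x %d frames, %.3g mm pixels, %.3g s interval\n",
              d[1], d[2], d[3], x$pixel_spacing, x$frame_interval))
  invisible(x)
}
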