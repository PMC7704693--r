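#' Forward project an attenuation map to a parallel-beam sinogram
#'
#' Computes line integrals of a square attenuation image along every ray of a
#' parallel-beam geometry, using Joseph-style interpolating integration (one
#' step per pixel along the dominant ray axis, linear interpolation along the
#' other). The projection operator is linear in the image.
#'
#' @param image square numeric matrix of attenuation coefficients (mm^-1);
#'   `image[ix, iy]` sits at `x = (ix-1-N/2) * pixel_spacing` and likewise in
#'   `y`, so the isocenter is at 1-based index `N/2 + 1`.
#' @param pixel_spacing pixel size in mm.
#' @param geometry a parallel-beam [projection_geometry()].
#' @return A [sinogram()] of dimensionless line integrals.
#' @examples
#' g <- projection_geometry("parallel", 96, 1, 180)
#' img <- matrix(0, 64, 64)
#' img[33, 33] <- 0.02
#' s <- forward_project_parallel(img, 1, g)
#' @export
forward_project_parallel <- function(image, pixel_spacing, geometry) {
  stopifnot(inherits(geometry, "projection_geometry"))
  if (geometry$beam_type != "parallel")
    stop("forward_project_parallel requires a parallel-beam geometry")
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  if (any(image < 0))
    warning("attenuation map contains negative values")
  angles <- parallel_view_angles(geometry)
  vals <- cpp_project_parallel(image, pixel_spacing, angles,
                               geometry$n_detectors,
                               geometry$detector_spacing)
  sinogram(vals, geometry, angles)
}

#' Forward project every frame of a dynamic series
#'
#' @param series a [dynamic_series()].
#' @param geometry a parallel-beam [projection_geometry()].
#' @return A [sinogram_series()].
#' @export
forward_project_series <- function(series, geometry) {
  stopifnot(inherits(series, "dynamic_series"))
  nt <- dim(series$data)[3]
  angles <- parallel_view_angles(geometry)
  out <- array(0, c(length(angles), geometry$n_detectors, nt))
  for (f in seq_len(nt)) {
    out[, , f] <- cpp_project_parallel(series$data[, , f],
                                       series$pixel_spacing, angles,
                                       geometry$n_detectors,
                                       geometry$detector_spacing)
  }
  sinogram_series(out, geometry, series$frame_interval, angles)
}

#' Rebin full-rotation fan-beam data to parallel-beam projections
#'
#' A fan ray at tube angle `theta` and fan angle `gamma` coincides with the
#' parallel ray at angle `theta + gamma` and offset
#' `t = source_to_isocenter * sin(gamma)` (equiangular detector arc; the tube
#' angle is identified by its central ray, so the `gamma = 0` ray at tube angle
#' `theta` maps to the parallel ray at angle `theta`, offset 0). A full
#' rotation of fan views provides every parallel ray twice; the rebinned
#' sinogram keeps `n_views_in / 2` distinct parallel angles over 180 degrees.
#' Interpolation is bilinear in (tube angle, fan angle).
#'
#' @param fan_sino fan-beam [sinogram()] covering a full rotation.
#' @param target_geometry parallel-beam [projection_geometry()] of the output;
#'   if `NULL`, a geometry with the same detector count, spacing
#'   `source_to_isocenter * detector_spacing / source_to_detector` and half the
#'   fan view count is derived.
#' @return A parallel-beam [sinogram()].
#' @export
rebin_fan_to_parallel <- function(fan_sino, target_geometry = NULL) {
  stopifnot(inherits(fan_sino, "sinogram"))
  g <- fan_sino$geometry
  if (g$beam_type != "fan") stop("input sinogram is not fan-beam")
  th <- fan_sino$view_angles
  span <- max(th) - min(th)
  if (span < 2 * pi - 2.5 * pi / length(th))
    stop("fan data must cover a full rotation (angular redundancy is needed)")
  dgam <- g$detector_spacing / g$source_to_detector
  if (is.null(target_geometry)) {
    target_geometry <- projection_geometry(
      "parallel", n_detectors = g$n_detectors,
      detector_spacing = g$source_to_isocenter * dgam,
      n_views_per_rotation = g$n_views_per_rotation,
      start_angle = g$start_angle)
  }
  if (target_geometry$beam_type != "parallel")
    stop("target_geometry must be parallel-beam")

  nv_f <- nrow(fan_sino$values)
  nd_f <- ncol(fan_sino$values)
  th0 <- th[1]
  dth <- 2 * pi / nv_f
  angles_out <- parallel_view_angles(target_geometry)
  nd_p <- target_geometry$n_detectors
  t_out <- (seq_len(nd_p) - 1 - nd_p %/% 2) * target_geometry$detector_spacing

  out <- matrix(0, length(angles_out), nd_p)
  sin_arg <- t_out / g$source_to_isocenter
  ok <- abs(sin_arg) < 1
  gam <- rep(NA_real_, nd_p)
  gam[ok] <- asin(sin_arg[ok])
  # fan-angle grid index (1-based, gamma_d = (d - 1 - nd_f/2) * dgam)
  fd <- gam / dgam + nd_f %/% 2 + 1
  for (i in seq_along(angles_out)) {
    theta_t <- (angles_out[i] - gam - th0) %% (2 * pi)
    fv <- theta_t / dth + 1    # 1-based fractional fan view index, wraps
    v0 <- floor(fv); wv <- fv - v0
    v0 <- ((v0 - 1) %% nv_f) + 1
    v1 <- (v0 %% nv_f) + 1
    d0 <- floor(fd); wd <- fd - d0
    valid <- ok & d0 >= 1 & d0 + 1 <= nd_f
    row <- numeric(nd_p)
    idx <- which(valid)
    if (length(idx)) {
      a00 <- fan_sino$values[cbind(v0[idx], d0[idx])]
      a01 <- fan_sino$values[cbind(v0[idx], d0[idx] + 1)]
      a10 <- fan_sino$values[cbind(v1[idx], d0[idx])]
      a11 <- fan_sino$values[cbind(v1[idx], d0[idx] + 1)]
      row[idx] <- (1 - wv[idx]) * ((1 - wd[idx]) * a00 + wd[idx] * a01) +
        wv[idx] * ((1 - wd[idx]) * a10 + wd[idx] * a11)
    }
    out[i, ] <- row
  }
  sinogram(out, target_geometry, angles_out)
}
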