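#' Circular or mask region of interest
#'
#' Circle ROIs include a pixel iff its center lies inside the radius.
#'
#' @param center (x, y) center in pixel indices (1-based).
#' @param radius radius in pixels.
#' @return Object of class `roi`.
#' @export
roi_circle <- function(center, radius) {
  stopifnot(radius > 0)
  structure(list(shape = "circle", center = center, radius = radius),
            class = "roi")
}

#' @rdname roi_circle
#' @param mask logical matrix marking member pixels.
#' @export
roi_mask <- function(mask) {
  stopifnot(is.matrix(mask), any(mask))
  structure(list(shape = "mask", mask = mask), class = "roi")
}

roi_indices <- function(roi, dims) {
  if (roi$shape == "mask") {
    if (!all(dim(roi$mask) == dims)) stop("mask does not match image size")
    return(which(roi$mask))
  }
  cx <- roi$center[1]; cy <- roi$center[2]
  ix <- pmax(1, ceiling(cx - roi$radius)):pmin(dims[1], floor(cx + roi$radius))
  iy <- pmax(1, ceiling(cy - roi$radius)):pmin(dims[2], floor(cy + roi$radius))
  sub <- as.matrix(expand.grid(ix = ix, iy = iy))
  keep <- (sub[, 1] - cx)^2 + (sub[, 2] - cy)^2 < roi$radius^2
  sub <- sub[keep, , drop = FALSE]
  if (!nrow(sub)) stop("ROI is empty")
  (sub[, 2] - 1) * dims[1] + sub[, 1]
}

#' Convert a position in mm (isocenter origin) to pixel indices
#' @param xy_mm (x, y) in mm.
#' @param image_size image side in pixels.
#' @param pixel_spacing mm per pixel.
#' @return (x, y) in 1-based pixel indices.
#' @export
mm_to_pixel <- function(xy_mm, image_size, pixel_spacing) {
  xy_mm / pixel_spacing + image_size %/% 2 + 1
}

#' Time density curve container
#' @param values signal per frame.
#' @param frame_interval seconds between frames.
#' @param baseline_frames frames used for the subtracted baseline.
#' @return Object of class `tdc`.
#' @export
time_density_curve <- function(values, frame_interval, baseline_frames = 0) {
  stopifnot(frame_interval > 0, length(values) >= 1)
  structure(list(values = as.numeric(values), frame_interval = frame_interval,
                 baseline_frames = as.integer(baseline_frames)),
            class = "tdc")
}

#' Extract a time density curve from a dynamic series
#'
#' Per-frame ROI mean, minus the mean over the first `baseline_frames` frames
#' (pre-contrast baseline).
#'
#' @param series a [dynamic_series()].
#' @param roi an `roi` from [roi_circle()] / [roi_mask()].
#' @param baseline_frames number of leading frames averaged for the baseline
#'   (0 disables subtraction).
#' @return A [time_density_curve()].
#' @export
extract_tdc <- function(series, roi, baseline_frames = 2) {
  stopifnot(inherits(series, "dynamic_series"))
  dims <- dim(series$data)[1:2]
  idx <- roi_indices(roi, dims)
  nt <- dim(series$data)[3]
  vals <- vapply(seq_len(nt),
                 function(f) mean(series$data[, , f][idx]), numeric(1))
  if (baseline_frames > 0)
    vals <- vals - mean(vals[seq_len(baseline_frames)])
  time_density_curve(vals, series$frame_interval, baseline_frames)
}

#' Perfusion quantification settings
#'
#' @param svd_truncation_fraction singular values below this fraction of the
#'   largest are zeroed when inverting the AIF convolution matrix (0.2 is a
#'   standard choice for noisy CTP data).
#' @param cbf_scale conversion from deconvolved peak (1/s) to ml/100g/min;
#'   the default `6000 / 1.04` assumes tissue density 1.04 g/ml and unit
#'   hematocrit correction.
#' @param baseline_frames leading frames used for TDC baselines.
#' @return Object of class `perfusion_config`.
#' @export
perfusion_config <- function(svd_truncation_fraction = 0.2,
                             cbf_scale = 6000 / 1.04,
                             baseline_frames = 2) {
  if (svd_truncation_fraction <= 0 || svd_truncation_fraction >= 1)
    stop("svd_truncation_fraction must be in (0, 1)")
  structure(list(svd_truncation_fraction = svd_truncation_fraction,
                 cbf_scale = cbf_scale,
                 baseline_frames = as.integer(baseline_frames)),
            class = "perfusion_config")
}

#' CBF by truncated-SVD deconvolution
#'
#' Solves the indicator-dilution system `tissue = dt * A %*% k` where `A` is
#' the lower-triangular convolution matrix of the arterial input function and
#' `k(t) = CBF * R(t)` is the flow-scaled residue function. The inverse is
#' stabilized by zeroing singular values below
#' `svd_truncation_fraction * sigma_max`; CBF is `cbf_scale * max(k)`.
#' The standard delay-sensitive formulation is used. Negative CBF estimates
#' are clipped to zero (a warning count is attached).
#'
#' @param tissue a [time_density_curve()] or list of them.
#' @param aif the arterial input [time_density_curve()].
#' @param config a [perfusion_config()].
#' @return For a single tissue curve, a list with `cbf` (ml/100g/min) and
#'   `residue` (the deconvolved flow-scaled residue, 1/s); for a list input, a
#'   list of such results.
#' @export
svd_deconvolve <- function(tissue, aif, config = perfusion_config()) {
  stopifnot(inherits(aif, "tdc"))
  if (all(aif$values == 0)) stop("AIF is identically zero")
  single <- inherits(tissue, "tdc")
  curves <- if (single) list(tissue) else tissue
  nt <- length(aif$values)
  dt <- aif$frame_interval
  A <- matrix(0, nt, nt)
  for (i in seq_len(nt)) A[i, seq_len(i)] <- aif$values[i:1]
  A <- A * dt
  sv <- svd(A)
  dinv <- ifelse(sv$d >= config$svd_truncation_fraction * max(sv$d),
                 1 / sv$d, 0)
  Ainv <- sv$v %*% (dinv * t(sv$u))
  out <- lapply(curves, function(cv) {
    stopifnot(length(cv$values) == nt)
    if (abs(cv$frame_interval - dt) > 1e-9)
      stop("tissue and AIF frame intervals differ")
    k <- drop(Ainv %*% cv$values)
    cbf <- config$cbf_scale * max(k)
    clipped <- FALSE
    if (cbf < 0) { cbf <- 0; clipped <- TRUE }
    list(cbf = cbf, residue = k, clipped = clipped)
  })
  if (single) out[[1]] else out
}

#' Area under a time density curve
#'
#' Trapezoid rule times the frame interval.
#' @param curve a [time_density_curve()].
#' @return Area in signal units times seconds.
#' @export
curve_auc <- function(curve) {
  v <- curve$values
  n <- length(v)
  sum((v[-1] + v[-n]) / 2) * curve$frame_interval
}

#' Full width at half maximum of a curve's main peak
#'
#' Linear interpolation of the two half-maximum crossings around the global
#' peak. If the curve never drops below half maximum on one side, the FWHM is
#' undefined and an error of class `kwia_fwhm_undefined` is signalled.
#'
#' @param curve a [time_density_curve()].
#' @return Width in seconds.
#' @export
curve_fwhm <- function(curve) {
  v <- curve$values
  n <- length(v)
  pk <- which.max(v)
  half <- v[pk] / 2
  cross <- function(i0, i1) {
    # linear interpolation between samples i0 and i1 (v[i0] and v[i1] straddle half)
    i0 + (half - v[i0]) / (v[i1] - v[i0])
  }
  left <- NA_real_
  for (i in rev(seq_len(pk - 1))) {
    if (v[i] <= half) { left <- cross(i, i + 1); break }
  }
  right <- NA_real_
  if (pk < n) for (i in (pk + 1):n) {
    if (v[i] <= half) { right <- cross(i - 1, i) - 0; break }
  }
  if (is.na(left) || is.na(right))
    stop(structure(class = c("kwia_fwhm_undefined", "error", "condition"),
                   list(message = "FWHM undefined: no half-maximum crossing on one side",
                        call = sys.call())))
  (right - left) * curve$frame_interval
}

#' Root mean squared difference between two curves
#' @param curve,reference [time_density_curve()] objects of equal length.
#' @return RMSE in signal units.
#' @export
curve_rmse <- function(curve, reference) {
  a <- curve$values; b <- reference$values
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}
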