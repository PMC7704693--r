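#' Gamma-variate contrast enhancement
#'
#' Bolus-passage enhancement `C(t) = c0 * tau^alpha * exp(alpha * (1 - tau))`
#' with `tau = t / peak_time`, so the curve is 0 at `t = 0`, rises to its
#' maximum `c0` exactly at `t = peak_time`, and decays thereafter. `alpha`
#' controls how fast the signal changes (larger = narrower bolus).
#'
#' @param t_frames frame times in seconds (may be a vector).
#' @param peak_time time of peak enhancement in seconds.
#' @param alpha_gamma positive shape parameter.
#' @param c0 peak amplitude.
#' @return Enhancement values, one per element of `t_frames`.
#' @examples
#' gamma_variate(seq(0, 54, by = 2), peak_time = 20, alpha_gamma = 11, c0 = 1)
#' @export
gamma_variate <- function(t_frames, peak_time, alpha_gamma = 11, c0 = 1) {
  if (alpha_gamma <= 0) stop("alpha_gamma must be positive")
  if (peak_time <= 0) stop("peak_time must be positive")
  tau <- t_frames / peak_time
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- c0 * tau[pos]^alpha_gamma * exp(alpha_gamma * (1 - tau[pos]))
  out
}

#' Time-varying vessel description
#'
#' @param center vessel center (x, y) in mm.
#' @param diameter vessel diameter in mm.
#' @param baseline_attenuation attenuation before contrast arrival (mm^-1).
#' @param c0 peak contrast enhancement added on top of the baseline (mm^-1).
#' @param peak_frame frame index (1-based) at which enhancement peaks.
#' @param alpha_gamma gamma-variate shape parameter.
#' @return Object of class `vessel_dynamics`.
#' @export
vessel_dynamics <- function(center, diameter, baseline_attenuation,
                            c0, peak_frame = 10, alpha_gamma = 11) {
  if (diameter <= 0) stop("diameter must be positive")
  if (alpha_gamma <= 0) stop("alpha_gamma must be positive")
  structure(list(center = center, diameter = diameter,
                 baseline_attenuation = baseline_attenuation,
                 c0 = c0, peak_frame = as.integer(peak_frame),
                 alpha_gamma = alpha_gamma),
            class = "vessel_dynamics")
}

#' Dynamic phantom specification
#'
#' Static primitives are painted in order (later primitives overwrite earlier
#' ones where they overlap, with area-weighted anti-aliased edges); vessels are
#' painted on top with attenuation `baseline + C(t)`.
#'
#' @param primitives list of primitives; each is a list with `shape`
#'   (`"disk"` or `"ellipse"`), `center` (mm), `axes` (half-axes in mm; a
#'   single radius for disks) and `value` (attenuation, mm^-1).
#' @param vessels list of [vessel_dynamics()] objects.
#' @param image_size image dimension in pixels.
#' @param pixel_spacing pixel size in mm.
#' @param n_frames number of time frames.
#' @param frame_interval seconds between frames; frame `f` is at
#'   `t = f * frame_interval` so enhancement is ~0 on the first frames.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(primitives, vessels = list(), image_size = 512,
                         pixel_spacing = 0.75, n_frames = 27,
                         frame_interval = 2) {
  fov <- image_size * pixel_spacing / 2
  for (v in vessels) {
    if (any(abs(v$center) + v$diameter / 2 > fov))
      stop("vessel outside the field of view")
    if (v$peak_frame < 1 || v$peak_frame > n_frames)
      stop("vessel peak_frame outside the series")
  }
  structure(list(primitives = primitives, vessels = vessels,
                 image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval),
            class = "phantom_spec")
}

# Anti-aliased coverage (0..1 per pixel) of a disk or axis-aligned ellipse.
# Edge coverage is a linear ramp over one pixel of the signed edge distance,
# which keeps rasterized areas within a fraction of a percent of analytic.
primitive_coverage <- function(shape, center, axes, image_size, pixel_spacing) {
  n <- image_size
  xs <- ((0:(n - 1)) - n %/% 2) * pixel_spacing
  if (identical(shape, "disk")) axes <- rep(axes[1], 2)
  dx <- outer(xs - center[1], rep(1, n))
  dy <- outer(rep(1, n), xs - center[2])
  f <- sqrt((dx / axes[1])^2 + (dy / axes[2])^2)
  gradf <- sqrt((dx / axes[1]^2)^2 + (dy / axes[2]^2)^2) / pmax(f, 1e-9)
  dist <- (f - 1) / pmax(gradf, 1e-12)      # approximate signed edge distance, mm
  pmin(pmax(0.5 - dist / pixel_spacing, 0), 1)
}

paint <- function(img, cov, value) img * (1 - cov) + value * cov

#' Render a dynamic phantom series
#'
#' Deterministic (no randomness): every frame equals the static background with
#' the vessels painted at their gamma-variate enhancement for that frame time.
#'
#' @param spec a [phantom_spec()].
#' @return A [dynamic_series()] of attenuation maps in mm^-1.
#' @export
render_dynamic_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  static <- matrix(0, n, n)
  for (p in spec$primitives) {
    cov <- primitive_coverage(p$shape, p$center, p$axes, n, spec$pixel_spacing)
    static <- paint(static, cov, p$value)
  }
  covs <- lapply(spec$vessels, function(v)
    primitive_coverage("disk", v$center, v$diameter / 2, n, spec$pixel_spacing))
  tt <- seq_len(spec$n_frames) * spec$frame_interval
  out <- array(0, c(n, n, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    frame <- static
    for (i in seq_along(spec$vessels)) {
      v <- spec$vessels[[i]]
      enh <- gamma_variate(tt[f], v$peak_frame * spec$frame_interval,
                           v$alpha_gamma, v$c0)
      frame <- paint(frame, covs[[i]], v$baseline_attenuation + enh)
    }
    out[, , f] <- frame
  }
  dynamic_series(out, spec$pixel_spacing, spec$frame_interval)
}

#' FORBILD-style dynamic head phantom preset
#'
#' A head-like phantom: elliptical skull ring, uniform brain background,
#' two low-attenuation ventricle-like ellipses, and three time-varying vessels
#' of 10, 5 and 2.5 mm diameter whose enhancement follows a gamma-variate
#' bolus (`alpha = 11`) peaking at the 10th of 27 frames (2 s interval, 54 s).
#' Attenuation values are realistic narrow-beam coefficients around
#' `mu_water = 0.02 mm^-1` (so 1000 HU ~ 0.02 mm^-1). The vessels' peak
#' enhancement defaults to 0.02 mm^-1 -- a unit bolus amplitude on the same
#' scale as the brain background, the convention of FORBILD-style phantoms
#' where tissue values are ~1 and the inserted bolus peaks at 1.
#'
#' @param image_size,pixel_spacing,n_frames,frame_interval see [phantom_spec()].
#' @param c0 vessel peak contrast enhancement in mm^-1.
#' @return A [phantom_spec()].
#' @export
forbild_head_spec <- function(image_size = 512, pixel_spacing = 0.75,
                              n_frames = 27, frame_interval = 2,
                              c0 = 0.02) {
  mu <- function(hu) 0.02 * (1 + hu / 1000)
  prim <- list(
    list(shape = "ellipse", center = c(0, 0), axes = c(90, 115),
         value = mu(1200)),                       # skull
    list(shape = "ellipse", center = c(0, 0), axes = c(82, 107),
         value = mu(40)),                         # brain
    list(shape = "ellipse", center = c(-14, 12), axes = c(9, 24),
         value = mu(2)),                          # ventricles
    list(shape = "ellipse", center = c(14, 12), axes = c(9, 24),
         value = mu(2))
  )
  vessels <- list(
    vessel_dynamics(c(-45, -40), 10,  mu(50), c0),
    vessel_dynamics(c(0, -48),    5,  mu(50), c0),
    vessel_dynamics(c(45, -40), 2.5,  mu(50), c0)
  )
  phantom_spec(prim, vessels, image_size, pixel_spacing,
               n_frames, frame_interval)
}

#' Rod-based perfusion phantom
#'
#' Emulates a flow phantom with an "artery" rod carrying the arterial input
#' function, a "vein" rod carrying a delayed/dispersed copy, and two "tissue"
#' rods whose signal follows the indicator-dilution model
#' `tissue(t) = (CBF / cbf_scale) * dt * (AIF (*) R)(t)` with residue function
#' `R` either a decaying exponential (`exp(-t/mtt)`) or a box (`1` for
#' `t < mtt`). A closed loop with [svd_deconvolve()] using the same
#' `cbf_scale` recovers `cbf_true`.
#'
#' @param aif arterial enhancement per frame (same units as image attenuation).
#' @param cbf_true ground-truth flow in ml/100g/min.
#' @param residue `"exponential"` or `"box"`.
#' @param mtt mean transit time in seconds.
#' @param spec a [phantom_spec()]-like layout created by [rod_phantom_spec()].
#' @param cbf_scale unit conversion from 1/s to ml/100g/min; see
#'   [perfusion_config()].
#' @return A [dynamic_series()].
#' @export
render_perfusion_rod_phantom <- function(aif, cbf_true,
                                         residue = c("exponential", "box"),
                                         mtt, spec = rod_phantom_spec(),
                                         cbf_scale = 6000 / 1.04) {
  residue <- match.arg(residue)
  if (mtt <= 0) stop("mtt must be positive")
  nt <- spec$n_frames
  if (length(aif) != nt) stop("aif must be sampled at the series frame interval")
  dt <- spec$frame_interval
  tt <- (seq_len(nt) - 1) * dt
  R <- switch(residue,
              exponential = exp(-tt / mtt),
              box = as.numeric(tt < mtt))
  flow <- cbf_true / cbf_scale                 # 1/s
  tissue <- dt * flow * discrete_convolve(aif, R)
  vein <- c(rep(0, 2), aif[seq_len(nt - 2)]) * 0.9   # delayed, slightly dispersed
  mu_base <- spec$base_value

  n <- spec$image_size
  static <- matrix(0, n, n)
  disk_cov <- primitive_coverage("disk", c(0, 0), spec$disk_radius, n,
                                 spec$pixel_spacing)
  static <- paint(static, disk_cov, mu_base)
  covs <- lapply(spec$rods, function(r)
    primitive_coverage("disk", r$center, r$radius, n, spec$pixel_spacing))
  series <- list(artery = aif, vein = vein,
                 tissue1 = tissue, tissue2 = tissue)
  out <- array(0, c(n, n, nt))
  for (f in seq_len(nt)) {
    frame <- static
    for (i in seq_along(spec$rods)) {
      r <- spec$rods[[i]]
      frame <- paint(frame, covs[[i]], mu_base + series[[r$role]][f])
    }
    out[, , f] <- frame
  }
  dynamic_series(out, spec$pixel_spacing, spec$frame_interval)
}

#' Rod phantom layout
#'
#' @param image_size,pixel_spacing,n_frames,frame_interval series geometry.
#' @param disk_radius scan-disk radius in mm.
#' @param base_value background attenuation in mm^-1.
#' @return Layout list used by [render_perfusion_rod_phantom()].
#' @export
rod_phantom_spec <- function(image_size = 256, pixel_spacing = 0.75,
                             n_frames = 27, frame_interval = 2,
                             disk_radius = 70, base_value = 0.019) {
  structure(list(
    image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    disk_radius = disk_radius, base_value = base_value,
    rods = list(
      list(role = "artery",  center = c(-30, 0),  radius = 6),
      list(role = "vein",    center = c(30, 0),   radius = 6),
      list(role = "tissue1", center = c(0, 30),   radius = 9),
      list(role = "tissue2", center = c(0, -30),  radius = 9)
    )), class = "rod_phantom_spec")
}

# Discrete linear convolution truncated to the length of x.
discrete_convolve <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(x[seq_len(i)] * k[i:1])
  out
}
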