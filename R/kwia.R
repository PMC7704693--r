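#' Nyquist-complete k-space radius of a radial acquisition
#'
#' With `n_parallel_views` distinct parallel angles over a half rotation, the
#' azimuthal sample spacing matches the radial spacing out to radius
#' `R = n_parallel_views / pi` (in radial index units); beyond it the spokes
#' are progressively sparser.
#'
#' @param n_parallel_views distinct parallel view angles over 180 degrees.
#' @return Unrounded radius in k-space index units.
#' @export
nyquist_radius <- function(n_parallel_views) {
  stopifnot(n_parallel_views > 0)
  n_parallel_views / pi
}

#' Radius of the unaveraged central ring (Ring 1)
#'
#' The central k-space disk has an effectively higher SNR because radial
#' spokes oversample it; shrinking the single-frame region to radius
#' `R1 = (n_parallel_views / pi) * relative_snr` restores the sampling-density
#' SNR of the full-dose scan when the dose is cut to `relative_snr^2`.
#'
#' @param n_parallel_views distinct parallel view angles over 180 degrees
#'   (fan views per rotation / 2).
#' @param relative_snr SNR of the low-dose scan relative to full dose, in
#'   (0, 1] (i.e. `sqrt(dose fraction)`).
#' @return Integer radius (round half-up).
#' @examples
#' ring1_radius(576, sqrt(0.5))  # 130
#' ring1_radius(576, 0.5)        # 92
#' @export
ring1_radius <- function(n_parallel_views, relative_snr) {
  if (relative_snr <= 0 || relative_snr > 1)
    stop("relative_snr must be in (0, 1]")
  r <- round_half_up(nyquist_radius(n_parallel_views) * relative_snr)
  if (r < 1) stop("Ring 1 radius would be smaller than one k-space sample")
  r
}

#' Outer-ring radii by linear interpolation to the k-space edge
#'
#' Rings 2..n split the remaining annulus evenly:
#' `R_n = R1 + (N_det/2 - R1) * (n - 1) / (N_rings - 1)`. The unrounded Ring-1
#' radius is used for the intermediate arithmetic and each final radius is
#' rounded half-up; the last radius is exactly `n_detectors / 2`.
#'
#' @param r1_unrounded unrounded Ring-1 radius (the [ring1_radius()]
#'   arithmetic before rounding).
#' @param n_detectors detector count (k-space spans `n_detectors` radial
#'   samples, max radius `n_detectors / 2`).
#' @param n_rings total number of rings (>= 1).
#' @return Integer vector of ring radii, strictly increasing.
#' @examples
#' ring_radii(576 / pi * 0.5, 728, 4)  # 92 182 273 364
#' @export
ring_radii <- function(r1_unrounded, n_detectors, n_rings) {
  if (n_rings == 1) return(n_detectors %/% 2)
  if (r1_unrounded >= n_detectors / 2)
    stop("Ring 1 radius must be smaller than n_detectors / 2")
  n <- seq_len(n_rings)
  r <- r1_unrounded + (n_detectors / 2 - r1_unrounded) * (n - 1) / (n_rings - 1)
  radii <- round_half_up(r)
  if (any(diff(radii) <= 0)) stop("ring radii must be strictly increasing")
  radii
}

#' KWIA ring specification
#'
#' @param radii strictly increasing integer k-space radii, ending at
#'   `n_detectors / 2`.
#' @param window_sizes temporal averaging window per ring; Ring 1 must be 1
#'   (never averaged). Default 1, 2, 4, 8, ... doubling outward.
#' @return Object of class `ring_spec`.
#' @export
ring_spec <- function(radii, window_sizes = 2^(seq_along(radii) - 1)) {
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (length(window_sizes) != length(radii))
    stop("one window size per ring is required")
  if (window_sizes[1] != 1) stop("Ring 1 is never averaged (window size 1)")
  if (any(window_sizes < 1)) stop("window sizes must be >= 1")
  structure(list(radii = as.integer(radii),
                 window_sizes = as.integer(window_sizes),
                 n_rings = length(radii)), class = "ring_spec")
}

#' Named ring presets
#'
#' Ring layouts for the shipped study conditions, one per dose level and ring
#' count. The digital-phantom/clinical presets assume 576 parallel views and
#' 728 detectors; the physical-phantom presets 736 detectors. Three-ring
#' middle radii are the empirically chosen values used in the reference
#' configuration rather than the linear-interpolation ones.
#'
#' @param name one of `"kwia50-2ring"`, `"kwia50-3ring"`, `"kwia25-3ring"`,
#'   `"kwia25-4ring"`, `"kwia60-2ring"`, `"kwia60-3ring"`, `"kwia30-3ring"`,
#'   `"kwia30-4ring"`.
#' @return A [ring_spec()].
#' @export
ring_preset <- function(name) {
  presets <- list(
    "kwia50-2ring" = list(c(130, 364),           c(1, 2)),
    "kwia50-3ring" = list(c(130, 234, 364),      c(1, 2, 4)),
    "kwia25-3ring" = list(c(92, 182, 364),       c(1, 2, 4)),
    "kwia25-4ring" = list(c(92, 182, 273, 364),  c(1, 2, 4, 8)),
    "kwia60-2ring" = list(c(142, 368),           c(1, 2)),
    "kwia60-3ring" = list(c(142, 256, 368),      c(1, 2, 4)),
    "kwia30-3ring" = list(c(100, 234, 368),      c(1, 2, 4)),
    "kwia30-4ring" = list(c(100, 190, 280, 368), c(1, 2, 4, 8))
  )
  p <- presets[[name]]
  if (is.null(p))
    stop("unknown ring preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  ring_spec(p[[1]], p[[2]])
}

#' Kaiser-Bessel gridding kernel parameters
#'
#' @param kb_beta kernel shape parameter.
#' @param width kernel support in grid cells.
#' @param oversampling Cartesian grid oversampling factor.
#' @return Object of class `kernel_spec`. Defaults balance side-lobe
#'   suppression against compute: `beta = 16.25`, width 7, oversampling 2.
#' @export
kernel_spec <- function(kb_beta = 16.25, width = 7, oversampling = 2) {
  stopifnot(kb_beta > 0, width > 0, oversampling >= 1)
  structure(list(kb_beta = kb_beta, width = width,
                 oversampling = oversampling), class = "kernel_spec")
}

# Kaiser-Bessel kernel on [-width/2, width/2] (grid cells), unnormalized.
kb_kernel <- function(u, kernel) {
  arg <- 1 - (2 * u / kernel$width)^2
  out <- numeric(length(u))
  ok <- arg > 0
  out[ok] <- besselI(kernel$kb_beta * sqrt(arg[ok]), 0)
  out
}

# Analytic Fourier transform of the KB kernel at nu cycles/grid-cell:
# W * sinh(sqrt(beta^2 - (pi W nu)^2)) / sqrt(...) (sin branch past beta).
kb_kernel_ft <- function(nu, kernel) {
  W <- kernel$width
  a2 <- kernel$kb_beta^2 - (pi * W * nu)^2
  out <- numeric(length(nu))
  pos <- a2 > 0
  out[pos] <- W * sinh(sqrt(a2[pos])) / sqrt(a2[pos])
  neg <- a2 < 0
  out[neg] <- W * sin(sqrt(-a2[neg])) / sqrt(-a2[neg])
  out[a2 == 0] <- W
  out
}

#' Radial k-space of a parallel-beam sinogram
#'
#' By the central slice theorem, the 1D Fourier transform of each parallel
#' projection is a radial spoke through the object's 2D Fourier transform.
#' Spokes are returned centered: column `j` holds radial index
#' `r = j - 1 - n_detectors/2`, with DC at 1-based column `n_detectors/2 + 1`.
#' Values carry physical FT scaling (`detector_spacing` times the DFT), so the
#' DC sample of every view equals the projection's total mass.
#'
#' @param sino a parallel-beam [sinogram()].
#' @return Object of class `radial_kspace`: complex matrix `samples`
#'   `[view, radial]`, `angles`, and the radial coordinate step
#'   `dk = 1 / (n_detectors * detector_spacing)` in cycles/mm.
#' @export
projections_to_radial_kspace <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  if (sino$geometry$beam_type != "parallel")
    stop("fan-beam input: rebin with rebin_fan_to_parallel() first")
  p <- sino$values
  M <- ncol(p)
  dd <- sino$geometry$detector_spacing
  # detector offsets are (j - M/2) * dd: shift before/after the row FFTs
  sh <- c((M %/% 2 + 1):M, 1:(M %/% 2))
  S <- t(mvfft(t(p[, sh, drop = FALSE])))[, sh, drop = FALSE] * dd
  structure(list(samples = S, angles = sino$view_angles,
                 n_radial = M, dk = 1 / (M * dd),
                 detector_spacing = dd), class = "radial_kspace")
}

# Exact band-limited radial refinement of centered spokes: back to the
# projection domain, zero-pad symmetrically, re-transform. Valid because the
# projections have compact support within the detector span.
refine_spokes <- function(S, factor) {
  M <- ncol(S)
  sh <- c((M %/% 2 + 1):M, 1:(M %/% 2))
  p <- t(mvfft(t(S[, sh, drop = FALSE]), inverse = TRUE))[, sh, drop = FALSE] / M
  M2 <- factor * M
  p2 <- matrix(0 + 0i, nrow(S), M2)
  p2[, (M2 %/% 2 - M %/% 2 + 1):(M2 %/% 2 + M %/% 2)] <- p
  sh2 <- c((M2 %/% 2 + 1):M2, 1:(M2 %/% 2))
  t(mvfft(t(p2[, sh2, drop = FALSE])))[, sh2, drop = FALSE]
}

# Radial index magnitude per column of a radial_kspace sample matrix.
radial_index <- function(n_radial) abs(seq_len(n_radial) - 1 - n_radial %/% 2)

# Ring membership per k-space column: ring n iff R_{n-1} < |r| <= R_n
# (R_0 = 0; DC belongs to Ring 1). Hard boundaries.
ring_of_column <- function(n_radial, rings) {
  rr <- radial_index(n_radial)
  ring <- findInterval(rr, c(0, rings$radii), left.open = TRUE)
  ring[rr == 0] <- 1L
  ring[ring > rings$n_rings] <- rings$n_rings  # r = n/2 edge sample
  ring
}

# Temporal window (frame indices) for frame i, window size M, series length T:
# offsets ceil(-(M-1)/2)..ceil((M-1)/2), slid (not shrunk) to stay in range.
window_frames <- function(i, M, T) {
  if (M > T) stop("series shorter than the averaging window")
  off <- ceiling(-(M - 1) / 2):ceiling((M - 1) / 2)
  f <- i + off
  if (f[1] < 1) f <- f - f[1] + 1
  if (f[M] > T) f <- f - (f[M] - T)
  f
}

#' KWIA view-shared averaging of a radial k-space series
#'
#' Builds frame `i`'s k-space ring by ring: samples in ring `n` are the
#' uniform average of the same samples over that ring's temporal window
#' (`1/M` weights); Ring 1 passes frame `i` through unchanged, preserving the
#' contrast-defining low-frequency content exactly. Near the ends of the
#' series the whole window slides to stay in range while keeping its size.
#'
#' @param series 3D complex array `[view, radial, frame]` (or a list of
#'   `radial_kspace` objects sharing geometry).
#' @param rings a [ring_spec()].
#' @param frame_index frame to reconstruct (1-based).
#' @return Complex matrix `[view, radial]` of combined samples.
#' @export
kwia_combine <- function(series, rings, frame_index) {
  if (is.list(series) && !is.array(series))
    series <- simplify2array(lapply(series, `[[`, "samples"))
  stopifnot(length(dim(series)) == 3)
  T <- dim(series)[3]
  if (max(rings$window_sizes) > T)
    stop("series shorter than the averaging window")
  out <- series[, , frame_index]
  ring_col <- ring_of_column(dim(series)[2], rings)
  for (n in seq_len(rings$n_rings)[-1]) {
    M <- rings$window_sizes[n]
    if (M == 1) next
    cols <- which(ring_col == n)
    if (!length(cols)) next
    fr <- window_frames(frame_index, M, T)
    acc <- series[, cols, fr[1]]
    for (f in fr[-1]) acc <- acc + series[, cols, f]
    out[, cols] <- acc / M
  }
  out
}

#' Density-compensation weights for radial k-space samples
#'
#' Voronoi-cell areas of the regular radial trajectory, in closed form: on a
#' polar lattice the cell of a sample at radius `r` spokes apart by `dtheta`
#' is the annular sector `[r - 1/2, r + 1/2] x dtheta`, whose area is exactly
#' `dtheta * r` -- the ramp profile expected of radial sampling. The DC cell
#' (a disk of radius 1/2) is shared equally by the spokes, and the outermost
#' cell is clipped to the maximum-frequency disk. Areas are in units of the
#' radial sample spacing squared; the full set partitions the sampled k-disk.
#'
#' @param n_radial radial samples per spoke (= detector count).
#' @param n_views number of spokes over 180 degrees (>= 3).
#' @return Weight matrix `[view, radial]` matching a `radial_kspace` sample
#'   matrix.
#' @export
voronoi_weights <- function(n_radial, n_views) {
  if (n_views < 3) stop("at least 3 views are required")
  rr <- radial_index(n_radial)
  dtheta <- pi / n_views
  R <- n_radial / 2
  w <- dtheta * rr
  w[rr == 0] <- pi * 0.25 / n_views          # shared DC disk
  w[rr == R] <- dtheta * (R - 0.25) / 2      # edge cell clipped to the k-disk
  matrix(rep(w, each = n_views), n_views, n_radial)
}

#' Regrid radial k-space onto an oversampled Cartesian grid
#'
#' Density-compensated convolution gridding with a Kaiser-Bessel kernel. Each
#' weighted sample is spread over `width x width` grid cells; the grid has
#' `oversampling * n_radial` cells per side and spans the same maximum
#' frequency as the spokes.
#'
#' Spokes are refined radially before gridding (default factor 2) by
#' zero-padding each projection and re-transforming: for an object contained
#' in the detector span the padded transform is the exact continuous
#' spectrum at the finer radial spacing. This sharpens the quadrature of the
#' rapidly varying low-frequency spectrum that the density weights integrate.
#' For synthetic spokes that do not come from a contained projection (e.g.
#' kernel-calibration impulses), set `radial_refine = 1`.
#'
#' @param kspace a `radial_kspace` (from [projections_to_radial_kspace()] or
#'   [kwia_combine()] plus geometry) or complex sample matrix.
#' @param weights per-sample density weights from [voronoi_weights()] sized
#'   for the *refined* spokes; if `NULL` (recommended) they are computed.
#' @param kernel a [kernel_spec()].
#' @param angles spoke angles (only needed when `kspace` is a bare matrix).
#' @param dk radial sample spacing in cycles/mm (bare-matrix case).
#' @param radial_refine integer radial refinement factor (1 disables).
#' @return Complex matrix `G x G` of gridded k-space, DC at 1-based index
#'   `G/2 + 1`, with attribute `dk` (grid cell size in cycles/mm).
#' @export
regrid_to_cartesian <- function(kspace, weights = NULL,
                                kernel = kernel_spec(),
                                angles = NULL, dk = NULL,
                                radial_refine = 2) {
  if (inherits(kspace, "radial_kspace")) {
    S <- kspace$samples; angles <- kspace$angles; dk <- kspace$dk
  } else S <- kspace
  if (is.null(angles) || is.null(dk))
    stop("angles and dk are required for bare sample matrices")
  M <- ncol(S)
  G <- as.integer(round(kernel$oversampling * M))
  if (kernel$width > G) stop("kernel width exceeds the grid size")
  if (radial_refine > 1) {
    S <- refine_spokes(S, radial_refine)
    dk <- dk / radial_refine
    M <- ncol(S)
  }
  if (is.null(weights)) weights <- voronoi_weights(M, nrow(S))
  # physical cell areas: weights are in (radial spacing)^2 units
  w_phys <- weights * dk^2
  nlut <- 2048L
  lut_u <- seq(0, kernel$width / 2, length.out = nlut)
  lut <- kb_kernel(lut_u, kernel)
  lut_scale <- (nlut - 1) / (kernel$width / 2)
  g <- cpp_grid_radial(Re(S), Im(S), w_phys, angles, G,
                       kernel$width, lut, lut_scale)
  out <- matrix(complex(real = g$re, imaginary = g$im), G, G)
  attr(out, "dk") <- dk / kernel$oversampling
  attr(out, "kernel") <- kernel
  out
}

#' Inverse FFT and deapodization of gridded k-space
#'
#' Centered 2D inverse FFT of the oversampled grid, division by the kernel's
#' analytic Fourier transform (deapodization), and central crop. Pixels where
#' the deapodization divisor falls below 1e-8 of its peak are masked to zero.
#'
#' @param cart complex `G x G` gridded k-space from [regrid_to_cartesian()].
#' @param kernel the [kernel_spec()] used for gridding.
#' @param final_size side length of the cropped output image
#'   (`G / oversampling` by default).
#' @return Real image matrix `final_size x final_size` in the units of the
#'   projected attenuation map (mm^-1), pixel size equal to the detector
#'   spacing.
#' @export
inverse_fft_and_deapodize <- function(cart, kernel = attr(cart, "kernel"),
                                      final_size = NULL) {
  G <- nrow(cart)
  if (is.null(kernel)) kernel <- kernel_spec()
  if (is.null(final_size)) final_size <- as.integer(round(G / kernel$oversampling))
  img_full <- Re(fftshift2(fft(ifftshift2(cart), inverse = TRUE)))
  nu <- (seq_len(G) - 1 - G %/% 2) / G
  de <- kb_kernel_ft(nu, kernel)
  D <- outer(de, de)
  bad <- abs(D) < 1e-8 * max(abs(D))
  D[bad] <- Inf
  img_full <- img_full / D
  keep <- (G %/% 2 - final_size %/% 2 + 1):(G %/% 2 + (final_size + 1) %/% 2)
  img_full[keep, keep]
}

#' Regridding reconstruction of a single parallel-beam sinogram
#'
#' The plain (no view sharing) Fourier reconstruction: 1D FFT per projection,
#' Voronoi/ramp density compensation, Kaiser-Bessel gridding, inverse 2D FFT
#' and deapodization.
#'
#' @param sino a parallel-beam [sinogram()].
#' @param kernel a [kernel_spec()].
#' @param final_size output image side (defaults to detector count).
#' @return Real image matrix (mm^-1), pixel size = detector spacing.
#' @export
regrid_reconstruct <- function(sino, kernel = kernel_spec(),
                               final_size = NULL) {
  ks <- projections_to_radial_kspace(sino)
  cart <- regrid_to_cartesian(ks, kernel = kernel)
  inverse_fft_and_deapodize(cart, kernel, final_size)
}

#' KWIA reconstruction of a dynamic sinogram series
#'
#' Full chain per frame: radial k-space of every frame, ring-wise view-shared
#' averaging ([kwia_combine()]), density compensation, Kaiser-Bessel
#' regridding, inverse FFT and deapodization. With a single ring the output is
#' identical to plain regridding reconstruction of each frame.
#'
#' @param series a [sinogram_series()] of (typically noisy) line integrals.
#' @param rings a [ring_spec()]; `NULL` means a single ring covering all of
#'   k-space (plain regridding, no view sharing).
#' @param kernel a [kernel_spec()].
#' @param final_size output image side (defaults to detector count).
#' @param frames frame indices to reconstruct (default all).
#' @return A [dynamic_series()] of reconstructed frames.
#' @export
reconstruct_kwia_series <- function(series, rings = NULL,
                                    kernel = kernel_spec(),
                                    final_size = NULL, frames = NULL) {
  stopifnot(inherits(series, "sinogram_series"))
  if (is.null(rings))
    rings <- ring_spec(series$geometry$n_detectors %/% 2)
  T <- n_frames(series)
  if (max(rings$window_sizes) > T)
    stop("series shorter than the largest averaging window")
  if (is.null(frames)) frames <- seq_len(T)
  M <- series$geometry$n_detectors
  if (is.null(final_size)) final_size <- M
  ks <- array(complex(real = 0, imaginary = 0),
              c(length(series$view_angles), M, T))
  for (f in seq_len(T))
    ks[, , f] <- projections_to_radial_kspace(sinogram_frame(series, f))$samples
  dk <- 1 / (M * series$geometry$detector_spacing)
  out <- array(0, c(final_size, final_size, length(frames)))
  for (j in seq_along(frames)) {
    comb <- kwia_combine(ks, rings, frames[j])
    cart <- regrid_to_cartesian(comb, kernel = kernel,
                                angles = series$view_angles, dk = dk)
    out[, , j] <- inverse_fft_and_deapodize(cart, kernel, final_size)
  }
  dynamic_series(out, series$geometry$detector_spacing,
                 series$frame_interval)
}
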