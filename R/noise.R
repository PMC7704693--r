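#' Dose / photon-flux configuration
#'
#' @param n_emitted photons emitted per detector channel per view at full dose
#'   (`N_e`). The default 4.8e6 is a clinical-equivalent full-dose flux.
#' @param dose_fraction tube-current fraction `beta/alpha` in (0, 1].
#' @param seed optional RNG seed applied by the sampling functions.
#' @return Object of class `dose_config`.
#' @export
dose_config <- function(n_emitted = 4.8e6, dose_fraction = 1, seed = NULL) {
  if (n_emitted <= 0) stop("n_emitted must be positive")
  if (dose_fraction <= 0 || dose_fraction > 1)
    stop("dose_fraction must be in (0, 1]")
  structure(list(n_emitted = n_emitted, dose_fraction = dose_fraction,
                 seed = seed), class = "dose_config")
}

#' Theoretical detector SNR for a Poisson-limited measurement
#'
#' For `N = Poisson(N_e * exp(-l))` counts, mean/SD equals
#' `sqrt(N_e * exp(-l))`: halving the flux multiplies SNR by `1/sqrt(2)`
#' (70.7%), quartering it by 0.5.
#'
#' @param n_emitted emitted photons `N_e`.
#' @param line_integral attenuation line integral `l` (dimensionless).
#' @return Dimensionless SNR.
#' @export
theoretical_snr <- function(n_emitted, line_integral) {
  stopifnot(all(n_emitted >= 0), all(line_integral >= 0))
  sqrt(n_emitted * exp(-line_integral))
}

#' Simulate detector counts from noiseless line integrals
#'
#' Each detector sample is drawn independently as
#' `Poisson(dose_fraction * N_e * exp(-l))`: tube-current reduction scales the
#' Poisson mean proportionally. Electronic (Gaussian) noise is ignored and the
#' compound-Poisson detector response is approximated as pure Poisson.
#'
#' @param sino a [sinogram()] (or bare matrix) of line integrals.
#' @param dose a [dose_config()]; if it carries a `seed`, the RNG is seeded
#'   for bit-reproducibility.
#' @return Matrix of integer counts with the shape of the input.
#' @export
counts_from_line_integrals <- function(sino, dose) {
  stopifnot(inherits(dose, "dose_config"))
  vals <- if (inherits(sino, "sinogram")) sino$values else sino
  if (!all(is.finite(vals))) stop("line integrals must be finite")
  lambda <- dose$dose_fraction * dose$n_emitted * exp(-vals)
  if (any(lambda > 1e12))
    stop("Poisson mean overflow: line integrals too negative for this flux")
  if (!is.null(dose$seed)) set.seed(dose$seed)
  matrix(rpois(length(lambda), lambda), nrow(vals), ncol(vals))
}

#' Inject additional dose reduction into already-noisy counts
#'
#' Turns full-dose counts (which already carry Poisson noise) into counts at a
#' reduced dose without access to the noiseless line integrals: the output is
#' `dose_fraction * counts + Poisson0(v)` where `Poisson0` is a zero-mean
#' Poisson-derived term with variance
#' `v = (dose_fraction - dose_fraction^2) * N_e * exp(-l)`. The unknown
#' per-ray attenuation is estimated from the observed counts
#' (`N_e * exp(-l_hat) = counts`), so both the mean and the variance of the
#' output equal `dose_fraction * N_e * exp(-l)` as for a genuine low-dose
#' acquisition.
#'
#' @param counts_full matrix of full-dose counts.
#' @param n_emitted_full full-dose `N_e` (used only for validation; the noise
#'   variance is estimated directly from the observed counts).
#' @param dose_fraction target dose fraction in (0, 1].
#' @param seed optional RNG seed.
#' @return Matrix of reduced-dose counts (non-integer: the scaled term is
#'   continuous, matching the target mean and variance).
#' @export
inject_dose_reduction <- function(counts_full, n_emitted_full, dose_fraction,
                                  seed = NULL) {
  if (any(counts_full < 0)) stop("counts must be non-negative")
  if (dose_fraction > 1) stop("dose_fraction must be <= 1")
  if (dose_fraction <= 0) stop("dose_fraction must be positive")
  if (dose_fraction == 1) return(counts_full)
  if (!is.null(seed)) set.seed(seed)
  v <- (dose_fraction - dose_fraction^2) * pmax(counts_full, 1)
  noise <- rpois(length(v), v) - v
  out <- dose_fraction * counts_full + noise
  matrix(pmax(out, 0), nrow(counts_full), ncol(counts_full))
}

#' Log-convert counts back to attenuation line integrals
#'
#' `l = -log(max(counts, 1) / n_emitted)`; counts are floored at one photon to
#' guard against photon starvation in the log.
#'
#' @param counts matrix of detector counts.
#' @param n_emitted emitted photons for these counts (i.e. already scaled by
#'   the dose fraction for a low-dose acquisition).
#' @param geometry optional [projection_geometry()]; when supplied a
#'   [sinogram()] is returned instead of a bare matrix.
#' @return Matrix (or [sinogram()]) of line integrals.
#' @export
line_integrals_from_counts <- function(counts, n_emitted, geometry = NULL) {
  if (n_emitted <= 0) stop("n_emitted must be positive")
  l <- -log(pmax(counts, 1) / n_emitted)
  if (!is.null(geometry)) sinogram(l, geometry) else l
}

#' Apply Poisson low-dose simulation to a whole sinogram series
#'
#' Convenience chain: counts at the requested dose from each frame's noiseless
#' line integrals, then log conversion back to noisy line integrals.
#'
#' @param series a [sinogram_series()] of noiseless line integrals.
#' @param dose a [dose_config()].
#' @return A [sinogram_series()] of noisy line integrals at that dose.
#' @export
simulate_low_dose_series <- function(series, dose) {
  stopifnot(inherits(series, "sinogram_series"))
  if (!is.null(dose$seed)) set.seed(dose$seed)
  out <- series$values
  ne <- dose$dose_fraction * dose$n_emitted
  for (f in seq_len(n_frames(series))) {
    cts <- counts_from_line_integrals(
      series$values[, , f],
      dose_config(dose$n_emitted, dose$dose_fraction))
    out[, , f] <- line_integrals_from_counts(cts, ne)
  }
  sinogram_series(out, series$geometry, series$frame_interval,
                  series$view_angles)
}
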