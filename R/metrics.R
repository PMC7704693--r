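#' ROI signal-to-noise ratio
#'
#' Mean over SD of the pixels in a (nominally uniform) ROI, the SD computed
#' with denominator `n - 1`. Mean and SD come from the same region, so SNR is
#' invariant to a positive rescaling of the image but not to adding an offset.
#'
#' @param image numeric matrix.
#' @param roi an `roi` ([roi_circle()] / [roi_mask()]) with at least 2 pixels.
#' @return Dimensionless SNR.
#' @export
roi_snr <- function(image, roi) {
  px <- image[roi_indices(roi, dim(image))]
  if (length(px) < 2) stop("ROI must contain at least 2 pixels")
  s <- sd(px)
  if (s == 0)
    stop(structure(class = c("kwia_snr_undefined", "error", "condition"),
                   list(message = "SNR undefined (uniform region)", call = sys.call())))
  mean(px) / s
}

#' Two-region contrast-to-noise ratio
#'
#' `(mean1 - mean2) / sqrt(var1 + var2)`. Shift-invariant (unlike SNR).
#'
#' @param image numeric matrix.
#' @param roi1,roi2 `roi` objects with at least 2 pixels each.
#' @return Dimensionless CNR.
#' @export
roi_cnr <- function(image, roi1, roi2) {
  p1 <- image[roi_indices(roi1, dim(image))]
  p2 <- image[roi_indices(roi2, dim(image))]
  if (length(p1) < 2 || length(p2) < 2)
    stop("both ROIs must contain at least 2 pixels")
  v <- var(p1) + var(p2)
  if (v == 0)
    stop(structure(class = c("kwia_cnr_undefined", "error", "condition"),
                   list(message = "CNR undefined (both regions uniform)", call = sys.call())))
  (mean(p1) - mean(p2)) / sqrt(v)
}

#' Bland-Altman agreement summary
#'
#' Mean difference between paired measurements and the 95% limits of
#' agreement (`bias +/- 1.96 * SD` of the differences).
#'
#' @param values_a,values_b equal-length paired numeric vectors.
#' @return List with `bias`, `lower`, `upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  if (length(values_a) < 2) stop("at least 2 pairs are required")
  d <- values_a - values_b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}
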