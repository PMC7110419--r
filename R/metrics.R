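# Focality metrics: ratio of the "therapeutic dose" (mean directional ROI
# intensity) to the "side effects" (a non-ROI field summary). Each metric
# is the natural companion of one non-ROI constraint type: the integral
# metric divides by the root mean non-ROI energy (the quadratic bound),
# the elementwise metric by the maximum non-ROI field magnitude (the
# second-order-cone bound). Both are unitless and invariant to pattern
# scaling.

#' Mean directional ROI intensity of a pattern
#'
#' `d' Gamma T i / Vol_ROI`, in V/m: the maximized functional normalized
#' by the ROI volume.
#'
#' @param pattern [current_pattern()], independent or expanded numeric.
#' @param transfer a [build_transfer_matrix()] result.
#' @param weights a [build_volume_weights()] result.
#' @param target a [define_roi_orientation()] result.
#' @return intensity in V/m.
#' @export
mean_roi_intensity <- function(pattern, transfer, weights, target) {
  i <- as_independent(pattern, transfer$L)
  sum(target$d * weights$gamma * (transfer$M %*% i)) / target$roi_volume
}

#' Integral focality
#'
#' Mean directional ROI intensity divided by the square root of the mean
#' non-ROI field energy:
#' `(d' Gamma T i / Vol_ROI) / sqrt(i' T' Gamma_nonROI T i / Vol_nonROI)`.
#'
#' @inheritParams mean_roi_intensity
#' @return unitless focality; `Inf` (with a warning) when the non-ROI
#'   field vanishes.
#' @export
integral_focality <- function(pattern, transfer, weights, target) {
  i <- as_independent(pattern, transfer$L)
  num <- mean_roi_intensity(i, transfer, weights, target)
  e <- as.numeric(i %*% crossprod(transfer$M, weights$gamma_nonroi * (transfer$M %*% i)))
  if (e <= 0) {
    warning("non-ROI field energy is zero; focality is infinite")
    return(Inf)
  }
  num / sqrt(e / target$nonroi_volume)
}

#' Elementwise focality
#'
#' Mean directional ROI intensity divided by the maximum non-ROI field
#' magnitude `max_n ||T_n i||`.
#'
#' @inheritParams mean_roi_intensity
#' @return unitless focality; `Inf` (with a warning) when the non-ROI
#'   field vanishes.
#' @export
elementwise_focality <- function(pattern, transfer, weights, target) {
  i <- as_independent(pattern, transfer$L)
  num <- mean_roi_intensity(i, transfer, weights, target)
  nrm <- sqrt(colSums(matrix(transfer$M %*% i, nrow = 3L)^2))
  roi_mask <- logical(length(transfer$elements))
  roi_mask[target$roi_local] <- TRUE
  mx <- max(nrm[!roi_mask])
  if (mx <= 0) {
    warning("non-ROI field is zero; focality is infinite")
    return(Inf)
  }
  num / mx
}
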