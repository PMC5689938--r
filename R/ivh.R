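# First-order intensity and intensity-volume-histogram (IVH) features.

IVH_CUTPOINTS <- c(10, 25, 50, 75, 90)

#' Intensity and intensity-volume histogram features
#'
#' Twenty global first-order metrics of the in-mask SUV distribution:
#' moments (mean, SD, min, max, median, range, skewness, excess kurtosis),
#' energy (sum of squared SUVs), intensity entropy (Shannon entropy in bits
#' of the discretized-level histogram), and the IVH families
#' \code{Vx}/\code{Ix} at x = 10, 25, 50, 75, 90:
#' \itemize{
#'   \item \code{Vx}: percentage of ROI volume with intensity at least
#'     x\% of the ROI intensity range above the minimum (relative-intensity
#'     axis), e.g. V90 is the volume fraction above 90\% relative intensity.
#'   \item \code{Ix}: the minimum absolute intensity of the hottest x\% of
#'     the ROI volume, e.g. I90 is the lowest SUV among the hottest 90\%.
#'     \code{Ix} is non-increasing in x (a larger hot fraction reaches down
#'     to cooler voxels).
#' }
#' A constant ROI returns sd = 0 and (with a warning) 0 for the
#' sd-normalized moments; its intensity entropy is 0.
#'
#' @param volume an [suv_volume].
#' @param mask an [roi_mask] aligned with \code{volume}.
#' @param d optional \code{discretized_roi} used for the intensity entropy;
#'   defaults to a 64-level discretization of \code{volume}/\code{mask}.
#' @return Named numeric vector of length 20.
#' @export
ivh_features <- function(volume, mask, d = NULL) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "roi_mask"))
  check_geometry(volume, mask)
  check_nonempty(mask)
  if (is.null(d)) {
    d <- suppressWarnings(discretize_roi(volume, mask, Ng = 64L))
  }
  vals <- volume$values[mask$values != 0L]
  n <- length(vals)
  mn <- min(vals); mx <- max(vals)
  rng <- mx - mn
  hist_p <- level_histogram(d) / sum(d$mask)
  entropy <- -sum(xlog2x(hist_p))

  vx <- vapply(IVH_CUTPOINTS, function(x) {
    thr <- mn + (x / 100) * rng
    100 * mean(vals >= thr)
  }, numeric(1))
  sorted_desc <- sort(vals, decreasing = TRUE)
  ix <- vapply(IVH_CUTPOINTS, function(x) {
    k <- max(1L, ceiling(x / 100 * n))
    sorted_desc[k]
  }, numeric(1))

  out <- c(
    ivh_mean = mean(vals),
    ivh_sd = stats::sd(if (n > 1L) vals else c(vals, vals)),
    ivh_min = mn,
    ivh_max = mx,
    ivh_median = stats::median(vals),
    ivh_range = rng,
    ivh_skewness = sample_skewness(vals),
    ivh_kurtosis = sample_kurtosis(vals),
    ivh_energy = sum(vals^2),
    ivh_intensity_entropy = entropy
  )
  names(vx) <- paste0("ivh_v", IVH_CUTPOINTS)
  names(ix) <- paste0("ivh_i", IVH_CUTPOINTS)
  c(out, vx, ix)
}
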