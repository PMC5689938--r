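#' Fixed-bin-count gray-level discretization of a masked ROI
#'
#' Down-samples in-mask SUVs into \code{Ng} equally spaced bins over the
#' ROI's own intensity range. The bin width is
#' \deqn{\mathrm{bin\ size} = (SUV_{max} - SUV_{min}) / N_g}
#' with extrema taken over in-mask voxels only, and each voxel gets level
#' \eqn{\min(N_g, \lfloor (SUV - SUV_{min}) / \mathrm{bin\ size} \rfloor + 1)}
#' so the ROI maximum lands in bin \eqn{N_g} rather than an overflow bin.
#'
#' A constant ROI (zero intensity range) is degenerate: every voxel is
#' assigned level 1 and a warning is emitted, so downstream texture matrices
#' stay defined.
#'
#' @param volume an [suv_volume].
#' @param mask an [roi_mask] aligned to \code{volume}, non-empty.
#' @param Ng number of gray levels, an integer >= 2 (the study grid is
#'   32, 64, 128, 256 with 64 as reference).
#' @return An object of class \code{discretized_roi} with fields
#'   \code{levels} (3D integer array, \code{NA} outside the mask),
#'   \code{mask} (logical array), \code{Ng}, \code{bin_size},
#'   \code{suv_min}, \code{suv_max} and \code{spacing_mm}.
#' @examples
#' v <- suv_volume(array(seq(0, 10, length.out = 8), c(2, 2, 2)),
#'                 spacing_mm = c(1, 1, 1))
#' m <- roi_mask(array(1, c(2, 2, 2)), c(1, 1, 1))
#' d <- discretize_roi(v, m, Ng = 32)
#' d$bin_size   # (10 - 0) / 32
#' @export
discretize_roi <- function(volume, mask, Ng) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "roi_mask"))
  check_geometry(volume, mask)
  check_nonempty(mask)
  if (!is.numeric(Ng) || length(Ng) != 1L || Ng < 2 || Ng != round(Ng)) {
    stop("`Ng` must be a single integer >= 2, got ", deparse(Ng),
         call. = FALSE)
  }
  Ng <- as.integer(Ng)
  inmask <- mask$values != 0L
  vals <- volume$values[inmask]
  suv_min <- min(vals)
  suv_max <- max(vals)
  bin_size <- (suv_max - suv_min) / Ng
  levels <- array(NA_integer_, dim = dim(volume$values))
  if (bin_size <= 0) {
    warning("constant ROI (SUVmax == SUVmin): all voxels assigned level 1",
            call. = FALSE)
    levels[inmask] <- 1L
  } else {
    lv <- pmin(Ng, as.integer(floor((vals - suv_min) / bin_size)) + 1L)
    levels[inmask] <- lv
  }
  structure(list(levels = levels, mask = inmask, Ng = Ng,
                 bin_size = bin_size, suv_min = suv_min, suv_max = suv_max,
                 spacing_mm = volume$spacing_mm),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf(
    "<discretized_roi> Ng = %d, bin size = %.4g SUV, range [%.3g, %.3g], %d voxels\n",
    x$Ng, x$bin_size, x$suv_min, x$suv_max, sum(x$mask)))
  invisible(x)
}

# Histogram of levels over the in-mask voxels, length Ng (may contain zeros).
level_histogram <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  tabulate(d$levels[d$mask], nbins = d$Ng)
}
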