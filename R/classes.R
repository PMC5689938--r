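#' SUV volume container
#'
#' A 3D scalar grid of standardized uptake values (SUV, g/ml) with voxel
#' spacing and a world origin. Internal coordinates are voxel-indexed with
#' canonical axis order (x, y, z); conversion to file conventions happens
#' only at the I/O boundary.
#'
#' @param values 3D numeric array, all finite.
#' @param spacing_mm numeric triple of strictly positive voxel sizes (mm).
#' @param origin numeric triple, world position (mm) of the first voxel.
#' @return An object of class \code{suv_volume}.
#' @examples
#' v <- suv_volume(array(1, c(4, 4, 2)), spacing_mm = c(5.49, 5.49, 3.30))
#' dim(v$values)
#' @export
suv_volume <- function(values, spacing_mm, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3D array, got ", length(dim(values)),
         " dimension(s)", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("volume contains non-finite voxels (NaN/Inf/NA)", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three strictly positive numbers", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite numbers", call. = FALSE)
  }
  structure(list(values = values, spacing_mm = spacing_mm, origin = origin),
            class = "suv_volume")
}

#' Binary region-of-interest mask
#'
#' A binary 3D mask aligned to an SUV volume. Any nonzero input value is
#' coerced to 1.
#'
#' @param values 3D array; nonzero entries mark the ROI.
#' @param spacing_mm voxel spacing triple (mm).
#' @param label variant label, e.g. \code{"MTV1"}, \code{"MTV2"},
#'   \code{"GBSV"}.
#' @param origin world origin triple (mm).
#' @return An object of class \code{roi_mask} whose \code{values} are
#'   integer 0/1.
#' @export
roi_mask <- function(values, spacing_mm, label = "ROI", origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("mask `values` must be a 3D array", call. = FALSE)
  }
  if (anyNA(values)) stop("mask contains NA voxels", call. = FALSE)
  v <- array(as.integer(values != 0), dim = dim(values))
  vol <- suv_volume(array(0, dim(v)), spacing_mm, origin) # reuse validation
  structure(list(values = v, spacing_mm = vol$spacing_mm,
                 origin = vol$origin, label = as.character(label)[1]),
            class = "roi_mask")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask '%s'> %s voxels, %d foreground\n", x$label,
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask an \code{roi_mask}.
#' @return Integer voxel count.
#' @export
mask_voxel_count <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$values)
}

# Geometry agreement between a volume/mask pair (or two masks). Errors with
# a descriptive message naming the mismatch.
check_geometry <- function(a, b, what = "mask") {
  if (!identical(dim(a$values), dim(b$values))) {
    stop(sprintf("geometry mismatch: %s grid %s vs volume grid %s", what,
                 paste(dim(b$values), collapse = "x"),
                 paste(dim(a$values), collapse = "x")), call. = FALSE)
  }
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6) {
    stop(sprintf("geometry mismatch: %s spacing differs (%s vs %s mm)", what,
                 paste(signif(b$spacing_mm, 6), collapse = "x"),
                 paste(signif(a$spacing_mm, 6), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Assert a non-empty mask before feature extraction.
check_nonempty <- function(mask) {
  if (sum(mask$values) < 1L) {
    stop("empty ROI mask: at least one foreground voxel required",
         call. = FALSE)
  }
  invisible(TRUE)
}
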