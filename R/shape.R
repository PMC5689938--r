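# Shape features of a binary tumor mask: volume, mesh surface area,
# sphericity, spherical disproportionality, convexity (solidity),
# eccentricity and the surface-to-volume ratio.

# Tetrahedral decomposition of a cube around the 0-7 main diagonal; corner
# index bit code: 1 + x + 2y + 4z.
MT_CORNERS <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
MT_TETS <- matrix(c(1, 2, 4, 8,
                    1, 4, 3, 8,
                    1, 3, 7, 8,
                    1, 7, 5, 8,
                    1, 5, 6, 8,
                    1, 6, 2, 8), ncol = 4, byrow = TRUE)

tri_area <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * sqrt(sum(cr^2))
}

# Iso-surface area at `level` of a scalar field by marching tetrahedra with
# linear edge interpolation. `field` must be zero-padded so the surface
# closes at the array border.
marching_tetrahedra_area <- function(field, spacing, level = 0.5) {
  d <- dim(field)
  inside <- field >= level
  # cubes whose 8 corners straddle the level
  sub <- function(dx, dy, dz)
    inside[(1 + dx):(d[1] - 1 + dx), (1 + dy):(d[2] - 1 + dy),
           (1 + dz):(d[3] - 1 + dz)]
  acc <- sub(0, 0, 0)
  any_in <- acc; all_in <- acc
  for (r in 2:8) {
    s <- sub(MT_CORNERS[r, 1], MT_CORNERS[r, 2], MT_CORNERS[r, 3])
    any_in <- any_in | s
    all_in <- all_in & s
  }
  mixed <- which(any_in & !all_in)
  if (!length(mixed)) return(0)
  ci <- arrayInd(mixed, d - 1L)
  corner_mm <- sweep(MT_CORNERS, 2L, spacing, "*")
  area <- 0
  for (q in seq_len(nrow(ci))) {
    base <- ci[q, ]
    vals <- numeric(8)
    for (r in 1:8) {
      vals[r] <- field[base[1] + MT_CORNERS[r, 1],
                       base[2] + MT_CORNERS[r, 2],
                       base[3] + MT_CORNERS[r, 3]]
    }
    for (t in 1:6) {
      vid <- MT_TETS[t, ]
      tv <- vals[vid]
      ins <- tv >= level
      ni <- sum(ins)
      if (ni == 0L || ni == 4L) next
      pos <- corner_mm[vid, , drop = FALSE]
      interp <- function(ai, bi) {
        tt <- (level - tv[ai]) / (tv[bi] - tv[ai])
        pos[ai, ] + tt * (pos[bi, ] - pos[ai, ])
      }
      if (ni == 1L || ni == 3L) {
        apex <- if (ni == 1L) which(ins) else which(!ins)
        oth <- setdiff(1:4, apex)
        area <- area + tri_area(interp(apex, oth[1]), interp(apex, oth[2]),
                                interp(apex, oth[3]))
      } else {
        aa <- which(ins); bb <- which(!ins)
        p1 <- interp(aa[1], bb[1]); p2 <- interp(aa[1], bb[2])
        p3 <- interp(aa[2], bb[2]); p4 <- interp(aa[2], bb[1])
        area <- area + tri_area(p1, p2, p3) + tri_area(p1, p3, p4)
      }
    }
  }
  area
}

# Voxel-face surface area (exposed face counting); retained as a
# cross-check for the mesh estimator, biased high on smooth shapes.
voxel_face_area <- function(mask_arr, spacing) {
  d <- dim(mask_arr)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask_arr
  face_areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                  spacing[1] * spacing[2])
  total <- 0
  for (axis in 1:3) {
    off <- c(0L, 0L, 0L); off[axis] <- 1L
    diffcnt <- sum(abs(pad - shift_array_zero(pad, off)) *
                     (pad | shift_array_zero(pad, off)))
    total <- total + diffcnt * face_areas[axis]
  }
  total
}

#' Shape features of an ROI mask
#'
#' Morphological descriptors of the binary tumor volume:
#' \itemize{
#'   \item \code{volume_mm3}: voxel count times voxel volume.
#'   \item \code{surface_area_mm2}: triangulated iso-surface area (marching
#'     tetrahedra at level 0.5 on the binary field, pre-smoothed with a
#'     small Gaussian to suppress voxelization staircase bias; set
#'     \code{smooth_sigma_vox = 0} for the raw blocky mesh, or
#'     \code{method = "voxel-face"} for exposed-face counting).
#'   \item \code{sphericity}: \eqn{\pi^{1/3} (6V)^{2/3} / A}, 1 for a ball.
#'   \item \code{spherical_disproportionality}: 1 / sphericity.
#'   \item \code{convexity}: solidity — mask voxel count over the voxel
#'     count of the convexified mask (voxel centers inside the convex hull
#'     of the mask's voxel centers), so any convex digitized shape scores
#'     close to 1 without half-voxel shell bias.
#'   \item \code{eccentricity}: \eqn{\sqrt{1 - \lambda_{min}/\lambda_{max}}}
#'     from the principal axes of the voxel-center covariance; each voxel
#'     contributes its own second moment (\code{spacing^2/12}), which floors
#'     axis lengths for planar or single-voxel masks.
#'   \item \code{surface_to_volume_ratio}: A / V (1/mm).
#' }
#' Shape features depend only on the mask, never on the gray-level
#' discretization.
#'
#' @param mask an [roi_mask], non-empty.
#' @param method surface estimator, \code{"mesh"} (default) or
#'   \code{"voxel-face"}.
#' @param smooth_sigma_vox Gaussian pre-smoothing (voxels) for the mesh
#'   estimator; the default 0.7 is calibrated on analytic balls, where it
#'   puts the iso-surface mid-voxel and keeps the area within about 1\% of
#'   the analytic value for radii of 10 voxels and up.
#' @return A named list of class \code{shape_summary} with the seven fields
#'   above.
#' @export
shape_features <- function(mask, method = c("mesh", "voxel-face"),
                           smooth_sigma_vox = 0.7) {
  stopifnot(inherits(mask, "roi_mask"))
  check_nonempty(mask)
  method <- match.arg(method)
  sp <- mask$spacing_mm
  m <- mask$values
  d <- dim(m)
  nvox <- sum(m)
  vol <- nvox * prod(sp)

  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- m
  if (method == "mesh") {
    field <- if (smooth_sigma_vox > 0) {
      gauss_smooth(pad, rep(smooth_sigma_vox, 3))
    } else pad
    area <- marching_tetrahedra_area(field, sp, level = 0.5)
    if (area <= 0) area <- voxel_face_area(m, sp)  # sub-voxel masks
  } else {
    area <- voxel_face_area(m, sp)
  }

  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area

  # convexity as solidity: voxelize the convex hull of in-mask voxel
  # centers and compare voxel counts
  inm <- m != 0L
  coords_all <- which(inm, arr.ind = TRUE)
  centers <- sweep(coords_all, 2L, sp, "*")
  hull <- convex_hull_3d(centers)
  convexity <- if (is.null(hull$normals)) {
    1  # degenerate (collinear/coplanar) mask: trivially convex
  } else {
    bb_lo <- apply(coords_all, 2L, min)
    bb_hi <- apply(coords_all, 2L, max)
    cand <- as.matrix(expand.grid(bb_lo[1]:bb_hi[1], bb_lo[2]:bb_hi[2],
                                  bb_lo[3]:bb_hi[3]))
    cand_mm <- sweep(cand, 2L, sp, "*")
    dists <- cand_mm %*% t(hull$normals) -
      matrix(hull$offsets, nrow(cand_mm), length(hull$offsets), byrow = TRUE)
    inside <- rowSums(dists > hull$tol) == 0L
    min(1, nvox / sum(inside))
  }

  # principal-axis eccentricity with intrinsic voxel moment
  coords <- which(inm, arr.ind = TRUE)
  xyz <- sweep(coords, 2L, sp, "*")
  cv <- if (nrow(xyz) > 1L) stats::cov(xyz) * (nrow(xyz) - 1) / nrow(xyz)
        else matrix(0, 3, 3)
  cv <- cv + diag(sp^2 / 12)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
  eccentricity <- sqrt(max(0, 1 - ev[1] / ev[3]))

  structure(list(
    volume_mm3 = vol,
    surface_area_mm2 = area,
    sphericity = sphericity,
    spherical_disproportionality = 1 / sphericity,
    convexity = convexity,
    eccentricity = eccentricity,
    surface_to_volume_ratio = area / vol
  ), class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, ...) {
  cat("<shape_summary>\n")
  for (nm in names(x)) cat(sprintf("  %-29s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

# Principal axis lengths (sqrt eigenvalues), exposed for tests.
principal_axis_lengths <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  coords <- which(mask$values != 0L, arr.ind = TRUE)
  xyz <- sweep(coords, 2L, mask$spacing_mm, "*")
  cv <- stats::cov(xyz) * (nrow(xyz) - 1) / nrow(xyz) +
    diag(mask$spacing_mm^2 / 12)
  sqrt(sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
            decreasing = TRUE))
}
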