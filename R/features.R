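# The 79-feature catalogue and the per-ROI extraction entry point.

SHAPE_FEATURE_NAMES <- c("shape_volume_mm3", "shape_sphericity",
                         "shape_spherical_disproportionality",
                         "shape_convexity", "shape_eccentricity",
                         "shape_surface_to_volume_ratio")

#' The radiomic feature catalogue
#'
#' The full set of 79 feature names computed by this package, split
#' 26 (GLCM) + 11 (GLRLM) + 11 (GLSZM) + 5 (NGTDM) + 6 (shape) + 20
#' (intensity / intensity-volume histogram). The GLCM list is the
#' Haralick-family set, GLRLM the Galloway/extended set, GLSZM the
#' Thibault set; beyond the handful of canonically named members each
#' family is completed from these standard lists. Note the shape summary
#' additionally exposes the raw surface area, which is not part of the
#' catalogue (it is redundant with the surface-to-volume ratio given the
#' volume).
#'
#' @param family optional subset: one of \code{"glcm"}, \code{"glrlm"},
#'   \code{"glszm"}, \code{"ngtdm"}, \code{"shape"}, \code{"ivh"}.
#' @return Character vector of feature names with a \code{family}
#'   attribute (a named factor-like character vector).
#' @examples
#' length(feature_catalogue())        # 79
#' table(attr(feature_catalogue(), "family"))
#' @export
feature_catalogue <- function(family = NULL) {
  probe <- local({
    # names are defined statically; build them without touching data
    glcm <- c("glcm_joint_maximum", "glcm_joint_average",
              "glcm_joint_variance", "glcm_entropy",
              "glcm_difference_average", "glcm_difference_variance",
              "glcm_difference_entropy", "glcm_sum_average",
              "glcm_sum_variance", "glcm_sum_entropy", "glcm_energy",
              "glcm_contrast", "glcm_dissimilarity", "glcm_id", "glcm_idn",
              "glcm_idm", "glcm_idmn", "glcm_inverse_variance",
              "glcm_correlation", "glcm_autocorrelation",
              "glcm_cluster_tendency", "glcm_cluster_shade",
              "glcm_cluster_prominence", "glcm_imc1", "glcm_imc2",
              "glcm_mcc")
    glrlm <- c("glrlm_sre", "glrlm_lre", "glrlm_glnu", "glrlm_rlnu",
               "glrlm_rpc", "glrlm_lgre", "glrlm_hgre", "glrlm_srlge",
               "glrlm_srhge", "glrlm_lrlge", "glrlm_lrhge")
    glszm <- c("glszm_sae", "glszm_lae", "glszm_iv", "glszm_szv",
               "glszm_zp", "glszm_lie", "glszm_hie", "glszm_lisae",
               "glszm_hisae", "glszm_lilae", "glszm_hilae")
    ngtdm <- c("ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
               "ngtdm_complexity", "ngtdm_strength")
    ivh <- c("ivh_mean", "ivh_sd", "ivh_min", "ivh_max", "ivh_median",
             "ivh_range", "ivh_skewness", "ivh_kurtosis", "ivh_energy",
             "ivh_intensity_entropy",
             paste0("ivh_v", IVH_CUTPOINTS), paste0("ivh_i", IVH_CUTPOINTS))
    list(glcm = glcm, glrlm = glrlm, glszm = glszm, ngtdm = ngtdm,
         shape = SHAPE_FEATURE_NAMES, ivh = ivh)
  })
  if (!is.null(family)) {
    family <- match.arg(family, names(probe))
    return(probe[[family]])
  }
  out <- unlist(probe, use.names = FALSE)
  attr(out, "family") <- rep(names(probe), lengths(probe))
  out
}

#' Extract all 79 radiomic features from one masked volume
#'
#' Runs the full extraction chain: fixed-bin-count discretization at
#' \code{Ng} levels, the four texture-matrix families, shape features
#' (which depend only on the mask) and the intensity/IVH features (raw
#' SUVs plus the level histogram for intensity entropy).
#'
#' @param volume an [suv_volume].
#' @param mask an [roi_mask] aligned with \code{volume}.
#' @param Ng gray-level count (default 64, the reference level).
#' @param directions direction matrix for GLCM/GLRLM.
#' @param connectivity GLSZM zone connectivity (26 or 6).
#' @param ngtdm_halfwidth NGTDM window halfwidths, default in-plane 7x7.
#' @return Named numeric vector of length 79, ordered as
#'   [feature_catalogue()].
#' @export
extract_all_features <- function(volume, mask, Ng = 64L,
                                 directions = direction_set_3d(),
                                 connectivity = 26,
                                 ngtdm_halfwidth = c(3L, 3L, 0L)) {
  d <- suppressWarnings(discretize_roi(volume, mask, Ng))
  vals <- c(
    glcm_features(build_glcm(d, directions)),
    glrlm_features(build_glrlm(d, directions)),
    glszm_features(build_glszm(d, connectivity)),
    ngtdm_features(build_ngtdm(d, ngtdm_halfwidth)),
    shape_feature_vector(mask),
    suppressWarnings(ivh_features(volume, mask, d))
  )
  catalogue <- feature_catalogue()
  stopifnot(identical(sort(names(vals)), sort(catalogue)))
  vals[catalogue]
}

shape_feature_vector <- function(mask) {
  s <- shape_features(mask)
  c(shape_volume_mm3 = s$volume_mm3,
    shape_sphericity = s$sphericity,
    shape_spherical_disproportionality = s$spherical_disproportionality,
    shape_convexity = s$convexity,
    shape_eccentricity = s$eccentricity,
    shape_surface_to_volume_ratio = s$surface_to_volume_ratio)
}
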