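# Synthetic phantom generator: tumor-like SUV volumes with tunable spatial
# heterogeneity, correlated segmentation-mask variants (emulating two manual
# observers and one semiautomatic method) and reconstruction-style image
# variants (emulating OSEM / FOREIR / FOREFBP / 3DRP by smoothing + noise).
# No scanner physics is modeled; these variants reproduce the statistical
# structure the reproducibility analysis assumes, not tomography.

RECON_LABELS <- c("OSEM", "FOREIR", "FOREFBP", "3DRP")
MASK_LABELS <- c("MTV1", "MTV2", "GBSV")

#' Phantom specification
#'
#' Parameters of one synthetic case. Defaults mirror a clinical PET grid
#' (5.49 x 5.49 mm pixels, 3.30 mm slices) and a cervical-tumor-like
#' uptake pattern: background SUV 1, tumor mean SUV 8 with a smooth
#' heterogeneity field of 8 mm correlation length and 1.5 SUV amplitude,
#' on a 64 x 64 x 48 grid.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_spacing_mm voxel size triple (mm).
#' @param tumor_radius_mm tumor radius (mm); the tumor is a sphere in
#'   world coordinates (an ellipsoid in voxel units).
#' @param suv_background background SUV (g/ml).
#' @param suv_tumor_mean mean tumor SUV; must exceed the background.
#' @param heterogeneity_scale_mm correlation length of the intratumoral
#'   texture field (Gaussian-smoothed white noise).
#' @param heterogeneity_amp SUV standard deviation of the texture field;
#'   0 gives a perfectly flat tumor.
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return A validated list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 48L),
                         voxel_spacing_mm = c(5.49, 5.49, 3.30),
                         tumor_radius_mm = 20,
                         suv_background = 1,
                         suv_tumor_mean = 8,
                         heterogeneity_scale_mm = 8,
                         heterogeneity_amp = 1.5,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_spacing_mm = as.numeric(voxel_spacing_mm),
               tumor_radius_mm = tumor_radius_mm,
               suv_background = suv_background,
               suv_tumor_mean = suv_tumor_mean,
               heterogeneity_scale_mm = heterogeneity_scale_mm,
               heterogeneity_amp = heterogeneity_amp,
               seed = as.integer(seed))
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 4L)) {
    stop("`grid_shape` must be three voxel counts >= 4", call. = FALSE)
  }
  if (length(spec$voxel_spacing_mm) != 3L || any(spec$voxel_spacing_mm <= 0)) {
    stop("`voxel_spacing_mm` must be three positive lengths", call. = FALSE)
  }
  if (spec$tumor_radius_mm <= 0) stop("`tumor_radius_mm` must be > 0",
                                      call. = FALSE)
  if (spec$suv_background < 0) stop("`suv_background` must be >= 0",
                                    call. = FALSE)
  if (spec$suv_tumor_mean <= spec$suv_background) {
    stop("`suv_tumor_mean` must exceed `suv_background`", call. = FALSE)
  }
  if (spec$heterogeneity_scale_mm <= 0) {
    stop("`heterogeneity_scale_mm` must be > 0", call. = FALSE)
  }
  if (spec$heterogeneity_amp < 0) {
    stop("`heterogeneity_amp` must be >= 0", call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

# Spherical (world-coordinate) tumor mask centered on the grid.
tumor_true_mask <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  ext <- d * sp
  if (any(2 * spec$tumor_radius_mm > ext)) {
    ax <- which(2 * spec$tumor_radius_mm > ext)[1]
    stop(sprintf(
      "tumor diameter %.4g mm exceeds grid extent %.4g mm along axis %d",
      2 * spec$tumor_radius_mm, ext[ax], ax), call. = FALSE)
  }
  ctr <- (d + 1) / 2 * sp
  x <- (seq_len(d[1]) * sp[1] - ctr[1])^2
  y <- (seq_len(d[2]) * sp[2] - ctr[2])^2
  z <- (seq_len(d[3]) * sp[3] - ctr[3])^2
  r2 <- outer(outer(x, y, "+"), z, "+")
  array(r2 <= spec$tumor_radius_mm^2, dim = d)
}

# Smooth unit-variance random field: white Gaussian noise convolved with a
# Gaussian kernel of width scale_mm, then standardized over the whole grid.
smooth_noise_field <- function(dims, spacing_mm, scale_mm) {
  w <- array(stats::rnorm(prod(dims)), dim = dims)
  f <- gauss_smooth(w, scale_mm / spacing_mm)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic tumor SUV volume
#'
#' Flat background plus a spherical tumor whose voxels carry the mean
#' tumor SUV plus a smooth heterogeneity field (Gaussian white noise
#' convolved to \code{heterogeneity_scale_mm}, rescaled to
#' \code{heterogeneity_amp} SUV standard deviation inside the tumor).
#' Values are clamped at 0. Deterministic in (spec, seed).
#'
#' @param spec a [phantom_spec()].
#' @return An [suv_volume] with attribute \code{true_mask} (an
#'   [roi_mask] of the exact tumor extent).
#' @export
generate_tumor_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tmask <- tumor_true_mask(spec)
  vals <- array(spec$suv_background, dim = spec$grid_shape)
  vals[tmask] <- spec$suv_tumor_mean
  if (spec$heterogeneity_amp > 0) {
    f <- with_seed(spec$seed, smooth_noise_field(
      spec$grid_shape, spec$voxel_spacing_mm, spec$heterogeneity_scale_mm))
    ft <- f[tmask]
    ft <- (ft - mean(ft)) / max(stats::sd(ft), 1e-12) * spec$heterogeneity_amp
    vals[tmask] <- vals[tmask] + ft
  }
  vals[vals < 0] <- 0
  vol <- suv_volume(vals, spec$voxel_spacing_mm)
  attr(vol, "true_mask") <- roi_mask(tmask, spec$voxel_spacing_mm,
                                     label = "TRUE")
  vol
}

#' Segmentation-mask variants by boundary jitter
#'
#' Emulates observer variation: the true mask's smoothed indicator field
#' (a monotone proxy of the signed distance near the boundary) is
#' perturbed by a smooth random field calibrated so the boundary shifts by
#' about the requested jitter magnitude (mm), then re-thresholded. Each
#' variant must reach the Dice floor against the true mask; otherwise the
#' jitter is halved and the variant regenerated (logged via
#' \code{message}), up to \code{max_retries} times.
#'
#' @param volume the case's [suv_volume] (geometry source).
#' @param true_mask the reference [roi_mask].
#' @param perturbation_mm named numeric vector of per-variant jitter
#'   magnitudes (mm); names become mask labels. Default emulates two
#'   manual observers and a semiautomatic method.
#' @param seed RNG seed.
#' @param dice_floor minimum Dice vs the true mask (default 0.75).
#' @param boundary_sigma_mm smoothing width of the indicator field.
#' @param max_retries jitter halvings before giving up.
#' @return Named list of [roi_mask] variants.
#' @export
make_mask_variants <- function(volume, true_mask,
                               perturbation_mm = c(MTV1 = 1.0, MTV2 = 2.0,
                                                   GBSV = 1.5),
                               seed = 1L, dice_floor = 0.75,
                               boundary_sigma_mm = 3,
                               max_retries = 6L) {
  stopifnot(inherits(volume, "suv_volume"), inherits(true_mask, "roi_mask"))
  check_geometry(volume, true_mask)
  check_nonempty(true_mask)
  if (is.null(names(perturbation_mm)) || any(names(perturbation_mm) == "")) {
    stop("`perturbation_mm` must be a named vector of jitter magnitudes",
         call. = FALSE)
  }
  sp <- true_mask$spacing_mm
  ind <- gauss_smooth(array(as.numeric(true_mask$values),
                            dim(true_mask$values)),
                      boundary_sigma_mm / sp)
  # gradient magnitude of the smoothed indicator at the 0.5 level: the
  # noise sd that shifts the boundary by `pert` mm is pert * |grad|,
  # with |grad| ~ 1/(sigma * sqrt(2*pi)) for a smoothed step
  grad_at_boundary <- 1 / (boundary_sigma_mm * sqrt(2 * pi))
  out <- vector("list", length(perturbation_mm))
  names(out) <- names(perturbation_mm)
  for (vi in seq_along(perturbation_mm)) {
    pert <- perturbation_mm[vi]
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      if (pert == 0) {
        cand <- roi_mask(true_mask$values, sp, label = names(out)[vi])
      } else {
        f <- with_seed(seed + 1000L * vi + attempt,
                       smooth_noise_field(dim(true_mask$values), sp,
                                          boundary_sigma_mm))
        noise_sd <- pert * grad_at_boundary
        cand_arr <- (ind + noise_sd * f) > 0.5
        cand <- roi_mask(cand_arr, sp, label = names(out)[vi])
      }
      if (sum(cand$values) > 0L && dice(cand, true_mask) >= dice_floor) {
        out[[vi]] <- cand
        break
      }
      if (attempt > max_retries) {
        stop("could not reach Dice floor ", dice_floor, " for variant ",
             names(out)[vi], " after ", max_retries, " retries",
             call. = FALSE)
      }
      pert <- pert / 2
      message("variant ", names(out)[vi], ": Dice below floor, reducing ",
              "jitter to ", signif(pert, 3), " mm (attempt ", attempt, ")")
    }
  }
  out
}

#' Default reconstruction-style variant profiles
#'
#' Four named smoothing/noise settings emulating reconstruction
#' differences: OSEM is the identity-like reference; the Fourier-rebinned
#' iterative variant adds mild smoothing and noise; the rebinned
#' filtered-back-projection variant more; the 3D-reprojection-like variant
#' carries the largest noise amplitude and is deliberately the most
#' divergent, mirroring its empirically lowest reproducibility.
#'
#' @return Named list of profiles with \code{fwhm_mm} and \code{noise_sd}
#'   (SUV).
#' @export
default_recon_profiles <- function() {
  list(
    OSEM    = list(fwhm_mm = 0, noise_sd = 0),
    FOREIR  = list(fwhm_mm = 4, noise_sd = 0.05),
    FOREFBP = list(fwhm_mm = 6, noise_sd = 0.10),
    `3DRP`  = list(fwhm_mm = 8, noise_sd = 0.20)
  )
}

#' Reconstruction-style image variants
#'
#' Each variant is the reference volume convolved with a profile-specific
#' Gaussian kernel (FWHM in mm) plus profile-specific additive Gaussian
#' noise, clamped at 0. Exactly four profiles are required and one must be
#' the identity-like \code{OSEM} reference.
#'
#' @param volume reference [suv_volume].
#' @param profiles named list of four profiles (see
#'   [default_recon_profiles()]).
#' @param seed RNG seed.
#' @return Named list of four [suv_volume]s.
#' @export
make_recon_variants <- function(volume, profiles = default_recon_profiles(),
                                seed = 1L) {
  stopifnot(inherits(volume, "suv_volume"))
  if (length(profiles) != 4L) {
    stop("exactly four reconstruction profiles required, got ",
         length(profiles), call. = FALSE)
  }
  if (!"OSEM" %in% names(profiles)) {
    stop("profiles must include the identity-like reference 'OSEM'",
         call. = FALSE)
  }
  sp <- volume$spacing_mm
  out <- vector("list", length(profiles))
  names(out) <- names(profiles)
  for (k in seq_along(profiles)) {
    pr <- profiles[[k]]
    vals <- volume$values
    if (pr$fwhm_mm > 0) {
      sigma_mm <- pr$fwhm_mm / (2 * sqrt(2 * log(2)))
      vals <- gauss_smooth(vals, sigma_mm / sp)
    }
    if (pr$noise_sd > 0) {
      noise <- with_seed(seed + 7000L * k,
                         array(stats::rnorm(length(vals), sd = pr$noise_sd),
                               dim = dim(vals)))
      vals <- vals + noise
    }
    vals[vals < 0] <- 0
    out[[k]] <- suv_volume(vals, sp, volume$origin)
  }
  out
}

#' Generate a full synthetic case bundle
#'
#' One case = base volume + four reconstruction-style variants + three
#' segmentation-mask variants, all on one grid, with every mask pair
#' meeting the Dice floor.
#'
#' @param spec a [phantom_spec()]; its \code{seed} drives all randomness.
#' @param dice_floor pairwise Dice floor for the mask variants.
#' @param perturbation_mm per-variant jitter magnitudes (mm).
#' @param profiles reconstruction profiles.
#' @return List of class \code{case_bundle}: \code{base_volume},
#'   \code{recon_variants}, \code{mask_variants}, \code{true_mask},
#'   \code{spec}.
#' @export
generate_case_bundle <- function(spec, dice_floor = 0.75,
                                 perturbation_mm = c(MTV1 = 1.0, MTV2 = 2.0,
                                                     GBSV = 1.5),
                                 profiles = default_recon_profiles()) {
  stopifnot(inherits(spec, "phantom_spec"))
  vol <- generate_tumor_volume(spec)
  tmask <- attr(vol, "true_mask")
  masks <- make_mask_variants(vol, tmask, perturbation_mm,
                              seed = spec$seed + 101L,
                              dice_floor = dice_floor)
  # enforce the pairwise floor too (variant-vs-variant), retrying with a
  # fresh jitter realization a few times
  tries <- 0L
  while (min_pairwise_dice(masks) < dice_floor && tries < 5L) {
    tries <- tries + 1L
    masks <- make_mask_variants(vol, tmask, perturbation_mm / 2^tries,
                                seed = spec$seed + 101L + tries,
                                dice_floor = dice_floor)
  }
  if (min_pairwise_dice(masks) < dice_floor) {
    stop("could not satisfy pairwise Dice floor ", dice_floor, call. = FALSE)
  }
  recons <- make_recon_variants(vol, profiles, seed = spec$seed + 501L)
  structure(list(base_volume = vol, recon_variants = recons,
                 mask_variants = masks, true_mask = tmask, spec = spec),
            class = "case_bundle")
}

min_pairwise_dice <- function(masks) {
  n <- length(masks)
  mins <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mins <- min(mins, dice(masks[[i]], masks[[j]]))
    }
  }
  mins
}

#' Write a cohort of case bundles to disk
#'
#' Emits per-case NIfTI volumes (base + recon variants) and uint8 NIfTI
#' masks plus a JSON manifest listing case ids, labels, file names and
#' seeds.
#'
#' @param out_dir destination directory (created if needed).
#' @param n_cases number of cases.
#' @param base_seed seed for case 1; case i uses \code{base_seed + i - 1}.
#' @param spec_template [phantom_spec()] whose seed is overridden per case.
#' @param ... passed to [generate_case_bundle()].
#' @return The manifest, invisibly.
#' @export
write_phantom_cohort <- function(out_dir, n_cases = 10L, base_seed = 1L,
                                 spec_template = phantom_spec(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(cases = list())
  for (i in seq_len(n_cases)) {
    spec <- spec_template
    spec$seed <- as.integer(base_seed + i - 1L)
    cb <- generate_case_bundle(spec, ...)
    cid <- sprintf("case%03d", i)
    files <- list()
    for (lab in names(cb$recon_variants)) {
      fn <- sprintf("%s_vol_%s.nii.gz", cid, lab)
      write_volume(cb$recon_variants[[lab]], file.path(out_dir, fn))
      files[[paste0("volume_", lab)]] <- fn
    }
    for (lab in names(cb$mask_variants)) {
      fn <- sprintf("%s_mask_%s.nii.gz", cid, lab)
      write_mask(cb$mask_variants[[lab]], file.path(out_dir, fn))
      files[[paste0("mask_", lab)]] <- fn
    }
    manifest$cases[[cid]] <- c(list(seed = spec$seed), files)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
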