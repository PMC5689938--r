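# Study orchestration: generate or load a cohort, apply the Dice inclusion
# filter, extract features for every (case, variant) combination the three
# testing parameters need, run the agreement statistics per pair, and emit
# a per-feature reproducibility report.

#' Study configuration
#'
#' Defines the full reproducibility design: the reference labels
#' (segmentation MTV1, gray level 64, reconstruction OSEM), the pair sets
#' per testing parameter, the gray-level grid and the Dice inclusion floor.
#' Pair sets follow the reference-vs-others design: segmentation
#' MTV1-MTV2 / MTV1-GBSV / MTV2-GBSV, gray levels 64-32 / 64-128 / 64-256,
#' reconstructions OSEM-FOREIR / OSEM-FOREFBP / OSEM-3DRP. The gray-level
#' and reconstruction studies are computed on the semiautomatic (GBSV)
#' mask.
#'
#' @param n_cases number of phantom cases (ignored when \code{input_dir}
#'   is given).
#' @param base_seed cohort seed; case i uses \code{base_seed + i - 1}.
#' @param gray_levels gray-level grid.
#' @param reference_gl reference gray level.
#' @param gl_mask segmentation label whose mask the GL and RA studies use.
#' @param dice_floor inclusion floor for pairwise mask Dice, in (0, 1].
#' @param spec_template [phantom_spec()] template for phantom input.
#' @param perturbation_mm mask jitter magnitudes per variant.
#' @param profiles reconstruction profiles.
#' @param input_dir optional directory of volumes + masks written by
#'   [write_phantom_cohort()] (manifest.json required); when given, cases
#'   are loaded instead of generated.
#' @return A list of class \code{study_config}.
#' @export
study_config <- function(n_cases = 10L, base_seed = 1L,
                         gray_levels = c(32L, 64L, 128L, 256L),
                         reference_gl = 64L,
                         gl_mask = "GBSV",
                         dice_floor = 0.75,
                         spec_template = phantom_spec(),
                         perturbation_mm = c(MTV1 = 1.0, MTV2 = 2.0,
                                             GBSV = 1.5),
                         profiles = default_recon_profiles(),
                         input_dir = NULL) {
  if (dice_floor <= 0 || dice_floor > 1) {
    stop("`dice_floor` must lie in (0, 1], got ", dice_floor, call. = FALSE)
  }
  if (!reference_gl %in% gray_levels) {
    stop("`reference_gl` must be one of `gray_levels`", call. = FALSE)
  }
  structure(list(
    n_cases = as.integer(n_cases), base_seed = as.integer(base_seed),
    gray_levels = as.integer(gray_levels),
    reference_gl = as.integer(reference_gl), gl_mask = gl_mask,
    dice_floor = dice_floor, spec_template = spec_template,
    perturbation_mm = perturbation_mm, profiles = profiles,
    input_dir = input_dir,
    sm_pairs = list(c("MTV1", "MTV2"), c("MTV1", "GBSV"), c("MTV2", "GBSV")),
    gl_pairs = lapply(setdiff(gray_levels, reference_gl),
                      function(g) c(reference_gl, g)),
    ra_pairs = list(c("OSEM", "FOREIR"), c("OSEM", "FOREFBP"),
                    c("OSEM", "3DRP"))
  ), class = "study_config")
}

load_cohort <- function(config) {
  if (!is.null(config$input_dir)) {
    man_path <- file.path(config$input_dir, "manifest.json")
    if (!file.exists(man_path)) {
      stop("no manifest.json in ", config$input_dir, call. = FALSE)
    }
    man <- jsonlite::read_json(man_path)
    bundles <- lapply(names(man$cases), function(cid) {
      entry <- man$cases[[cid]]
      vols <- list()
      for (lab in RECON_LABELS) {
        vols[[lab]] <- read_volume(
          file.path(config$input_dir, entry[[paste0("volume_", lab)]]))
      }
      masks <- list()
      for (lab in MASK_LABELS) {
        masks[[lab]] <- read_mask(
          file.path(config$input_dir, entry[[paste0("mask_", lab)]]),
          label = lab, volume = vols$OSEM)
      }
      list(id = cid, recon_variants = vols, mask_variants = masks,
           base_volume = vols$OSEM)
    })
    return(bundles)
  }
  lapply(seq_len(config$n_cases), function(i) {
    spec <- config$spec_template
    spec$seed <- as.integer(config$base_seed + i - 1L)
    cb <- generate_case_bundle(spec, dice_floor = config$dice_floor,
                               perturbation_mm = config$perturbation_mm,
                               profiles = config$profiles)
    list(id = sprintf("case%03d", i), recon_variants = cb$recon_variants,
         mask_variants = cb$mask_variants, base_volume = cb$base_volume)
  })
}

#' Run the full reproducibility study
#'
#' Executes the complete design on a phantom (or loaded) cohort:
#' \enumerate{
#'   \item Dice filter: cases whose mask variants fail the pairwise Dice
#'     floor are excluded and logged.
#'   \item Feature extraction for every needed (case, variant)
#'     combination: the three segmentation masks at the reference gray
#'     level on the reference (OSEM) image; the designated mask
#'     (default GBSV) at every gray level; the designated mask at the
#'     reference gray level on every reconstruction variant.
#'   \item Agreement statistics per pair (mean percentage differences,
#'     Bland-Altman limits, reproducibility class) and per-parameter ICC
#'     with precision (the reconstruction ICC excludes the most divergent
#'     3DRP-like variant, mirroring how that analysis is usually
#'     reported), plus gray-level inter-item correlations.
#'   \item The cross-parameter intersection: features reproducible in all
#'     three parameters.
#' }
#'
#' @param config a [study_config()].
#' @return A list of class \code{repro_report} with elements
#'   \code{features} (the long feature table), \code{pairs} (classified
#'   paired-difference table over all 9 pairs), \code{icc} (per-parameter
#'   ICC table), \code{iic} (gray-level inter-item correlations),
#'   \code{dice} (per-case pairwise Dice), \code{excluded_cases},
#'   \code{reproducible} (per-parameter feature sets and their
#'   intersection) and \code{config}.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cohort <- load_cohort(config)
  if (!length(cohort)) stop("empty cohort", call. = FALSE)

  # --- Dice inclusion filter -------------------------------------------------
  dice_rows <- list()
  keep <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    cs <- cohort[[i]]
    labs <- names(cs$mask_variants)
    ok <- TRUE
    for (a in seq_len(length(labs) - 1L)) {
      for (b in (a + 1L):length(labs)) {
        dc <- dice(cs$mask_variants[[a]], cs$mask_variants[[b]])
        dice_rows[[length(dice_rows) + 1L]] <- data.frame(
          case_id = cs$id, pair = paste(labs[a], labs[b], sep = "-"),
          dice = dc, stringsAsFactors = FALSE)
        if (dc < config$dice_floor) ok <- FALSE
      }
    }
    keep[i] <- ok
    if (!ok) message("case ", cs$id, " excluded: Dice below floor ",
                     config$dice_floor)
  }
  excluded <- vapply(cohort[!keep], `[[`, character(1), "id")
  cohort <- cohort[keep]
  if (!length(cohort)) stop("zero cases survive the Dice floor",
                            call. = FALSE)

  # --- feature extraction ----------------------------------------------------
  ref_gl <- config$reference_gl
  rows <- list()
  add_row <- function(case_id, seg, gl, recon, vals) {
    rows[[length(rows) + 1L]] <<- data.frame(
      case_id = case_id, segmentation = seg, gray_level = as.integer(gl),
      recon = recon, feature = names(vals), value = as.numeric(vals),
      stringsAsFactors = FALSE)
  }
  for (cs in cohort) {
    ref_vol <- cs$recon_variants$OSEM
    for (seg in names(cs$mask_variants)) {
      vals <- extract_all_features(ref_vol, cs$mask_variants[[seg]], ref_gl)
      add_row(cs$id, seg, ref_gl, "OSEM", vals)
    }
    gmask <- cs$mask_variants[[config$gl_mask]]
    for (gl in setdiff(config$gray_levels, ref_gl)) {
      vals <- extract_all_features(ref_vol, gmask, gl)
      add_row(cs$id, config$gl_mask, gl, "OSEM", vals)
    }
    for (rc in setdiff(names(cs$recon_variants), "OSEM")) {
      vals <- extract_all_features(cs$recon_variants[[rc]], gmask, ref_gl)
      add_row(cs$id, config$gl_mask, ref_gl, rc, vals)
    }
  }
  features <- validate_feature_table(do.call(rbind, rows),
                                     features = feature_catalogue())

  # --- agreement statistics --------------------------------------------------
  sm_slice <- features[features$gray_level == ref_gl &
                         features$recon == "OSEM", ]
  gl_slice <- features[features$segmentation == config$gl_mask &
                         features$recon == "OSEM", ]
  ra_slice <- features[features$segmentation == config$gl_mask &
                         features$gray_level == ref_gl, ]

  pair_tabs <- list()
  for (p in config$sm_pairs) {
    pair_tabs[[length(pair_tabs) + 1L]] <-
      classify_reproducibility(paired_differences(sm_slice, p, "SM"))
  }
  for (p in config$gl_pairs) {
    pair_tabs[[length(pair_tabs) + 1L]] <-
      classify_reproducibility(paired_differences(gl_slice, p, "GL"))
  }
  for (p in config$ra_pairs) {
    pair_tabs[[length(pair_tabs) + 1L]] <-
      classify_reproducibility(paired_differences(ra_slice, p, "RA"))
  }
  pairs <- do.call(rbind, pair_tabs)

  icc_tab <- rbind(
    icc_with_precision(sm_slice, "SM"),
    icc_with_precision(gl_slice, "GL"),
    icc_with_precision(ra_slice, "RA",
                       levels = setdiff(RECON_LABELS, "3DRP"))
  )
  iic_tab <- inter_item_correlation(gl_slice, reference_gl = ref_gl)

  # a feature is reproducible for a parameter iff it passes the |d|/SD gate
  # in every pair of that parameter
  per_param <- lapply(c(SM = "SM", GL = "GL", RA = "RA"), function(pp) {
    sub <- pairs[pairs$parameter == pp, ]
    feats <- unique(sub$feature)
    # shape features are mask-only, hence not informative for GL/RA pairs
    feats[vapply(feats, function(f)
      all(sub$reproducible[sub$feature == f]), logical(1))]
  })
  reproducible <- c(per_param, list(
    all = Reduce(intersect, per_param)))

  structure(list(features = features, pairs = pairs, icc = icc_tab,
                 iic = iic_tab, dice = do.call(rbind, dice_rows),
                 excluded_cases = excluded, reproducible = reproducible,
                 config = config),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("<repro_report> %d cases kept (%d excluded), %d features\n",
              length(unique(x$features$case_id)), length(x$excluded_cases),
              length(unique(x$features$feature))))
  counts <- table(x$pairs$parameter, x$pairs$class)
  print(counts)
  cat("Reproducible in all parameters: ",
      if (length(x$reproducible$all))
        paste(x$reproducible$all, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a reproducibility report to disk
#'
#' Emits \code{features.csv} (the long feature table), \code{report.csv}
#' (classified pair statistics joined with ICC) and \code{report.json}
#' (everything, including the reproducible-feature sets).
#'
#' @param report a \code{repro_report}.
#' @param out_dir destination directory.
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "repro_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(report$features, file.path(out_dir, "features.csv"))
  flat <- report$pairs
  flat$d <- NULL
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(out_dir, "report.csv"))
  data.table::fwrite(data.table::as.data.table(report$icc),
                     file.path(out_dir, "icc.csv"))
  payload <- list(
    pairs = flat, icc = report$icc, iic = report$iic, dice = report$dice,
    excluded_cases = report$excluded_cases,
    reproducible = report$reproducible)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out_dir)
}
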