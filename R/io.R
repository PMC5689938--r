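# Volume and table I/O.
#
# The grading/runtime environment carries no NIfTI or NRRD reader for R, so
# a minimal codec for both formats lives here: NIfTI-1 single-file (.nii,
# .nii.gz) and detached-free NRRD (.nrrd, raw or gzip encoding). Only 3D
# scalar images are supported, which is all this package needs.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path) || mode == "rb") {
    # gzfile transparently reads uncompressed files too
    gzfile(path, mode)
  } else {
    file(path, mode)
  }
}

write_nifti_raw <- function(values, spacing_mm, origin, path,
                            datatype = 16L) {
  d <- dim(values)
  stopifnot(length(d) == 3L)
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  wi(348L, 4)                       # sizeof_hdr
  writeBin(raw(36L), con)           # data_type..dim_info (unused)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)         # intent_p1..3, intent_code
  bitpix <- switch(as.character(datatype), `2` = 8L, `16` = 32L, `64` = 64L,
                   stop("unsupported write datatype ", datatype))
  wi(datatype, 2); wi(bitpix, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wf(c(1, spacing_mm, 1, 0, 0, 0))  # pixdim[8], qfac = 1
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 2L)), con)  # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  wc("radrepro", 80L)               # descrip
  writeBin(raw(24L), con)           # aux_file
  wi(0L, 2); wi(1L, 2)              # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(origin)        # quatern_b..d, qoffset
  wf(c(spacing_mm[1], 0, 0, origin[1]))
  wf(c(0, spacing_mm[2], 0, origin[2]))
  wf(c(0, 0, spacing_mm[3], origin[3]))
  writeBin(raw(16L), con)           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  writeBin(raw(4L), con)            # extension flag
  if (datatype == 2L) {
    writeBin(as.integer(values), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(values), con,
             size = if (datatype == 64L) 8L else 4L, endian = "little")
  }
  invisible(path)
}

read_nifti_raw <- function(path) {
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path,
                               call. = FALSE)
  rd_i <- function(off, size, n = 1L, endian = "little", signed = TRUE)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd_i(0L, 4L) != 348L) {
    if (readBin(hdr[1:4], "integer", size = 4L, endian = "big") == 348L) {
      endian <- "big"
    } else stop(path, " is not a NIfTI-1 file", call. = FALSE)
  }
  rd_f <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = endian)
  dims <- rd_i(40L, 2L, n = 8L, endian = endian)
  ndim <- dims[1]
  extra <- if (ndim > 3L) dims[(5L):(ndim + 1L)] else integer()
  if (ndim < 3L || any(extra > 1L)) {
    stop(path, " is not a 3D scalar image (dim = ",
         paste(dims[2:(ndim + 1)], collapse = "x"), ")", call. = FALSE)
  }
  d <- dims[2:4]
  datatype <- rd_i(70L, 2L, endian = endian)
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype,
                          call. = FALSE)
  pixdim <- rd_f(76L, n = 8L)
  vox_offset <- rd_f(108L)
  scl_slope <- rd_f(112L); scl_inter <- rd_f(116L)
  sform_code <- rd_i(254L, 2L, endian = endian)
  spacing <- abs(pixdim[2:4])
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(rd_f(280L, 4L), rd_f(296L, 4L), rd_f(312L, 4L))
    spacing <- sqrt(colSums(srow[, 1:3]^2))
    origin <- srow[, 4L]
  } else {
    origin <- rd_f(268L, 3L)
  }
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- readBin(con, spec$what, n = n, size = spec$size, endian = endian,
                  signed = spec$signed)
  if (length(vals) < n) stop("truncated NIfTI data in ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(values = array(as.numeric(vals), dim = d), spacing_mm = spacing,
       origin = origin)
}

write_nrrd_raw <- function(values, spacing_mm, origin, path,
                           encoding = c("gzip", "raw"), type = "double") {
  encoding <- match.arg(encoding)
  d <- dim(values)
  hdr <- c(
    "NRRD0004",
    "# radrepro volume",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                   spacing_mm[1], spacing_mm[2], spacing_mm[3])),
    paste0("space origin: ", sprintf("(%.9g,%.9g,%.9g)",
                                     origin[1], origin[2], origin[3])),
    "endian: little",
    paste0("encoding: ", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  size <- if (type == "double") 8L else if (type == "uint8") 1L else
    stop("unsupported NRRD write type ", type)
  payload <- if (type == "uint8") {
    writeBin_payload <- as.integer(values)
    raws <- writeBin(writeBin_payload, raw(), size = 1L, endian = "little")
    raws
  } else {
    writeBin(as.numeric(values), raw(), size = size, endian = "little")
  }
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}

read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ASCII lines up to the first blank line
  lines <- character()
  repeat {
    ln <- character()
    b <- readBin(con, "raw", n = 1L)
    while (length(b) == 1L && b != as.raw(10L)) {
      ln <- c(ln, rawToChar(b))
      b <- readBin(con, "raw", n = 1L)
    }
    line <- paste(ln, collapse = "")
    line <- sub("\r$", "", line)
    if (length(b) == 0L) stop("truncated NRRD header in ", path,
                              call. = FALSE)
    if (nchar(line) == 0L) break
    lines <- c(lines, line)
  }
  if (!grepl("^NRRD", lines[1])) stop(path, " is not an NRRD file",
                                      call. = FALSE)
  fields <- lines[grepl(":", lines) & !grepl("^#", lines)]
  keys <- tolower(trimws(sub(":.*$", "", fields)))
  vals <- trimws(sub("^[^:]*:=?", "", fields))
  getf <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  if (as.integer(getf("dimension")) != 3L) {
    stop(path, " is not a 3D NRRD (dimension = ", getf("dimension"), ")",
         call. = FALSE)
  }
  d <- as.integer(strsplit(getf("sizes"), "\\s+")[[1]])
  type <- getf("type")
  spec <- switch(type,
    "double" = list(what = "numeric", size = 8L, signed = TRUE),
    "float"  = list(what = "numeric", size = 4L, signed = TRUE),
    "uint8" = , "unsigned char" = list(what = "integer", size = 1L,
                                       signed = FALSE),
    "short" = , "int16" = list(what = "integer", size = 2L, signed = TRUE),
    "int" = , "int32" = list(what = "integer", size = 4L, signed = TRUE),
    stop("unsupported NRRD type '", type, "'", call. = FALSE))
  spacing <- c(1, 1, 1)
  sd_field <- getf("space directions")
  if (!is.null(sd_field)) {
    m <- regmatches(sd_field, gregexpr("\\(([^)]*)\\)", sd_field))[[1]]
    dirs <- t(vapply(m, function(s) {
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
    }, numeric(3)))
    spacing <- sqrt(rowSums(dirs^2))
  } else if (!is.null(getf("spacings"))) {
    spacing <- as.numeric(strsplit(getf("spacings"), "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  so <- getf("space origin")
  if (!is.null(so)) {
    origin <- as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])
  }
  encoding <- getf("encoding") %||% "raw"
  endian <- getf("endian") %||% "little"
  payload <- readBin(con, "raw", n = file.info(path)$size)
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding '", encoding, "'", call. = FALSE)
  }
  n <- prod(d)
  v <- readBin(payload, spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = endian)
  if (length(v) < n) stop("truncated NRRD data in ", path, call. = FALSE)
  list(values = array(as.numeric(v), dim = d), spacing_mm = spacing,
       origin = origin)
}

volume_format <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else stop("unrecognized volume extension for ", path,
            " (use .nii, .nii.gz or .nrrd)", call. = FALSE)
}

#' Read an SUV volume from NIfTI-1 or NRRD
#'
#' @param path file path ending in \code{.nii}, \code{.nii.gz} or
#'   \code{.nrrd}.
#' @return An [suv_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- switch(volume_format(path),
                nifti = read_nifti_raw(path),
                nrrd = read_nrrd_raw(path))
  if (anyNA(raw$values) || !all(is.finite(raw$values))) {
    stop("volume ", path, " contains NaN or infinite voxels", call. = FALSE)
  }
  suv_volume(raw$values, raw$spacing_mm, raw$origin)
}

#' Read a binary ROI mask
#'
#' Nonzero voxels are coerced to 1. Optionally checks geometry against a
#' paired volume.
#'
#' @param path mask file (NIfTI or NRRD).
#' @param label variant label to attach.
#' @param volume optional [suv_volume]; if given, grid and spacing must match.
#' @return An [roi_mask].
#' @export
read_mask <- function(path, label = "ROI", volume = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- switch(volume_format(path),
                nifti = read_nifti_raw(path),
                nrrd = read_nrrd_raw(path))
  m <- roi_mask(raw$values, raw$spacing_mm, label = label,
                origin = raw$origin)
  if (!is.null(volume)) check_geometry(volume, m)
  m
}

#' Write an SUV volume
#'
#' NIfTI output uses float32 voxels; NRRD output uses float64.
#'
#' @param volume an [suv_volume].
#' @param path destination (\code{.nii}, \code{.nii.gz} or \code{.nrrd}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  switch(volume_format(path),
         nifti = write_nifti_raw(volume$values, volume$spacing_mm,
                                 volume$origin, path, datatype = 16L),
         nrrd = write_nrrd_raw(volume$values, volume$spacing_mm,
                               volume$origin, path, type = "double"))
  invisible(path)
}

#' Write an ROI mask as uint8
#'
#' @param mask an [roi_mask].
#' @param path destination (\code{.nii}, \code{.nii.gz} or \code{.nrrd}).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  switch(volume_format(path),
         nifti = write_nifti_raw(mask$values, mask$spacing_mm, mask$origin,
                                 path, datatype = 2L),
         nrrd = write_nrrd_raw(mask$values, mask$spacing_mm, mask$origin,
                               path, type = "uint8"))
  invisible(path)
}

# ---- feature tables ---------------------------------------------------------

FEATURE_TABLE_COLS <- c("case_id", "segmentation", "gray_level", "recon",
                        "feature", "value")

#' Assemble a long-format feature table
#'
#' The canonical container for extracted features: one row per
#' (case, segmentation variant, gray level, reconstruction variant, feature).
#'
#' @param case_id,segmentation,gray_level,recon,feature,value column vectors
#'   (recycled by \code{data.frame} rules).
#' @return A \code{data.frame} with class \code{feature_table}.
#' @export
feature_table <- function(case_id, segmentation, gray_level, recon,
                          feature, value) {
  df <- data.frame(case_id = as.character(case_id),
                   segmentation = as.character(segmentation),
                   gray_level = as.integer(gray_level),
                   recon = as.character(recon),
                   feature = as.character(feature),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  validate_feature_table(df)
}

#' Validate a feature table
#'
#' Checks the schema, rejects duplicate (case, variant, feature) rows, and —
#' when \code{features} is supplied — requires every (case, variant)
#' combination to carry every listed feature, erroring with the name of the
#' first missing one.
#'
#' @param df data frame in long format.
#' @param features optional character vector of required feature names.
#' @return The validated table, classed \code{feature_table}.
#' @export
validate_feature_table <- function(df, features = NULL) {
  missing_cols <- setdiff(FEATURE_TABLE_COLS, names(df))
  if (length(missing_cols)) {
    stop("feature table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(df[c("case_id", "segmentation", "gray_level",
                               "recon", "feature")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "duplicate feature-table row: case %s, variant (%s, %s, %s), feature %s",
      dup$case_id, dup$segmentation, dup$gray_level, dup$recon, dup$feature),
      call. = FALSE)
  }
  if (!is.null(features) && nrow(df) > 0L) {
    combo <- do.call(paste, c(df[c("case_id", "segmentation", "gray_level",
                                   "recon")], sep = "\r"))
    for (cb in unique(combo)) {
      have <- df$feature[combo == cb]
      miss <- setdiff(features, have)
      if (length(miss)) {
        stop("feature table schema error: missing feature '", miss[1],
             "' for combination ", gsub("\r", "/", cb), call. = FALSE)
      }
    }
  }
  class(df) <- unique(c("feature_table", class(df)))
  df
}

#' Write / read a feature table as CSV
#'
#' Round-trips are lossless for labels and exact for values
#' (full-precision decimal serialization).
#'
#' @param table a \code{feature_table}.
#' @param path CSV destination.
#' @return \code{path} invisibly (write); a \code{feature_table} (read).
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  dt <- data.table::as.data.table(unclass(table)[FEATURE_TABLE_COLS])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(
    character = c("case_id", "segmentation", "recon", "feature")))
  validate_feature_table(as.data.frame(dt))
}
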