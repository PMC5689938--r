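# Gray-level size-zone matrix (GLSZM) and its 11 Thibault-family features.

#' Build a size-zone matrix
#'
#' Zones are connected components of equal-level in-mask voxels under
#' 26-connectivity in 3D (the package convention for 3D clusters;
#' 6-connectivity is available via \code{connectivity = 6}). The matrix is
#' indexed (gray level, zone size), with columns capped at the largest
#' observed zone.
#'
#' @param d a \code{discretized_roi}.
#' @param connectivity 26 (default) or 6.
#' @return Integer matrix of class \code{glszm} with attribute
#'   \code{n_voxels}.
#' @export
build_glszm <- function(d, connectivity = 26) {
  stopifnot(inherits(d, "discretized_roi"))
  check_nonempty_levels(d)
  if (!connectivity %in% c(6, 26)) {
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  }
  offsets <- if (connectivity == 26) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  }
  dims <- dim(d$levels)
  nxy <- dims[1] * dims[2]
  lin_off <- offsets[, 1] + offsets[, 2] * dims[1] + offsets[, 3] * nxy
  # pad-free bounds handling: precompute coordinates for candidate voxels
  visited <- array(FALSE, dim = dims)
  zones_level <- integer(0)
  zones_size <- integer(0)
  seeds <- which(d$mask)
  lev_arr <- d$levels
  for (s in seeds) {
    if (visited[s]) next
    level <- lev_arr[s]
    visited[s] <- TRUE
    frontier <- s
    size <- 1L
    while (length(frontier)) {
      cand <- rep(frontier, each = nrow(offsets)) +
        rep(lin_off, times = length(frontier))
      # reject candidates that wrapped around an axis
      cc <- arrayInd(rep(frontier, each = nrow(offsets)), dims)
      nb <- cc + offsets[rep(seq_len(nrow(offsets)), length(frontier)), ,
                         drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
            nb[, 2] >= 1L & nb[, 2] <= dims[2] &
            nb[, 3] >= 1L & nb[, 3] <= dims[3]
      cand <- unique(cand[ok])
      cand <- cand[!visited[cand] & !is.na(lev_arr[cand]) &
                     lev_arr[cand] == level]
      visited[cand] <- TRUE
      size <- size + length(cand)
      frontier <- cand
    }
    zones_level <- c(zones_level, level)
    zones_size <- c(zones_size, size)
  }
  Ng <- d$Ng
  smax <- max(zones_size)
  counts <- matrix(tabulate((zones_size - 1L) * Ng + zones_level,
                            nbins = Ng * smax), Ng, smax)
  structure(counts, class = c("glszm", "matrix"), n_voxels = sum(d$mask))
}

#' Compute the 11 GLSZM features
#'
#' Small/large area emphasis (SAE, LAE), intensity variability (IV, the
#' gray-level non-uniformity of zones), size-zone variability (SZV), zone
#' percentage (ZP), low/high intensity emphasis (LIE, HIE) and the four
#' joint emphases (LISAE, HISAE, LILAE, HILAE).
#'
#' @param glszm matrix from [build_glszm()].
#' @return Named numeric vector of length 11.
#' @export
glszm_features <- function(glszm) {
  m <- unclass(glszm)
  n_vox <- attr(glszm, "n_voxels")
  if (is.null(n_vox)) {
    stop("`glszm` must come from build_glszm() (missing n_voxels)",
         call. = FALSE)
  }
  nz <- sum(m)
  lvl <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  sz <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  c(
    glszm_sae   = sum(m / sz^2) / nz,
    glszm_lae   = sum(m * sz^2) / nz,
    glszm_iv    = sum(rowSums(m)^2) / nz,
    glszm_szv   = sum(colSums(m)^2) / nz,
    glszm_zp    = nz / n_vox,
    glszm_lie   = sum(m / lvl^2) / nz,
    glszm_hie   = sum(m * lvl^2) / nz,
    glszm_lisae = sum(m / (lvl^2 * sz^2)) / nz,
    glszm_hisae = sum(m * lvl^2 / sz^2) / nz,
    glszm_lilae = sum(m * sz^2 / lvl^2) / nz,
    glszm_hilae = sum(m * lvl^2 * sz^2) / nz
  )
}
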