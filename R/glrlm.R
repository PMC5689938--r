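# Gray-level run-length matrix (GLRLM) and its 11 Galloway-family features.

#' Build a run-length matrix pooled over directions
#'
#' A run is a maximal set of consecutive in-mask voxels sharing one gray
#' level along a linear direction; runs break at mask boundaries. Runs are
#' collected for every direction and summed into one \code{Ng x Rmax}
#' count matrix (columns = run length, capped at the observed maximum).
#'
#' @param d a \code{discretized_roi}.
#' @param directions direction matrix, default the 13 unique 3D offsets.
#' @return Integer matrix of class \code{glrlm} with attributes
#'   \code{n_voxels} (in-mask voxels) and \code{n_directions}.
#' @export
build_glrlm <- function(d, directions = direction_set_3d()) {
  stopifnot(inherits(d, "discretized_roi"))
  check_nonempty_levels(d)
  directions <- check_directions(directions)
  Ng <- d$Ng
  dims <- dim(d$levels)
  coords <- which(d$mask, arr.ind = TRUE)
  lev <- d$levels[d$mask]
  n_vox <- nrow(coords)
  runs_level <- integer(0)
  runs_len <- integer(0)
  big <- 4L * max(dims) + 4L
  for (r in seq_len(nrow(directions))) {
    off <- directions[r, ]
    ax <- which(off != 0L)[1]
    t_pos <- coords[, ax] * off[ax]
    base <- coords - outer(t_pos, off)
    key <- ((base[, 1] + big) * big + (base[, 2] + big)) * big +
      (base[, 3] + big)
    o <- order(key, t_pos)
    k_o <- key[o]; t_o <- t_pos[o]; l_o <- lev[o]
    n <- length(o)
    if (n == 1L) {
      runs_level <- c(runs_level, l_o)
      runs_len <- c(runs_len, 1L)
      next
    }
    brk <- c(TRUE, k_o[-1] != k_o[-n] | t_o[-1] != t_o[-n] + 1L |
               l_o[-1] != l_o[-n])
    starts <- which(brk)
    lens <- diff(c(starts, n + 1L))
    runs_level <- c(runs_level, l_o[starts])
    runs_len <- c(runs_len, lens)
  }
  rmax <- max(runs_len)
  counts <- matrix(tabulate((runs_len - 1L) * Ng + runs_level,
                            nbins = Ng * rmax), Ng, rmax)
  structure(counts, class = c("glrlm", "matrix"), n_voxels = n_vox,
            n_directions = nrow(directions))
}

#' Compute the 11 GLRLM features
#'
#' Short/long run emphasis (SRE, LRE), gray-level and run-length
#' non-uniformity (GLNU, RLNU), run percentage (RPC, runs per voxel pooled
#' over the direction count), low/high gray-level run emphasis (LGRE,
#' HGRE) and the four joint emphases (SRLGE, SRHGE, LRLGE, LRHGE).
#' Gray-level weights use bin indices.
#'
#' @param glrlm matrix from [build_glrlm()].
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(glrlm) {
  m <- unclass(glrlm)
  n_vox <- attr(glrlm, "n_voxels")
  n_dir <- attr(glrlm, "n_directions")
  if (is.null(n_vox) || is.null(n_dir)) {
    stop("`glrlm` must come from build_glrlm() (missing attributes)",
         call. = FALSE)
  }
  nr <- sum(m)
  lvl <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  len <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  c(
    glrlm_sre   = sum(m / len^2) / nr,
    glrlm_lre   = sum(m * len^2) / nr,
    glrlm_glnu  = sum(rowSums(m)^2) / nr,
    glrlm_rlnu  = sum(colSums(m)^2) / nr,
    glrlm_rpc   = nr / (n_dir * n_vox),
    glrlm_lgre  = sum(m / lvl^2) / nr,
    glrlm_hgre  = sum(m * lvl^2) / nr,
    glrlm_srlge = sum(m / (lvl^2 * len^2)) / nr,
    glrlm_srhge = sum(m * lvl^2 / len^2) / nr,
    glrlm_lrlge = sum(m * len^2 / lvl^2) / nr,
    glrlm_lrhge = sum(m * lvl^2 * len^2) / nr
  )
}

check_nonempty_levels <- function(d) {
  if (sum(d$mask) < 1L) stop("empty ROI: no in-mask voxels", call. = FALSE)
  invisible(TRUE)
}
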