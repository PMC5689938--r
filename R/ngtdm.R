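# Neighborhood gray-tone difference matrix (NGTDM): coarseness, contrast,
# complexity, busyness and texture strength (Amadasun-King), adapted to
# irregular multi-slice ROIs by averaging over in-mask neighbors only.

#' Build the NGTDM accumulators
#'
#' For every in-mask voxel the mean gray level of its in-mask neighbors in
#' a 7x7 in-plane window (center excluded) is computed; voxels with no
#' in-mask neighbor are skipped. Per level \eqn{i} the occurrence count
#' \eqn{n_i} and the summed absolute deviation
#' \eqn{s_i = \sum |i - \bar A|} are accumulated.
#'
#' The window is 2D in-plane by default (halfwidths \code{c(3, 3, 0)});
#' pass e.g. \code{c(3, 3, 1)} for a 3D window.
#'
#' @param d a \code{discretized_roi}.
#' @param window_halfwidth integer triple of window halfwidths per axis.
#' @return List of class \code{ngtdm} with \code{n_i}, \code{s_i}
#'   (length-\code{Ng} vectors), \code{n_valid} (voxels scored) and
#'   \code{Ng}.
#' @export
build_ngtdm <- function(d, window_halfwidth = c(3L, 3L, 0L)) {
  stopifnot(inherits(d, "discretized_roi"))
  check_nonempty_levels(d)
  hw <- as.integer(window_halfwidth)
  if (length(hw) != 3L || any(hw < 0L) || all(hw == 0L)) {
    stop("`window_halfwidth` must be three non-negative integers, not all 0",
         call. = FALSE)
  }
  offs <- as.matrix(expand.grid(x = -hw[1]:hw[1], y = -hw[2]:hw[2],
                                z = -hw[3]:hw[3]))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]  # exclude center
  mask_num <- array(as.numeric(d$mask), dim = dim(d$levels))
  lev0 <- d$levels
  lev0[!d$mask] <- 0L
  lev_num <- array(as.numeric(lev0), dim = dim(d$levels))
  nb_sum <- array(0, dim = dim(d$levels))
  nb_cnt <- array(0, dim = dim(d$levels))
  for (r in seq_len(nrow(offs))) {
    nb_sum <- nb_sum + shift_array_zero(lev_num, offs[r, ])
    nb_cnt <- nb_cnt + shift_array_zero(mask_num, offs[r, ])
  }
  valid <- d$mask & nb_cnt > 0
  if (!any(valid)) {
    stop("no voxel has an in-mask neighbor within the NGTDM window",
         call. = FALSE)
  }
  avg <- nb_sum[valid] / nb_cnt[valid]
  lv <- d$levels[valid]
  dev <- abs(lv - avg)
  Ng <- d$Ng
  n_i <- tabulate(lv, nbins = Ng)
  s_i <- vapply(seq_len(Ng), function(k) sum(dev[lv == k]), numeric(1))
  structure(list(n_i = n_i, s_i = s_i, n_valid = sum(valid), Ng = Ng),
            class = "ngtdm")
}

#' Compute the 5 NGTDM features
#'
#' Amadasun-King coarseness, contrast, complexity, busyness and texture
#' strength, with an \code{eps = 1e-12} guard on vanishing denominators:
#' a perfectly flat ROI has zero summed deviation, so coarseness saturates
#' at the finite sentinel \code{1/eps}.
#'
#' @param ngtdm from [build_ngtdm()].
#' @param eps denominator guard.
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(ngtdm, eps = 1e-12) {
  stopifnot(inherits(ngtdm, "ngtdm"))
  n_i <- ngtdm$n_i
  s_i <- ngtdm$s_i
  nv <- ngtdm$n_valid
  p_i <- n_i / nv
  act <- which(p_i > 0)
  ngp <- length(act)
  lv <- act
  pv <- p_i[act]
  sv <- s_i[act]

  coarseness <- 1 / (sum(pv * sv) + eps)

  contrast <- if (ngp > 1L) {
    pij <- outer(pv, pv)
    dij2 <- outer(lv, lv, function(a, b) (a - b)^2)
    (sum(pij * dij2) / (ngp * (ngp - 1))) * (sum(sv) / nv)
  } else 0

  busyness <- if (ngp > 1L) {
    denom <- sum(abs(outer(lv * pv, lv * pv, "-")))
    if (denom > eps) sum(pv * sv) / denom else 0
  } else 0

  complexity <- if (ngp > 1L) {
    num <- outer(seq_along(lv), seq_along(lv), Vectorize(function(a, b) {
      abs(lv[a] - lv[b]) * (pv[a] * sv[a] + pv[b] * sv[b]) /
        (pv[a] + pv[b])
    }))
    sum(num) / nv
  } else 0

  strength <- if (ngp > 1L) {
    pij_sum <- outer(pv, pv, "+")
    dij2 <- outer(lv, lv, function(a, b) (a - b)^2)
    sum(pij_sum * dij2) / (eps + sum(sv))
  } else 0

  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}
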