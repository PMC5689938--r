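# Gray-level co-occurrence matrix (GLCM) and its 26 second-order features.

#' Build a pooled symmetric GLCM
#'
#' Counts co-occurrences of gray levels between voxel pairs at one-voxel
#' displacement along the 13 unique 3D directions, pooled into a single
#' symmetric matrix (both orientations of every offset) and normalized to
#' probabilities. Pairs with either member outside the mask are skipped.
#'
#' Pooling over directions (rather than averaging 13 per-direction feature
#' sets) is the package convention; pass a single-row \code{directions}
#' matrix to work per-direction.
#'
#' @param d a \code{discretized_roi}.
#' @param directions integer matrix of displacement vectors, one per row;
#'   default [direction_set_3d()].
#' @return An \code{Ng x Ng} probability matrix of class \code{glcm}
#'   (entries sum to 1) with attribute \code{n_pairs}.
#' @export
build_glcm <- function(d, directions = direction_set_3d()) {
  stopifnot(inherits(d, "discretized_roi"))
  directions <- check_directions(directions)
  Ng <- d$Ng
  dims <- dim(d$levels)
  coords <- which(d$mask, arr.ind = TRUE)
  lev_self <- d$levels[d$mask]
  counts <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(directions))) {
    off <- directions[r, ]
    nb <- sweep(coords, 2L, off, "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    inm <- d$mask[lin]
    if (!any(inm)) next
    i <- lev_self[ok][inm]
    j <- d$levels[lin[inm]]
    tab <- tabulate((j - 1L) * Ng + i, nbins = Ng * Ng)
    counts <- counts + matrix(tab, Ng, Ng)
  }
  counts <- counts + t(counts)   # both orientations -> symmetric
  n_pairs <- sum(counts)
  if (n_pairs == 0) {
    stop("no valid voxel pairs (single-voxel or fully isolated ROI): ",
         "GLCM features are undefined for this ROI", call. = FALSE)
  }
  p <- counts / n_pairs
  structure(p, class = c("glcm", "matrix"), n_pairs = n_pairs)
}

#' Compute the 26 GLCM features
#'
#' The Haralick-family catalogue evaluated on a normalized symmetric GLCM:
#' joint maximum/average/variance/entropy, the difference- and sum-histogram
#' statistics (average, variance, entropy), angular second moment (energy),
#' contrast, dissimilarity, inverse difference (ID) and its normalized form,
#' inverse difference moment (IDM) and its normalized form, inverse
#' variance, correlation, autocorrelation, cluster tendency/shade/prominence,
#' the two information measures of correlation (IMC1, IMC2) and the maximal
#' correlation coefficient. Gray-level weights use the bin indices
#' \code{1..Ng}. Entropies are in bits.
#'
#' Degenerate single-level matrices give ID = IDM = 1 (their analytic
#' maximum), zero entropies, and correlation-type features fixed at their
#' perfect-agreement value 1.
#'
#' @param glcm a normalized \code{glcm} matrix from [build_glcm()].
#' @return Named numeric vector of length 26.
#' @export
glcm_features <- function(glcm) {
  p <- unclass(glcm)
  if (!is.matrix(p) || nrow(p) != ncol(p)) {
    stop("`glcm` must be a square matrix", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop("GLCM is not normalized (entries must sum to 1); use build_glcm()",
         call. = FALSE)
  }
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p)               # == colSums(p) for a symmetric matrix
  py <- colSums(p)
  mu_x <- sum(seq_len(Ng) * px)
  mu_y <- sum(seq_len(Ng) * py)
  var_x <- sum((seq_len(Ng) - mu_x)^2 * px)
  var_y <- sum((seq_len(Ng) - mu_y)^2 * py)

  # difference histogram p_{|i-j|}, k = 0..Ng-1
  dk <- abs(i - j)
  p_diff <- vapply(0:(Ng - 1L), function(k) sum(p[dk == k]), numeric(1))
  kd <- 0:(Ng - 1L)
  diff_avg <- sum(kd * p_diff)
  # sum histogram p_{i+j}, k = 2..2Ng
  sk <- i + j
  p_sum <- vapply(2:(2L * Ng), function(k) sum(p[sk == k]), numeric(1))
  ks <- 2:(2L * Ng)
  sum_avg <- sum(ks * p_sum)

  hxy <- -sum(xlog2x(p))
  hx <- -sum(xlog2x(px))
  hy <- -sum(xlog2x(py))
  pxpy <- outer(px, py)
  lg <- matrix(0, Ng, Ng)
  pos <- pxpy > 0
  lg[pos] <- log2(pxpy[pos])
  hxy1 <- -sum(p[pos] * lg[pos])
  hxy2 <- -sum(pxpy[pos] * lg[pos])

  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))

  corr <- if (var_x > 0 && var_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / sqrt(var_x * var_y)
  } else 1  # single-level ROI: perfect agreement by convention

  mcc <- glcm_mcc(p, px, py)

  c(
    glcm_joint_maximum       = max(p),
    glcm_joint_average       = mu_x,
    glcm_joint_variance      = sum((i - mu_x)^2 * p),
    glcm_entropy             = hxy,
    glcm_difference_average  = diff_avg,
    glcm_difference_variance = sum((kd - diff_avg)^2 * p_diff),
    glcm_difference_entropy  = -sum(xlog2x(p_diff)),
    glcm_sum_average         = sum_avg,
    glcm_sum_variance        = sum((ks - sum_avg)^2 * p_sum),
    glcm_sum_entropy         = -sum(xlog2x(p_sum)),
    glcm_energy              = sum(p^2),
    glcm_contrast            = sum((i - j)^2 * p),
    glcm_dissimilarity       = sum(abs(i - j) * p),
    glcm_id                  = sum(p / (1 + abs(i - j))),
    glcm_idn                 = sum(p / (1 + abs(i - j) / Ng)),
    glcm_idm                 = sum(p / (1 + (i - j)^2)),
    glcm_idmn                = sum(p / (1 + (i - j)^2 / Ng^2)),
    glcm_inverse_variance    = sum(p[i != j] / (i - j)[i != j]^2),
    glcm_correlation         = corr,
    glcm_autocorrelation     = sum(i * j * p),
    glcm_cluster_tendency    = sum((i + j - mu_x - mu_y)^2 * p),
    glcm_cluster_shade       = sum((i + j - mu_x - mu_y)^3 * p),
    glcm_cluster_prominence  = sum((i + j - mu_x - mu_y)^4 * p),
    glcm_imc1                = imc1,
    glcm_imc2                = imc2,
    glcm_mcc                 = mcc
  )
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), restricted to occupied
# levels. Single-level matrices return 1 (perfect agreement).
glcm_mcc <- function(p, px, py) {
  keep <- px > 0
  if (sum(keep) < 2L) return(1)
  ps <- p[keep, keep, drop = FALSE]
  pxs <- px[keep]
  pys <- py[keep]
  r1 <- ps / pxs                      # rowwise divide
  m <- sweep(ps, 2L, pys, "/")        # columnwise divide
  q <- r1 %*% t(m)
  ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(0, min(ev[2], 1)))
}
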