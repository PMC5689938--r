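# Agreement statistics: Dice overlap, mean percentage differences with
# Bland-Altman reproducibility limits, the High/Intermediate/Low/NR
# classification, ICC with confidence-interval precision, and inter-item
# correlations across gray levels.

PARAMETER_COLUMNS <- c(SM = "segmentation", GL = "gray_level", RA = "recon")

#' Dice similarity coefficient of two masks
#'
#' \eqn{DC = 2|A \cap B| / (|A| + |B|)}, the overlap agreement between two
#' segmentations of the same grid.
#'
#' @param a,b [roi_mask] objects on identical geometry.
#' @return Scalar in \[0, 1\].
#' @examples
#' m <- roi_mask(array(c(1, 1, 0, 0), c(4, 1, 1)), c(1, 1, 1))
#' dice(m, m)  # 1
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  check_geometry(a, b, what = "mask pair")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) {
    stop("Dice undefined: both masks are empty", call. = FALSE)
  }
  2 * sum(a$values & b$values) / (na + nb)
}

#' Per-feature paired percentage differences and Bland-Altman limits
#'
#' For each feature, computes the per-case signed percentage difference
#' \deqn{d_i = \frac{f_m - f_n}{(f_m + f_n)/2} \times 100}
#' between the two variant labels of one testing parameter, then the
#' absolute mean difference \eqn{|\bar d|}, the SD of the signed
#' differences, and the upper/lower reproducibility limits
#' \eqn{URL = \bar d + 1.96\,SD}, \eqn{LRL = \bar d - 1.96\,SD}.
#'
#' \eqn{|\bar d|} is the absolute value of the mean \emph{signed}
#' difference (not the mean of absolute differences); the Bland-Altman
#' limits require the signed mean, so the signed-first reading of the
#' formula is used throughout. A case with \eqn{f_m = f_n = 0} is perfect
#' agreement and scores \eqn{d = 0}; a case with \eqn{f_m = -f_n \ne 0}
#' has a genuinely undefined denominator and is excluded per feature, with
#' the count reported in \code{n_excluded} and a message.
#'
#' @param table a \code{feature_table} already restricted to the study
#'   slice of interest (one value per case for each pair member).
#' @param pair character (or numeric for GL) vector of two variant labels,
#'   order \code{c(m, n)}.
#' @param parameter which variant column the pair refers to: \code{"SM"}
#'   (segmentation), \code{"GL"} (gray level) or \code{"RA"} (recon).
#' @return A data frame with one row per feature: \code{feature},
#'   \code{pair_label}, \code{n_cases}, \code{n_excluded}, \code{d_mean}
#'   (signed \%), \code{d_mean_abs}, \code{sd}, \code{lrl}, \code{url};
#'   per-case differences are kept in the list column \code{d}.
#' @export
paired_differences <- function(table, pair,
                               parameter = c("SM", "GL", "RA")) {
  parameter <- match.arg(parameter)
  col <- PARAMETER_COLUMNS[[parameter]]
  table <- validate_feature_table(as.data.frame(table))
  if (length(pair) != 2L) stop("`pair` must have exactly two labels",
                               call. = FALSE)
  pair <- as.character(pair)
  sub <- table[as.character(table[[col]]) %in% pair, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no rows match pair (", paste(pair, collapse = ", "), ") in column ",
         col, call. = FALSE)
  }
  pair_label <- paste(pair, collapse = "-")
  feats <- unique(sub$feature)
  out <- vector("list", length(feats))
  for (fi in seq_along(feats)) {
    fs <- sub[sub$feature == feats[fi], , drop = FALSE]
    wide_m <- fs[as.character(fs[[col]]) == pair[1], c("case_id", "value")]
    wide_n <- fs[as.character(fs[[col]]) == pair[2], c("case_id", "value")]
    if (anyDuplicated(wide_m$case_id) || anyDuplicated(wide_n$case_id)) {
      stop("multiple rows per case for feature ", feats[fi],
           " and pair member; restrict `table` to one study slice ",
           "(fixed values of the other variant columns)", call. = FALSE)
    }
    common <- intersect(wide_m$case_id, wide_n$case_id)
    miss <- setdiff(union(wide_m$case_id, wide_n$case_id), common)
    if (length(miss)) {
      stop("case(s) missing one pair member for feature ", feats[fi], ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    fm <- wide_m$value[match(common, wide_m$case_id)]
    fn <- wide_n$value[match(common, wide_n$case_id)]
    denom <- (fm + fn) / 2
    # a zero pair mean with fm == fn == 0 is perfect agreement (d = 0);
    # only fm == -fn != 0 leaves the ratio genuinely undefined
    bad <- denom == 0 & fm != fn
    zero_pair <- denom == 0 & fm == fn
    if (any(bad)) {
      message(sum(bad), " case(s) excluded for feature ", feats[fi],
              " (zero pair-mean denominator)")
    }
    d <- numeric(sum(!bad))
    dn <- denom[!bad]
    d[!zero_pair[!bad]] <- (fm[!bad] - fn[!bad])[!zero_pair[!bad]] /
      dn[!zero_pair[!bad]] * 100
    d_mean <- if (length(d)) mean(d) else NA_real_
    d_sd <- if (length(d) > 1L) stats::sd(d) else 0
    out[[fi]] <- data.frame(
      feature = feats[fi], pair_label = pair_label, parameter = parameter,
      n_cases = length(d), n_excluded = sum(bad),
      d_mean = d_mean, d_mean_abs = abs(d_mean), sd = d_sd,
      lrl = d_mean - 1.96 * d_sd, url = d_mean + 1.96 * d_sd,
      stringsAsFactors = FALSE)
    out[[fi]]$d <- I(list(d))
  }
  res <- do.call(rbind, out)
  class(res) <- c("paired_diff_result", class(res))
  res
}

#' Classify feature reproducibility
#'
#' A feature is \emph{reproducible} iff \eqn{|\bar d| \le 25\%} and
#' \eqn{SD \le 35\%}. Features passing that gate are banded by the largest
#' reproducibility-limit magnitude \eqn{m = \max(|URL|, |LRL|)}:
#' High for \eqn{m \le 30}, Intermediate for \eqn{30 < m \le 45}, Low for
#' \eqn{45 < m \le 50}; anything beyond, or failing the gate, is
#' nonreproducible (NR). Band edges are inclusive as stated; limits with
#' \eqn{m < 1} (tighter than the nominal \eqn{\pm 1\%} lower edge of the
#' High band) are graded High.
#'
#' @param res output of [paired_differences()] (or any data frame with
#'   \code{d_mean_abs}, \code{sd}, \code{lrl}, \code{url}).
#' @return \code{res} with added columns \code{limit_magnitude},
#'   \code{reproducible} and \code{class}
#'   (\code{High}/\code{Intermediate}/\code{Low}/\code{NR}).
#' @export
classify_reproducibility <- function(res) {
  need <- c("d_mean_abs", "sd", "lrl", "url")
  if (!all(need %in% names(res))) {
    stop("`res` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m <- pmax(abs(res$url), abs(res$lrl))
  gate <- res$d_mean_abs <= 25 & res$sd <= 35
  cls <- ifelse(!gate, "NR",
         ifelse(m <= 30, "High",
         ifelse(m <= 45, "Intermediate",
         ifelse(m <= 50, "Low", "NR"))))
  res$limit_magnitude <- m
  res$reproducible <- cls != "NR"
  res$class <- factor(cls, levels = c("High", "Intermediate", "Low", "NR"))
  res
}

#' Precision of a confidence interval
#'
#' Half the CI width, scaled by 100:
#' \eqn{(UB - LB)/2 \times 100}. Applied to ICC 95\% bounds this yields the
#' "±x\%" precision used to grade reliability. Bounds are ordered
#' numerically before use (published tables sometimes print them
#' upper-first).
#'
#' @param ci_lb,ci_ub confidence bounds (vectorized).
#' @return Numeric precision value(s).
#' @examples
#' precision_from_ci(0.84, 0.94)  # 5
#' @export
precision_from_ci <- function(ci_lb, ci_ub) {
  lo <- pmin(ci_lb, ci_ub)
  hi <- pmax(ci_lb, ci_ub)
  (hi - lo) / 2 * 100
}

# Two-way random-effects, absolute-agreement, single-measurement ICC
# (McGraw & Wong ICC(A,1)) with the F-distribution 95% CI, on an n x k
# matrix (rows = cases, columns = variant levels).
icc_a1 <- function(y, conf_level = 0.95) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  if (n < 3L || k < 2L) {
    stop("ICC needs >= 3 cases and >= 2 variant levels (got ", n, " x ", k,
         ")", call. = FALSE)
  }
  mr <- rowMeans(y); mc <- colMeans(y); gm <- mean(y)
  msr <- k * sum((mr - gm)^2) / (n - 1)
  msc <- n * sum((mc - gm)^2) / (k - 1)
  mse <- sum((y - outer(mr, rep(1, k)) - outer(rep(1, n), mc) + gm)^2) /
    ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= .Machine$double.eps * max(1, gm^2) || denom <= 0) {
    warning("zero between-case variance: ICC undefined", call. = FALSE)
    return(list(icc = NA_real_, ci_lb = NA_real_, ci_ub = NA_real_,
                precision = NA_real_, n = n, k = k))
  }
  icc <- (msr - mse) / denom
  if (mse == 0 && msc == 0) {
    # perfect agreement: degenerate CI collapses onto the estimate
    return(list(icc = icc, ci_lb = icc, ci_ub = icc, precision = 0,
                n = n, k = k))
  }
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lb <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ub <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci_lb = lb, ci_ub = ub,
       precision = precision_from_ci(lb, ub), n = n, k = k)
}

#' Per-feature ICC with precision
#'
#' Treats the variant levels of one testing parameter (segmentation
#' methods, gray levels or reconstruction variants) as raters in a two-way
#' random-effects, absolute-agreement, single-measurement ICC (ICC(A,1))
#' and reports the 95\% confidence bounds and the precision (CI half-width
#' times 100). Features with zero between-case variance get an \code{NA}
#' sentinel with a warning.
#'
#' @param table a \code{feature_table} restricted to the study slice.
#' @param parameter \code{"SM"}, \code{"GL"} or \code{"RA"}.
#' @param levels optional subset of variant labels to use as raters (e.g.
#'   excluding the most divergent reconstruction); default all present.
#' @param conf_level confidence level, default 0.95.
#' @return Data frame with one row per feature: \code{feature},
#'   \code{parameter}, \code{icc}, \code{ci_lb}, \code{ci_ub},
#'   \code{precision}, \code{n_cases}, \code{n_levels}.
#' @export
icc_with_precision <- function(table, parameter = c("SM", "GL", "RA"),
                               levels = NULL, conf_level = 0.95) {
  parameter <- match.arg(parameter)
  col <- PARAMETER_COLUMNS[[parameter]]
  table <- validate_feature_table(as.data.frame(table))
  lv <- as.character(table[[col]])
  use <- if (is.null(levels)) sort(unique(lv)) else as.character(levels)
  sub <- table[lv %in% use, , drop = FALSE]
  feats <- unique(sub$feature)
  rows <- lapply(feats, function(f) {
    fs <- sub[sub$feature == f, , drop = FALSE]
    y <- tapply(fs$value, list(fs$case_id, as.character(fs[[col]])),
                function(v) {
                  if (length(v) != 1L) {
                    stop("multiple values per (case, level) for feature ", f,
                         "; restrict `table` to one study slice",
                         call. = FALSE)
                  }
                  v
                })
    y <- y[, use[use %in% colnames(y)], drop = FALSE]
    if (anyNA(y)) {
      y <- y[stats::complete.cases(y), , drop = FALSE]
    }
    r <- icc_a1(y, conf_level)
    data.frame(feature = f, parameter = parameter, icc = r$icc,
               ci_lb = r$ci_lb, ci_ub = r$ci_ub, precision = r$precision,
               n_cases = r$n, n_levels = r$k, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Inter-item correlation across gray levels
#'
#' Pearson correlation, across cases, between each feature's values at the
#' reference gray level and at each other gray level. Used to justify the
#' choice of reference level (the level most correlated with all others).
#'
#' @param table a \code{feature_table} spanning the gray levels.
#' @param reference_gl reference gray level (default 64).
#' @param other_gls gray levels to correlate against; default all others
#'   present.
#' @return Data frame: \code{feature}, \code{gray_level}, \code{iic}
#'   (\code{NA} with \code{constant = TRUE} when either vector is
#'   constant).
#' @export
inter_item_correlation <- function(table, reference_gl = 64,
                                   other_gls = NULL) {
  table <- validate_feature_table(as.data.frame(table))
  gls <- sort(unique(table$gray_level))
  if (!reference_gl %in% gls) {
    stop("reference gray level ", reference_gl, " not present in table",
         call. = FALSE)
  }
  if (is.null(other_gls)) other_gls <- setdiff(gls, reference_gl)
  feats <- unique(table$feature)
  out <- list()
  for (f in feats) {
    fs <- table[table$feature == f, , drop = FALSE]
    ref <- fs[fs$gray_level == reference_gl, c("case_id", "value")]
    for (g in other_gls) {
      oth <- fs[fs$gray_level == g, c("case_id", "value")]
      common <- intersect(ref$case_id, oth$case_id)
      x <- ref$value[match(common, ref$case_id)]
      y <- oth$value[match(common, oth$case_id)]
      const <- stats::sd(x) == 0 || stats::sd(y) == 0
      iic <- if (const || length(common) < 3L) NA_real_ else stats::cor(x, y)
      out[[length(out) + 1L]] <- data.frame(
        feature = f, gray_level = g, iic = iic, constant = const,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Bland-Altman plot for one feature pair
#'
#' Scatter of per-case signed percentage differences against case index,
#' with the mean difference and the upper/lower reproducibility limits.
#'
#' @param res one row of a [paired_differences()] result (or the full
#'   result plus \code{feature} to select a row).
#' @param feature feature name when \code{res} has several rows.
#' @return Invisibly, the per-case differences.
#' @export
plot_bland_altman <- function(res, feature = NULL) {
  if (nrow(res) > 1L) {
    if (is.null(feature)) stop("specify `feature` to select a row",
                               call. = FALSE)
    res <- res[res$feature == feature, , drop = FALSE]
  }
  d <- res$d[[1]]
  plot(seq_along(d), d, xlab = "case", ylab = "percentage difference (%)",
       main = sprintf("%s  (%s)", res$feature, res$pair_label),
       pch = 19)
  graphics::abline(h = res$d_mean, lty = 1)
  graphics::abline(h = c(res$lrl, res$url), lty = 2)
  invisible(d)
}
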