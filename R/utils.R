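# Internal numeric helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded operations never
#' leak state into the caller's RNG stream. Seeds are always explicit
#' function arguments in this package.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Shift a 3D array by an integer offset, replicating edge values.
# Used by the separable Gaussian filter and the NGTDM window sums.
shift_array <- function(arr, offset) {
  d <- dim(arr)
  ix <- pmin(pmax(seq_len(d[1]) + offset[1], 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + offset[2], 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + offset[3], 1L), d[3])
  arr[ix, iy, iz, drop = FALSE]
}

# Shift with zero padding instead of edge replication (for masked sums).
shift_array_zero <- function(arr, offset) {
  d <- dim(arr)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- offset[a]
    if (o >= d[a] || -o >= d[a]) return(out)
    if (o >= 0) {
      dst[[a]] <- seq_len(d[a] - o)
      src[[a]] <- seq_len(d[a] - o) + o
    } else {
      dst[[a]] <- seq_len(d[a] + o) - o
      src[[a]] <- seq_len(d[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Gaussian smoothing of a 3D array. `sigma_vox` is per-axis in
# voxel units; zero entries skip that axis. Edges are replicated, which
# keeps background flat up to the volume border.
gauss_smooth <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L, length(sigma_vox) == 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    halfw <- max(1L, as.integer(ceiling(3 * s)))
    taps <- (-halfw):halfw
    w <- exp(-0.5 * (taps / s)^2)
    w <- w / sum(w)
    acc <- array(0, dim = dim(arr))
    off <- c(0L, 0L, 0L)
    for (t in seq_along(taps)) {
      off[axis] <- taps[t]
      acc <- acc + w[t] * shift_array(arr, off)
    }
    arr <- acc
  }
  arr
}

# Sample moments. Skewness is the Fisher-Pearson g1; kurtosis is excess
# (g2 = m4/m2^2 - 3). Both return 0 with a warning on constant input,
# a documented convention so degenerate ROIs keep defined feature rows.
sample_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= .Machine$double.eps * max(1, mean(x)^2)) {
    warning("constant input: skewness undefined, returning 0", call. = FALSE)
    return(0)
  }
  mean((x - mean(x))^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= .Machine$double.eps * max(1, mean(x)^2)) {
    warning("constant input: kurtosis undefined, returning 0", call. = FALSE)
    return(0)
  }
  mean((x - mean(x))^4) / m2^2 - 3
}

# xlogx with the 0*log(0) = 0 convention, base 2.
xlog2x <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
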