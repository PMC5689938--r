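# Independent brute-force oracles for the texture-matrix builders. These
# deliberately use naive per-voxel loops, structured differently from the
# vectorized implementations they check.

# All 26 signed unit offsets (both orientations of the 13 directions).
oracle_all_offsets <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# GLCM by double loop over every in-mask voxel and every signed offset.
oracle_glcm <- function(d) {
  Ng <- d$Ng
  dims <- dim(d$levels)
  offs <- oracle_all_offsets()
  counts <- matrix(0, Ng, Ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      if (!d$mask[x, y, z]) next
      for (r in seq_len(nrow(offs))) {
        p <- c(x, y, z) + offs[r, ]
        if (any(p < 1L) || any(p > dims)) next
        if (!d$mask[p[1], p[2], p[3]]) next
        i <- d$levels[x, y, z]
        j <- d$levels[p[1], p[2], p[3]]
        counts[i, j] <- counts[i, j] + 1
      }
    }
  counts / sum(counts)
}

# GLRLM by walking runs from their starting voxel, one direction at a time.
oracle_glrlm <- function(d, directions = direction_set_3d()) {
  dims <- dim(d$levels)
  inb <- function(p) all(p >= 1L) && all(p <= dims)
  at <- function(p) d$levels[p[1], p[2], p[3]]
  inm <- function(p) inb(p) && d$mask[p[1], p[2], p[3]]
  runs <- list()
  for (r in seq_len(nrow(directions))) {
    dir <- directions[r, ]
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        p <- c(x, y, z)
        if (!inm(p)) next
        prev <- p - dir
        if (inm(prev) && at(prev) == at(p)) next  # not a run start
        len <- 1L
        q <- p + dir
        while (inm(q) && at(q) == at(p)) {
          len <- len + 1L
          q <- q + dir
        }
        runs[[length(runs) + 1L]] <- c(at(p), len)
      }
  }
  runs <- do.call(rbind, runs)
  rmax <- max(runs[, 2])
  m <- matrix(0L, d$Ng, rmax)
  for (i in seq_len(nrow(runs))) {
    m[runs[i, 1], runs[i, 2]] <- m[runs[i, 1], runs[i, 2]] + 1L
  }
  m
}

# GLSZM by repeated-scan region growing (O(n^2), independent of the BFS
# in the implementation).
oracle_glszm <- function(d, connectivity = 26) {
  coords <- which(d$mask, arr.ind = TRUE)
  lev <- d$levels[d$mask]
  n <- nrow(coords)
  assigned <- rep(FALSE, n)
  adjacent <- function(a, b) {
    dd <- abs(coords[a, ] - coords[b, ])
    if (connectivity == 26) all(dd <= 1L) && any(dd > 0L)
    else sum(dd) == 1L
  }
  zones <- list()
  for (s in seq_len(n)) {
    if (assigned[s]) next
    zone <- s
    assigned[s] <- TRUE
    repeat {
      grew <- FALSE
      for (cand in which(!assigned & lev == lev[s])) {
        if (any(vapply(zone, function(z) adjacent(z, cand), logical(1)))) {
          zone <- c(zone, cand)
          assigned[cand] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    zones[[length(zones) + 1L]] <- c(lev[s], length(zone))
  }
  zones <- do.call(rbind, zones)
  smax <- max(zones[, 2])
  m <- matrix(0L, d$Ng, smax)
  for (i in seq_len(nrow(zones))) {
    m[zones[i, 1], zones[i, 2]] <- m[zones[i, 1], zones[i, 2]] + 1L
  }
  m
}

# NGTDM accumulators by per-voxel window loops.
oracle_ngtdm <- function(d, hw = c(3L, 3L, 0L)) {
  dims <- dim(d$levels)
  n_i <- numeric(d$Ng)
  s_i <- numeric(d$Ng)
  nv <- 0L
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      if (!d$mask[x, y, z]) next
      nbr <- c()
      for (dx in -hw[1]:hw[1]) for (dy in -hw[2]:hw[2])
        for (dz in -hw[3]:hw[3]) {
          if (dx == 0 && dy == 0 && dz == 0) next
          p <- c(x + dx, y + dy, z + dz)
          if (any(p < 1L) || any(p > dims)) next
          if (d$mask[p[1], p[2], p[3]]) {
            nbr <- c(nbr, d$levels[p[1], p[2], p[3]])
          }
        }
      if (!length(nbr)) next
      lv <- d$levels[x, y, z]
      n_i[lv] <- n_i[lv] + 1
      s_i[lv] <- s_i[lv] + abs(lv - mean(nbr))
      nv <- nv + 1L
    }
  list(n_i = n_i, s_i = s_i, n_valid = nv)
}

# Random small discretized ROI for property tests.
random_discretized_roi <- function(dims = c(5L, 5L, 3L), Ng = 6L,
                                   mask_prob = 0.7) {
  suv <- array(stats::runif(prod(dims), 0, 10), dim = dims)
  msk <- array(stats::runif(prod(dims)) < mask_prob, dim = dims)
  if (sum(msk) < 2L) msk[1:2] <- TRUE
  v <- suv_volume(suv, c(1, 1, 1))
  m <- roi_mask(msk, c(1, 1, 1))
  suppressWarnings(discretize_roi(v, m, Ng))
}

# Digitized ball mask on an isotropic grid.
ball_mask <- function(radius_vox, spacing = c(1, 1, 1), margin = 4L) {
  n <- 2L * ceiling(radius_vox) + 2L * margin + 1L
  ctr <- (n + 1) / 2
  x <- (seq_len(n) - ctr)^2
  arr <- outer(outer(x, x, "+"), x, "+") <= radius_vox^2
  roi_mask(arr, spacing)
}
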