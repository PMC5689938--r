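# Minimal 3D quickhull, used for mask convexity. Grid-aligned point clouds
# are highly degenerate (many coplanar points), so all visibility tests use
# a tolerance scaled to the cloud's bounding box; points within tolerance of
# a face plane are treated as interior, which does not affect the hull
# volume.

convex_hull_volume <- function(pts) {
  convex_hull_3d(pts)$volume
}

# Full quickhull: returns volume plus face-plane normals and offsets
# (outward; a point q is inside iff normal . q <= offset for every face).
convex_hull_3d <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  degenerate <- list(volume = 0, normals = NULL, offsets = NULL)
  if (n < 4L) return(degenerate)
  scale <- max(apply(pts, 2L, function(c) diff(range(c))), .Machine$double.eps)
  eps <- 1e-9 * scale

  # initial simplex: extreme pair, then max-distance-from-line, then
  # max-distance-from-plane
  ext <- c(apply(pts, 2L, which.min), apply(pts, 2L, which.max))
  d2 <- as.matrix(dist(pts[ext, , drop = FALSE]))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  a <- ext[ij[1]]; b <- ext[ij[2]]
  ab <- pts[b, ] - pts[a, ]
  rel <- sweep(pts, 2L, pts[a, ])
  crossm <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
                  rel[, 3] * ab[1] - rel[, 1] * ab[3],
                  rel[, 1] * ab[2] - rel[, 2] * ab[1])
  dline <- sqrt(rowSums(crossm^2))
  cc <- which.max(dline)
  if (dline[cc] <= eps) return(degenerate)    # collinear cloud
  nrm <- c(ab[2] * (pts[cc, 3] - pts[a, 3]) - ab[3] * (pts[cc, 2] - pts[a, 2]),
           ab[3] * (pts[cc, 1] - pts[a, 1]) - ab[1] * (pts[cc, 3] - pts[a, 3]),
           ab[1] * (pts[cc, 2] - pts[a, 2]) - ab[2] * (pts[cc, 1] - pts[a, 1]))
  dplane <- rel %*% nrm
  dd <- which.max(abs(dplane))
  if (abs(dplane[dd]) <= eps * sqrt(sum(nrm^2))) {
    return(degenerate)                         # coplanar cloud
  }
  simplex <- c(a, b, cc, dd)
  interior <- colMeans(pts[simplex, ])

  face_normal <- function(f) {
    u <- pts[f[2], ] - pts[f[1], ]
    v <- pts[f[3], ] - pts[f[1], ]
    nr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    if (sum((interior - pts[f[1], ]) * nr) > 0) nr <- -nr  # outward
    nr
  }
  faces <- list(simplex[c(1, 2, 3)], simplex[c(1, 2, 4)],
                simplex[c(1, 3, 4)], simplex[c(2, 3, 4)])
  normals <- lapply(faces, face_normal)
  offsets <- vapply(seq_along(faces), function(i)
    sum(normals[[i]] * pts[faces[[i]][1], ]), numeric(1))

  dist_to <- function(i, idx) {
    nr <- normals[[i]]
    (pts[idx, , drop = FALSE] %*% nr - offsets[i]) / sqrt(sum(nr^2))
  }
  cand <- setdiff(seq_len(n), simplex)
  outside <- vector("list", length(faces))
  assign_pts <- function(idx, face_ids, outside) {
    for (i in face_ids) {
      if (!length(idx)) break
      dd <- dist_to(i, idx)
      sel <- dd > eps
      if (any(sel)) {
        outside[[i]] <- c(outside[[i]], idx[sel])
        idx <- idx[!sel]
      }
    }
    outside
  }
  outside <- assign_pts(cand, seq_along(faces), outside)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 10000L) stop("convex hull failed to converge", call. = FALSE)
    pend <- which(vapply(outside, length, integer(1)) > 0L)
    if (!length(pend)) break
    fi <- pend[1]
    idx <- outside[[fi]]
    far <- idx[which.max(dist_to(fi, idx))]
    visible <- which(vapply(seq_along(faces), function(i)
      dist_to(i, far)[1] > eps, logical(1)))
    # horizon: undirected edges used by exactly one visible face
    edges <- do.call(rbind, lapply(visible, function(i) {
      f <- faces[[i]]
      rbind(sort(f[c(1, 2)]), sort(f[c(2, 3)]), sort(f[c(1, 3)]))
    }))
    ekey <- paste(edges[, 1], edges[, 2])
    horizon <- edges[ekey %in% names(which(table(ekey) == 1L)), ,
                     drop = FALSE]
    orphan <- unique(unlist(outside[visible]))
    orphan <- setdiff(orphan, far)
    keep <- setdiff(seq_along(faces), visible)
    faces <- faces[keep]; normals <- normals[keep]
    offsets <- offsets[keep]; outside <- outside[keep]
    new_ids <- integer(0)
    for (e in seq_len(nrow(horizon))) {
      f <- c(horizon[e, ], far)
      nr <- face_normal(f)
      faces[[length(faces) + 1L]] <- f
      normals[[length(normals) + 1L]] <- nr
      offsets[length(offsets) + 1L] <- sum(nr * pts[f[1], ])
      outside[[length(outside) + 1L]] <- integer(0)
      new_ids <- c(new_ids, length(faces))
    }
    outside <- assign_pts(orphan, new_ids, outside)
  }

  vol <- 0
  for (f in faces) {
    u <- pts[f[1], ] - interior
    v <- pts[f[2], ] - interior
    w <- pts[f[3], ] - interior
    vol <- vol + abs(u[1] * (v[2] * w[3] - v[3] * w[2]) -
                     u[2] * (v[1] * w[3] - v[3] * w[1]) +
                     u[3] * (v[1] * w[2] - v[2] * w[1])) / 6
  }
  nrm_mat <- do.call(rbind, normals)
  nrm_len <- sqrt(rowSums(nrm_mat^2))
  list(volume = vol, normals = nrm_mat / nrm_len,
       offsets = offsets / nrm_len, tol = eps)
}
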