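#' The 13 unique 3D displacement directions
#'
#' All voxel-pair relations at one-voxel displacement in 3D: 26 nonzero
#' offsets with components in \{-1, 0, 1\}, collapsed to 13 by keeping one
#' representative per axis-symmetric pair (the lexicographically positive
#' one). Texture matrices accumulate both orientations of each offset, so
#' these 13 cover the full 26-neighborhood.
#'
#' @return A 13 x 3 integer matrix, one offset per row.
#' @examples
#' nrow(direction_set_3d())  # 13
#' @export
direction_set_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1L, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  stopifnot(nrow(m) == 13L)
  m
}

# Validate a user-supplied direction set: integer offsets in {-1,0,1},
# nonzero, no offset equal to the negation of another.
check_directions <- function(directions) {
  if (!is.matrix(directions) || ncol(directions) != 3L) {
    stop("`directions` must be a matrix with 3 columns", call. = FALSE)
  }
  if (any(abs(directions) > 1L) || any(directions != round(directions))) {
    stop("direction components must be integers in {-1, 0, 1}", call. = FALSE)
  }
  if (any(rowSums(abs(directions)) == 0L)) {
    stop("the zero offset is not a valid direction", call. = FALSE)
  }
  key <- apply(directions, 1L, paste, collapse = ",")
  negkey <- apply(-directions, 1L, paste, collapse = ",")
  if (any(key %in% negkey)) {
    stop("direction set contains an offset and its negation; keep one of ",
         "each symmetric pair", call. = FALSE)
  }
  storage.mode(directions) <- "integer"
  directions
}
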