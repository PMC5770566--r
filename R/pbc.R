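# Periodic boundary utilities (orthorhombic boxes only).

#' Minimum-image displacement vector
#'
#' Displacement `b - a` under the minimum-image convention for an
#' orthorhombic box.  Each component of the result lies in `[-edge/2,
#' +edge/2)`.
#'
#' @param a,b positions: length-3 vectors or n x 3 matrices, nm
#' @param box length-3 box edge lengths, nm
#' @return displacement vector(s), same shape as the broadcast of `a`/`b`
#' @export
min_image_vector <- function(a, b, box) {
  if (any(box <= 0)) stop("box edges must be > 0")
  if (is.matrix(a) || is.matrix(b)) {
    if (!is.matrix(a)) a <- matrix(a, nrow(b), 3, byrow = TRUE)
    if (!is.matrix(b)) b <- matrix(b, nrow(a), 3, byrow = TRUE)
    v <- b - a
    for (k in 1:3) v[, k] <- v[, k] - box[k] * floor(v[, k] / box[k] + 0.5)
    v
  } else {
    v <- b - a
    v - box * floor(v / box + 0.5)
  }
}

#' Minimum-image distances from one point to a set of points
#'
#' @param p length-3 position, nm
#' @param pts n x 3 positions, nm
#' @param box length-3 box edges, nm
#' @return numeric vector of n distances
#' @export
min_image_dist <- function(p, pts, box) {
  v <- min_image_vector(p, pts, box)
  sqrt(rowSums(v * v))
}

# Cross-set minimum-image distance matrix (n x m), fully vectorized; used
# by the phrase builder and residence tracker.
cross_dist <- function(A, B, box) {
  dx <- outer(A[, 1], B[, 1], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(A[, 2], B[, 2], "-")
  dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(A[, 3], B[, 3], "-")
  dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Wrap positions into the primary box image
#'
#' @param xyz n x 3 positions, nm
#' @param box length-3 box edges, nm
#' @return wrapped positions, each coordinate in `[0, edge)`
#' @export
wrap_positions <- function(xyz, box) {
  if (any(box <= 0)) stop("box edges must be > 0")
  for (k in 1:3) xyz[, k] <- xyz[, k] - box[k] * floor(xyz[, k] / box[k])
  xyz
}
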