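# Rigid-body superposition (Kabsch) used to remove global drift/rotation of
# the protein before any density or occupancy accumulation.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation `R` and translation `t` minimizing the RMSD of
#' `P %*% R + t` onto `Q`.  With `in_plane = TRUE` the rotation is restricted
#' to the membrane (xy) plane, i.e. a rotation about z; translation remains
#' fully 3D.
#'
#' @param P,Q n x 3 matrices of paired coordinates (moving and reference)
#' @param in_plane restrict the rotation to the xy plane
#' @return list with `R` (3 x 3), `t` (length 3) and `rmsd` after fitting
#' @export
kabsch_fit <- function(P, Q, in_plane = FALSE) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  if (nrow(P) < 3L) stop("need at least 3 selection beads for a rigid fit")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Pc))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("selection beads are collinear; rigid fit is underdetermined")
  }
  if (in_plane) {
    # 2D Kabsch on xy; z untouched by the rotation
    H <- crossprod(Pc[, 1:2, drop = FALSE], Qc[, 1:2, drop = FALSE])
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R2 <- s$v %*% diag(c(1, d)) %*% t(s$u)
    R <- diag(3)
    R[1:2, 1:2] <- t(R2)  # applied as P %*% R
  } else {
    H <- crossprod(Pc, Qc)
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  }
  t_vec <- cq - as.numeric(cp %*% R)
  fitted <- sweep(P %*% R, 2, t_vec, "+")
  list(R = R, t = t_vec, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Fit a frame onto a reference by rigid superposition of a selection
#'
#' The rotation/translation is computed from the selection (default: protein
#' backbone beads, falling back to all protein beads when no bead is named
#' "BB") and applied to every bead of the frame.
#'
#' @param frame frame list (`time`, `xyz`, `box`) as from [get_frame()]
#' @param reference_frame reference frame list with matching beads
#' @param topology a `cg_topology` (used for the default selection)
#' @param selection integer vector of bead rows (1-based) to superpose;
#'   default protein backbone
#' @param in_plane restrict the rotation to the membrane plane
#' @return the transformed frame (same structure as `frame`)
#' @export
fit_frame <- function(frame, reference_frame, topology = NULL,
                      selection = NULL, in_plane = FALSE) {
  if (is.null(selection)) {
    if (is.null(topology)) stop("supply either a topology or a selection")
    selection <- protein_backbone_selection(topology)
  }
  if (length(selection) == 0L) stop("empty fit selection")
  fit <- kabsch_fit(frame$xyz[selection, , drop = FALSE],
                    reference_frame$xyz[selection, , drop = FALSE],
                    in_plane = in_plane)
  frame$xyz <- sweep(frame$xyz %*% fit$R, 2, fit$t, "+")
  frame
}

#' Default fit selection: protein backbone beads
#'
#' @param topology a `cg_topology`
#' @return integer vector of bead rows (1-based)
#' @export
protein_backbone_selection <- function(topology) {
  b <- topology$beads
  sel <- which(b$species == "PROTEIN" & b$name == "BB")
  if (length(sel) == 0L) sel <- which(b$species == "PROTEIN")
  sel
}

#' RMSD between two coordinate sets
#' @param A,B n x 3 matrices
#' @return root-mean-square deviation
#' @export
rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))
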