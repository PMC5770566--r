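# Leaflet assignment.  Convention: bilayer normal = z, stromal = +z side.

#' Assign lipids to leaflets
#'
#' Each lipid is labelled by the sign of (headgroup z - membrane midplane z),
#' where the midplane is the median z of all lipid tail-terminal beads in the
#' frame.  Labels are re-evaluated per frame by callers so that flip-flopping
#' lipids are tracked.
#'
#' @param frame frame list (`time`, `xyz`, `box`)
#' @param topology a `cg_topology`
#' @return named character vector, lipid `molecule_id` -> `"stromal"` /
#'   `"lumenal"`; warns when a putative leaflet holds fewer than 10 lipids
#' @export
assign_leaflets <- function(frame, topology) {
  b <- topology$beads
  head_rows <- which(b$is_headgroup)
  if (length(head_rows) == 0L) stop("topology has no headgroup beads")
  tail_rows <- which(b$is_tail_terminal)
  if (length(tail_rows) == 0L) stop("topology has no tail-terminal beads")
  midplane <- stats::median(frame$xyz[tail_rows, 3])
  head_z <- frame$xyz[head_rows, 3]
  mol <- b$molecule_id[head_rows]
  # one headgroup bead per lipid in the CG representation; if several, the
  # first per molecule represents the lipid
  keep <- !duplicated(mol)
  lab <- ifelse(head_z[keep] >= midplane, "stromal", "lumenal")
  names(lab) <- as.character(mol[keep])
  counts <- table(factor(lab, levels = c("stromal", "lumenal")))
  if (any(counts < 10L)) {
    warning("fewer than 10 lipids in leaflet(s): ",
            paste(names(counts)[counts < 10L], collapse = ", "))
  }
  lab
}
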