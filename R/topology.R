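#' @keywords internal
"_PACKAGE"

# Internal unit conventions: lengths in nm, times in ns, membrane normal = z,
# stromal side = +z.  Bead indices are 0-based internally and 1-based in all
# file I/O (GRO/PDB convention).

SPECIES_LEVELS <- c("PROTEIN", "MGDG", "DGDG", "SQDG", "PG",
                    "COFACTOR", "SOLVENT", "ION")

#' Construct a coarse-grained topology
#'
#' A topology is the static description of the system: one row per bead with
#' species/residue/subunit labels, plus the dimer bookkeeping needed by the
#' C2-symmetry site filter (which protein molecules belong to which monomer,
#' and the two-fold axis relating them).
#'
#' @param beads data.frame with columns `bead_id` (0-based integer), `name`,
#'   `residue_id`, `residue_name`, `molecule_id`, `subunit`, `species`
#'   (one of PROTEIN, MGDG, DGDG, SQDG, PG, COFACTOR, SOLVENT, ION),
#'   `is_headgroup`, `is_tail_terminal`, `is_cocrystallized`.
#' @param monomer_map named character vector mapping protein `molecule_id`
#'   (as character) to `"A"`, `"B"` or `"none"`.
#' @param c2_axis list with `point` (length-3 numeric, nm) and `direction`
#'   (length-3 numeric); the two-fold rotation axis relating monomer A to B.
#'   May be `NULL` for systems without a dimer.
#' @return An object of class `cg_topology`.
#' @export
cg_topology <- function(beads, monomer_map = NULL, c2_axis = NULL) {
  required <- c("bead_id", "name", "residue_id", "residue_name",
                "molecule_id", "subunit", "species", "is_headgroup",
                "is_tail_terminal", "is_cocrystallized")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols) > 0L) {
    stop("beads is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(beads$species), SPECIES_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown species label(s): ", paste(bad, collapse = ", "))
  }
  lipid_sp <- beads$species %in% c("MGDG", "DGDG", "SQDG", "PG")
  if (any(beads$is_headgroup & !lipid_sp)) {
    stop("is_headgroup = TRUE is only valid for lipid species")
  }
  if (!is.null(c2_axis)) {
    stopifnot(length(c2_axis$point) == 3L, length(c2_axis$direction) == 3L)
    c2_axis$direction <- c2_axis$direction / sqrt(sum(c2_axis$direction^2))
  }
  prot_mols <- unique(beads$molecule_id[beads$species == "PROTEIN"])
  if (!is.null(monomer_map)) {
    unassigned <- setdiff(as.character(prot_mols), names(monomer_map))
    if (length(unassigned) > 0L) {
      stop("monomer_map does not assign protein molecule(s): ",
           paste(unassigned, collapse = ", "))
    }
  }
  structure(list(beads = beads, monomer_map = monomer_map, c2_axis = c2_axis),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  b <- x$beads
  cat("Coarse-grained topology:", nrow(b), "beads,",
      length(unique(b$molecule_id)), "molecules\n")
  tab <- table(b$species)
  for (sp in names(tab)) cat(sprintf("  %-8s %6d beads\n", sp, tab[[sp]]))
  if (!is.null(x$c2_axis)) {
    cat("C2 axis through (", paste(signif(x$c2_axis$point, 4), collapse = ", "),
        ") along (", paste(signif(x$c2_axis$direction, 3), collapse = ", "),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Number of beads in a topology
#' @param topology a `cg_topology`
#' @return integer bead count
#' @export
n_beads <- function(topology) nrow(topology$beads)

#' Construct a trajectory container
#'
#' Frames are stored densely: an `n_beads x 3 x n_frames` coordinate array,
#' a time vector (ns) and per-frame orthorhombic box edges (nm).
#'
#' @param times numeric vector, ns, strictly increasing
#' @param coords numeric array `n_beads x 3 x n_frames`, nm
#' @param box numeric matrix `n_frames x 3`, box edge lengths, nm
#' @return An object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(times, coords, box) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_beads x 3 x n_frames array")
  }
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  stopifnot(length(times) == nf, nrow(box) == nf, ncol(box) == 3L)
  if (nf > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (any(box <= 0)) stop("box edges must be > 0")
  structure(list(times = times, coords = coords, box = box),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat("Trajectory:", dim(x$coords)[1], "beads,", nf, "frames, t =",
      x$times[1], "..", x$times[nf], "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

# coordinates of a bead subset in one frame, always an n x 3 matrix
frame_coords <- function(traj, rows, f) {
  x <- traj$coords[rows, , f, drop = FALSE]
  dim(x) <- c(length(rows), 3L)
  x
}

#' Extract one frame from a trajectory
#' @param traj a `cg_trajectory`
#' @param i frame index (1-based)
#' @return list with `time` (ns), `xyz` (n_beads x 3 matrix, nm), `box`
#'   (length-3, nm)
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  list(time = traj$times[i], xyz = traj$coords[, , i, drop = TRUE],
       box = traj$box[i, ])
}

#' Default species configuration for thylakoid-like systems
#'
#' Maps residue names to species, headgroup beads and tail-terminal beads.
#' The Martini GL1 glycerol bead is the headgroup proxy for all four thylakoid
#' lipid classes.  `SQDS` is the fully saturated SQDG variant; it maps to the
#' SQDG species.
#'
#' @return named list: residue_name -> list(species, headgroup_beads,
#'   tail_terminal_beads)
#' @export
default_species_config <- function() {
  lip <- function(sp) list(species = sp, headgroup_beads = "GL1",
                           tail_terminal_beads = c("C4A", "C4B"))
  c(
    list(MGDG = lip("MGDG"), DGDG = lip("DGDG"), SQDG = lip("SQDG"),
         SQDS = lip("SQDG"), PG = lip("PG")),
    stats::setNames(
      lapply(AA3, function(a) list(species = "PROTEIN",
                                   headgroup_beads = character(),
                                   tail_terminal_beads = character())),
      AA3),
    list(CHL = list(species = "COFACTOR", headgroup_beads = character(),
                    tail_terminal_beads = character()),
         HEM = list(species = "COFACTOR", headgroup_beads = character(),
                    tail_terminal_beads = character()),
         W   = list(species = "SOLVENT", headgroup_beads = character(),
                    tail_terminal_beads = character()),
         ION = list(species = "ION", headgroup_beads = character(),
                    tail_terminal_beads = character()))
  )
}

#' Read a species configuration from YAML
#'
#' @param path YAML file mapping residue_name -> species / headgroup_beads /
#'   tail_terminal_beads
#' @return named list as [default_species_config()]
#' @export
read_species_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) {
    list(species = x$species,
         headgroup_beads = as.character(x$headgroup_beads %||% character()),
         tail_terminal_beads = as.character(x$tail_terminal_beads %||%
                                              character()))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
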