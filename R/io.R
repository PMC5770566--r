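# Structure and trajectory readers/writers.
#
# GRO and the plain-text fixture trajectory format are parsed natively; PDB
# and DCD go through bio3d.  The fixture format is:
#   line 1 per frame:  "t <ns> box <x> <y> <z>"
#   then one "x y z" line per bead (nm).

#' Read a GRO structure file
#'
#' @param path GRO file
#' @return list with `atoms` data.frame (residue_id, residue_name, name,
#'   atom_id), `xyz` (n x 3 matrix, nm) and `box` (length-3, nm; orthorhombic
#'   only — triclinic boxes are rejected)
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < 3L + n) {
    stop("GRO file truncated or malformed atom count: ", path)
  }
  atom_lines <- lines[3:(2 + n)]
  res_id   <- as.integer(substr(atom_lines, 1, 5))
  res_name <- trimws(substr(atom_lines, 6, 10))
  at_name  <- trimws(substr(atom_lines, 11, 15))
  at_id    <- as.integer(substr(atom_lines, 16, 20))
  x <- as.numeric(substr(atom_lines, 21, 28))
  y <- as.numeric(substr(atom_lines, 29, 36))
  z <- as.numeric(substr(atom_lines, 37, 44))
  box_fields <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  if (length(box_fields) > 3L && any(box_fields[-(1:3)] != 0)) {
    stop("triclinic box in GRO file not supported (off-diagonal elements ",
         "present); only orthorhombic boxes are handled")
  }
  list(atoms = data.frame(residue_id = res_id, residue_name = res_name,
                          name = at_name, atom_id = at_id,
                          stringsAsFactors = FALSE),
       xyz = cbind(x, y, z), box = box_fields[1:3])
}

#' Write a GRO structure file
#'
#' Coordinates are written with the GRO standard 3 decimals (nm).
#'
#' @param topology a `cg_topology`
#' @param xyz n_beads x 3 matrix, nm
#' @param box length-3 box edges, nm
#' @param path output file
#' @param title title line
#' @return `path`, invisibly
#' @export
write_gro <- function(topology, xyz, box, path, title = "lipidsites system") {
  b <- topology$beads
  n <- nrow(b)
  stopifnot(nrow(xyz) == n)
  # GRO fixed width: %5d%-5s%5s%5d%8.3f%8.3f%8.3f ; ids wrap at 100000
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   b$residue_id %% 100000L,
                   substr(b$residue_name, 1, 5),
                   substr(b$name, 1, 5),
                   (b$bead_id + 1L) %% 100000L,
                   xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(title, sprintf("%5d", n), lines,
               sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), path)
  invisible(path)
}

#' Write a plain-text fixture trajectory
#'
#' @param traj a `cg_trajectory`
#' @param path output file
#' @param digits decimal digits for coordinates
#' @return `path`, invisibly
#' @export
write_fixture_trajectory <- function(traj, path, digits = 4) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "f")
  for (i in seq_len(n_frames(traj))) {
    fr <- get_frame(traj, i)
    writeLines(sprintf("t %s box %s %s %s",
                       format(fr$time, trim = TRUE, scientific = FALSE),
                       sprintf(fmt, fr$box[1]), sprintf(fmt, fr$box[2]),
                       sprintf(fmt, fr$box[3])), con)
    writeLines(paste(sprintf(fmt, fr$xyz[, 1]), sprintf(fmt, fr$xyz[, 2]),
                     sprintf(fmt, fr$xyz[, 3])), con)
  }
  invisible(path)
}

#' Read a plain-text fixture trajectory
#'
#' @param path fixture trajectory file (see [write_fixture_trajectory()])
#' @param n_beads expected bead count per frame
#' @return a `cg_trajectory`
#' @export
read_fixture_trajectory <- function(path, n_beads) {
  lines <- readLines(path)
  header_idx <- grep("^t ", lines)
  if (length(header_idx) == 0L) stop("no frame headers found in ", path)
  per_frame <- diff(c(header_idx, length(lines) + 1L)) - 1L
  if (any(per_frame != per_frame[1])) {
    stop("inconsistent bead counts across frames in ", path)
  }
  if (per_frame[1] != n_beads) {
    stop("trajectory/structure bead count mismatch: ", per_frame[1], " vs ",
         n_beads)
  }
  nf <- length(header_idx)
  times <- numeric(nf)
  box <- matrix(0, nf, 3)
  coords <- array(0, dim = c(n_beads, 3L, nf))
  for (i in seq_len(nf)) {
    h <- strsplit(trimws(lines[header_idx[i]]), "\\s+")[[1]]
    times[i] <- as.numeric(h[2])
    box[i, ] <- as.numeric(h[4:6])
    block <- lines[(header_idx[i] + 1L):(header_idx[i] + n_beads)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"),
                                  use.names = FALSE)),
                ncol = 3L, byrow = TRUE)
    coords[, , i] <- m
  }
  cg_trajectory(times, coords, box)
}

classify_beads <- function(atoms, species_config, allow_unknown = FALSE) {
  known <- names(species_config)
  unknown <- setdiff(unique(atoms$residue_name), known)
  if (length(unknown) > 0L && !allow_unknown) {
    stop("unknown residue name(s) without allow_unknown: ",
         paste(unknown, collapse = ", "))
  }
  species <- character(nrow(atoms))
  is_head <- logical(nrow(atoms))
  is_tail <- logical(nrow(atoms))
  for (rn in intersect(unique(atoms$residue_name), known)) {
    sel <- atoms$residue_name == rn
    cfg <- species_config[[rn]]
    species[sel] <- cfg$species
    is_head[sel] <- atoms$name[sel] %in% cfg$headgroup_beads
    is_tail[sel] <- atoms$name[sel] %in% cfg$tail_terminal_beads
  }
  species[atoms$residue_name %in% unknown] <- "SOLVENT"
  list(species = species, is_headgroup = is_head, is_tail_terminal = is_tail)
}

#' Read a structure plus trajectory into a topology and trajectory
#'
#' Accepts a GRO or PDB structure and a trajectory in the plain-text fixture
#' format or DCD (via bio3d).  Every bead is classified by species via the
#' species configuration; molecules are inferred from runs of identical
#' residue ids.
#'
#' @param structure_path GRO or PDB file
#' @param trajectory_path fixture `.trj`/`.txt` or `.dcd` file; `NULL` to use
#'   the structure as a single frame (box from the structure)
#' @param species_config named list, see [default_species_config()]
#' @param allow_unknown classify unknown residue names as SOLVENT instead of
#'   erroring
#' @param dt_frame frame spacing in ns used for DCD input (DCD carries no
#'   physical time base)
#' @return list with `topology` (`cg_topology`) and `trajectory`
#'   (`cg_trajectory`)
#' @export
read_system <- function(structure_path, trajectory_path = NULL,
                        species_config = default_species_config(),
                        allow_unknown = FALSE, dt_frame = 1) {
  ext <- tolower(tools::file_ext(structure_path))
  if (ext == "gro") {
    s <- read_gro(structure_path)
  } else if (ext == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("reading PDB requires the bio3d package")
    }
    p <- bio3d::read.pdb(structure_path)
    a <- p$atom
    s <- list(atoms = data.frame(residue_id = a$resno, residue_name = a$resid,
                                 name = a$elety, atom_id = a$eleno,
                                 stringsAsFactors = FALSE),
              xyz = cbind(a$x, a$y, a$z) / 10,  # Angstrom -> nm
              box = rep(NA_real_, 3))
  } else {
    stop("unsupported structure format: .", ext, " (use GRO or PDB)")
  }
  cls <- classify_beads(s$atoms, species_config, allow_unknown)
  # molecule = maximal run of constant residue_id for lipids/solvent; protein
  # molecules = runs of constant (residue_name %in% AA) chain ... simplest
  # robust rule for CG files: a new molecule starts when residue_id decreases
  # or when species changes between non-protein residues; for protein,
  # consecutive amino-acid residues belong to one molecule (chain).
  n <- nrow(s$atoms)
  new_res <- c(TRUE, s$atoms$residue_id[-1] != s$atoms$residue_id[-n])
  is_prot <- cls$species == "PROTEIN"
  new_mol <- new_res & !(is_prot & c(FALSE, is_prot[-n]))
  molecule_id <- cumsum(new_mol)
  beads <- data.frame(
    bead_id = seq_len(n) - 1L,
    name = s$atoms$name,
    residue_id = s$atoms$residue_id,
    residue_name = s$atoms$residue_name,
    molecule_id = molecule_id,
    subunit = ifelse(is_prot, paste0("CH", molecule_id), "LIPID"),
    species = cls$species,
    is_headgroup = cls$is_headgroup,
    is_tail_terminal = cls$is_tail_terminal,
    is_cocrystallized = FALSE,
    stringsAsFactors = FALSE
  )
  prot_mols <- unique(molecule_id[is_prot])
  monomer_map <- NULL
  if (length(prot_mols) > 0L) {
    monomer_map <- stats::setNames(rep("none", length(prot_mols)),
                                   as.character(prot_mols))
  }
  topo <- cg_topology(beads, monomer_map = monomer_map, c2_axis = NULL)

  if (is.null(trajectory_path)) {
    if (any(is.na(s$box))) stop("structure has no box; supply a trajectory")
    traj <- cg_trajectory(0, array(s$xyz, dim = c(n, 3L, 1L)),
                          matrix(s$box, 1L))
  } else {
    text <- tolower(tools::file_ext(trajectory_path))
    if (text == "dcd") {
      if (!requireNamespace("bio3d", quietly = TRUE)) {
        stop("reading DCD requires the bio3d package")
      }
      x <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      nb <- ncol(x) / 3L
      if (nb != n) {
        stop("trajectory/structure bead count mismatch: ", nb, " vs ", n)
      }
      nf <- nrow(x)
      coords <- array(0, dim = c(n, 3L, nf))
      for (i in seq_len(nf)) {
        coords[, , i] <- matrix(x[i, ], ncol = 3L, byrow = TRUE) / 10
      }
      traj <- cg_trajectory(seq(0, by = dt_frame, length.out = nf), coords,
                            matrix(rep(s$box, nf), nf, 3, byrow = TRUE))
    } else {
      traj <- read_fixture_trajectory(trajectory_path, n)
    }
  }
  list(topology = topo, trajectory = traj)
}
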