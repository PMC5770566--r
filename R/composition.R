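# Binding-site residue composition via contact phrases.
#
# A "phrase" is the set of protein (or cofactor) residues found within a
# cutoff of a lipid headgroup at one sampled time point.  Phrases are
# clustered with a GROMOS-like greedy algorithm; residues present in at
# least a presence fraction of a cluster's phrases form the consensus
# binding-site composition, which is normalized against the composition of
# all residues that ever contact any lipid headgroup.

#' Build contact phrases
#'
#' At `interval`-spaced time points, for every selected lipid, collect the
#' residues with any bead within `cutoff` (minimum-image) of any headgroup
#' bead of the lipid.  Phrases with fewer than `min_len` residues are
#' dropped.  Contact is inclusive at the cutoff (d <= cutoff).
#'
#' @param traj a `cg_trajectory`
#' @param topology a `cg_topology`
#' @param lipid_molecules molecule ids of the lipids to scan (default: all
#'   lipids)
#' @param cutoff contact cutoff, nm (default 0.8)
#' @param interval sampling interval, ns (default 10); must not be smaller
#'   than the frame spacing
#' @param min_len minimum residues per phrase (default 5)
#' @param residue_species species whose residues can appear in phrases
#'   (default PROTEIN and COFACTOR; cofactors are ordinary residues here)
#' @return data.frame of class `phrase_set` with columns `lipid_id`,
#'   `species`, `time` and a list-column `residues` (character vectors
#'   "subunit|residue_id|residue_name")
#' @export
build_phrases <- function(traj, topology, lipid_molecules = NULL,
                          cutoff = 0.8, interval = 10, min_len = 5L,
                          residue_species = c("PROTEIN", "COFACTOR")) {
  b <- topology$beads
  dt <- if (n_frames(traj) > 1L) diff(traj$times[1:2]) else interval
  if (interval < dt) {
    stop("sampling interval (", interval, " ns) is smaller than the frame ",
         "spacing (", dt, " ns)")
  }
  if (is.null(lipid_molecules)) {
    lipid_molecules <- unique(b$molecule_id[b$is_headgroup])
  }
  head_rows <- which(b$is_headgroup & b$molecule_id %in% lipid_molecules)
  head_mol <- b$molecule_id[head_rows]
  res_rows <- which(b$species %in% residue_species)
  if (length(res_rows) == 0L) stop("no residue beads of species ",
                                   paste(residue_species, collapse = "/"))
  res_key <- paste(b$subunit[res_rows], b$residue_id[res_rows],
                   b$residue_name[res_rows], sep = "|")
  rel <- (traj$times - traj$times[1]) / interval
  sample_frames <- which(abs(rel - round(rel)) < 1e-6)
  out <- list()
  for (f in sample_frames) {
    box <- traj$box[f, ]
    H <- frame_coords(traj, head_rows, f)
    Rb <- frame_coords(traj, res_rows, f)
    # cheap prefilter: only lipids inside the residue bounding box (expanded
    # by the cutoff, PBC-aware via wrapped comparison) can be in contact
    near <- rep(TRUE, nrow(H))
    for (k in 1:3) {
      lo <- min(Rb[, k]) - cutoff; hi <- max(Rb[, k]) + cutoff
      if (hi - lo < box[k]) near <- near & H[, k] >= lo & H[, k] <= hi
    }
    cand <- which(near)
    if (length(cand) == 0L) next
    D <- cross_dist(H[cand, , drop = FALSE], Rb, box)
    hits <- which(D <= cutoff, arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    by_lipid <- split(hits[, 2], hits[, 1])
    for (nm in names(by_lipid)) {
      li <- cand[as.integer(nm)]
      res <- unique(res_key[by_lipid[[nm]]])
      if (length(res) < min_len) next
      out[[length(out) + 1L]] <- list(
        lipid_id = head_mol[li],
        species = b$species[head_rows[li]],
        time = traj$times[f],
        residues = res)
    }
  }
  df <- data.frame(
    lipid_id = vapply(out, `[[`, numeric(1), "lipid_id"),
    species = vapply(out, `[[`, character(1), "species"),
    time = vapply(out, `[[`, numeric(1), "time"))
  df$residues <- lapply(out, `[[`, "residues")
  class(df) <- c("phrase_set", class(df))
  df
}

# shared-residue fraction between two phrases; denominator = min set size
# by default (a short phrase wholly inside a long one clusters with it),
# or Jaccard
overlap_fraction <- function(p, q, method = c("min", "jaccard")) {
  method <- match.arg(method)
  inter <- length(intersect(p, q))
  if (method == "min") inter / min(length(p), length(q))
  else inter / length(union(p, q))
}

#' Cluster phrases with a GROMOS-like greedy algorithm
#'
#' All phrases start in a pool.  Repeatedly, the phrase with the most
#' neighbours (a neighbour shares at least `overlap_fraction` of its
#' residues with the centre, evaluated centre-vs-candidate) is taken as a
#' cluster centre; the centre and its neighbours are removed as one
#' cluster; this repeats until the pool is empty, so the clusters partition
#' the pool.  Ties for the biggest cluster are broken by the smallest
#' centre index.
#'
#' @param phrases a `phrase_set` (or plain list of residue-id character
#'   vectors)
#' @param overlap_fraction minimum shared-residue fraction (default 0.70)
#' @param method overlap denominator: `"min"` (default; |P.Q| /
#'   min(|P|,|Q|)) or `"jaccard"`
#' @return list of clusters; each a list with `members` (indices into the
#'   input), `centre` (index), `size`, `phrases` (the member residue sets)
#' @export
cluster_phrases <- function(phrases, overlap_fraction = 0.70,
                            method = c("min", "jaccard")) {
  method <- match.arg(method)
  sets <- phrase_residue_sets(phrases)
  n <- length(sets)
  if (n == 0L) return(list())
  # shared-residue counts for all phrase pairs via a sparse incidence
  # matrix; phrase pools grow with trajectory length, so the O(n^2)
  # all-pairs set intersection is avoided
  res_levels <- unique(unlist(sets, use.names = FALSE))
  sizes <- lengths(sets)
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(n), sizes),
    j = match(unlist(sets, use.names = FALSE), res_levels),
    x = 1, dims = c(n, length(res_levels)))
  S <- Matrix::tcrossprod(M)
  trip <- Matrix::summary(S)
  denom <- if (method == "min") {
    pmin(sizes[trip$i], sizes[trip$j])
  } else {
    sizes[trip$i] + sizes[trip$j] - trip$x
  }
  is_nbr <- trip$x / denom >= overlap_fraction
  # S is stored as one triangle of a symmetric matrix; mirror the pairs
  off_diag <- is_nbr & trip$i != trip$j
  ii <- c(trip$i[is_nbr], trip$j[off_diag])
  jj <- c(trip$j[is_nbr], trip$i[off_diag])
  adj <- split(jj, factor(ii, levels = seq_len(n)))
  active <- rep(TRUE, n)
  counts <- lengths(adj)  # includes self (diagonal of S is always a neighbour)
  clusters <- list()
  remaining <- n
  while (remaining > 0L) {
    counts_masked <- ifelse(active, counts, -1L)
    centre <- which.max(counts_masked)  # first max = smallest phrase index
    members <- adj[[centre]]
    members <- members[active[members]]
    clusters[[length(clusters) + 1L]] <-
      list(members = members, centre = centre, size = length(members),
           phrases = sets[members])
    active[members] <- FALSE
    remaining <- remaining - length(members)
    for (r in members) {
      nb <- adj[[r]]
      counts[nb] <- counts[nb] - 1L
    }
  }
  clusters
}

overlap_fraction_pair <- function(p, q, method) {
  inter <- length(intersect(p, q))
  if (method == "min") inter / min(length(p), length(q))
  else inter / length(union(p, q))
}

phrase_residue_sets <- function(phrases) {
  if (inherits(phrases, "phrase_set") || is.data.frame(phrases)) {
    phrases$residues
  } else {
    phrases
  }
}

#' Consensus residue set of a phrase cluster
#'
#' Residues present in at least `presence_fraction` of the cluster's
#' phrases (inclusive), minus any explicitly configured manual exclusions.
#' Manual exclusions mirror a visual-curation step: they are declarative
#' and recorded in the output, never silent.
#'
#' @param cluster one cluster from [cluster_phrases()]
#' @param presence_fraction minimum presence (default 0.80)
#' @param manual_exclusions character vector of residue keys to drop
#' @return data.frame with `residue` (key "subunit|id|name"), `presence`
#'   (fraction of member phrases containing it) and `excluded` (TRUE for
#'   manually excluded residues, which are reported but flagged)
#' @export
consensus_site <- function(cluster, presence_fraction = 0.80,
                           manual_exclusions = character()) {
  stopifnot(cluster$size >= 1L)
  tab <- table(unlist(cluster$phrases, use.names = FALSE))
  presence <- as.numeric(tab) / cluster$size
  keep <- presence >= presence_fraction
  res <- names(tab)[keep]
  out <- data.frame(residue = res, presence = presence[keep],
                    excluded = res %in% manual_exclusions,
                    stringsAsFactors = FALSE)
  out[order(-out$presence, out$residue), , drop = FALSE]
}

#' Consensus residues of a site, combined over monomers
#'
#' The per-monomer consensus sets are combined by set union (e.g. one
#' monomer giving {Arg, Lys, Tyr} and the other {Lys, Tyr, Asn} yields
#' {Arg, Lys, Tyr, Asn}).
#'
#' @param consensus_a,consensus_b data.frames from [consensus_site()]
#' @return character vector of residue keys (manual exclusions dropped)
#' @export
combine_monomer_consensus <- function(consensus_a, consensus_b) {
  keep <- function(x) x$residue[!x$excluded]
  sort(union(keep(consensus_a), keep(consensus_b)))
}

#' Residue-type composition profile of binding sites
#'
#' Counts residue types (3-letter names; cofactors are residue types too)
#' over the supplied consensus residue sets, as percentages and normalized
#' against a background composition (residues in contact with any lipid
#' headgroup during the simulation).  A normalized occurrence > 1 indicates
#' a preference for that residue type in binding sites.
#'
#' @param site_residues character vector (or list of vectors, concatenated)
#'   of residue keys "subunit|id|name"
#' @param background character vector of residue keys, or named counts per
#'   residue type
#' @param uncertainty optional list of per-sample residue-key vectors (e.g.
#'   3 time blocks x 2 monomers = 6 quasi-independent samples); adds a
#'   per-type standard deviation of the percentage.  Blocks of one long
#'   correlated trajectory are not independent, so treat this as an
#'   indication only.
#' @return data.frame of class `composition_profile`: `residue_type`,
#'   `count`, `percent`, `normalized` (+Inf, with a warning, for types
#'   absent from the background), and `percent_sd` when `uncertainty` given
#' @export
composition_profile <- function(site_residues, background,
                                uncertainty = NULL) {
  res_type <- function(keys) vapply(strsplit(keys, "|", fixed = TRUE),
                                    `[[`, character(1), 3L)
  keys <- unlist(site_residues, use.names = FALSE)
  counts <- table(res_type(keys))
  if (is.character(background)) {
    bg <- table(res_type(unique(background)))
  } else {
    bg <- background
  }
  types <- names(counts)
  count <- as.numeric(counts)
  percent <- 100 * count / sum(count)
  bg_frac <- as.numeric(bg[types]) / sum(bg)
  normalized <- (count / sum(count)) / bg_frac
  if (any(is.na(bg_frac) | bg_frac == 0)) {
    missing <- types[is.na(bg_frac) | bg_frac == 0]
    warning("residue type(s) absent from background: ",
            paste(missing, collapse = ", "), " (normalized set to +Inf)")
    normalized[is.na(bg_frac) | bg_frac == 0] <- Inf
  }
  out <- data.frame(residue_type = types, count = count, percent = percent,
                    normalized = normalized, stringsAsFactors = FALSE)
  if (!is.null(uncertainty)) {
    per_sample <- vapply(uncertainty, function(s) {
      tt <- table(factor(res_type(unlist(s, use.names = FALSE)),
                         levels = types))
      100 * as.numeric(tt) / max(sum(tt), 1L)
    }, numeric(length(types)))
    out$percent_sd <- apply(matrix(per_sample, nrow = length(types)), 1,
                            stats::sd)
  }
  class(out) <- c("composition_profile", class(out))
  out
}

#' Background residue set: residues ever in contact with any lipid headgroup
#'
#' @param traj a `cg_trajectory`
#' @param topology a `cg_topology`
#' @param cutoff contact cutoff, nm
#' @param interval sampling interval, ns
#' @return character vector of residue keys
#' @export
background_contacts <- function(traj, topology, cutoff = 0.8, interval = 10) {
  phrases <- build_phrases(traj, topology, cutoff = cutoff,
                           interval = interval, min_len = 1L)
  unique(unlist(phrases$residues, use.names = FALSE))
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("Binding-site composition (", sum(x$count), " residues):\n", sep = "")
  print.data.frame(head(x[order(-x$normalized), ], 10), row.names = FALSE,
                   digits = 3)
  invisible(x)
}
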