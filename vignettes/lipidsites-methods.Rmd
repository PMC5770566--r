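---
title: "Lipid binding-site analysis for coarse-grained membrane simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid binding-site analysis for coarse-grained membrane simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsites)
```

## Scope and model of the data

`lipidsites` analyses lipid–protein interactions in coarse-grained (CG)
molecular dynamics trajectories of membrane protein complexes, with the
homodimeric, C2-symmetric case (such as Photosystem II in a thylakoid
membrane of MGDG, DGDG, SQDG and PG lipids) as the motivating system.  A
system is a `cg_topology` (one row per bead, with species, residue,
subunit, headgroup and tail-terminal flags, a monomer map and a two-fold
symmetry axis) plus a `cg_trajectory` (dense bead × coordinate × frame
array with per-frame orthorhombic boxes).  Internal units are fixed:
lengths in nm, times in ns, membrane normal along z, stromal side at +z.
The lipid position proxy is the Martini GL1 glycerol bead throughout.

The pipeline has five analysis stages, each usable on its own:

1. **Density maps** (`compute_density_map`, `quadruple_and_center`):
   per-species, per-leaflet lateral histograms of GL1 positions,
   normalized by the mean over all bins so that 1 equals the bulk density
   of that species in the membrane plane.  To remove periodic-boundary
   artifacts the box can be replicated 2×2 in-plane, the protein image
   nearest the enlarged box centre selected, and every frame rigidly
   fitted (Kabsch superposition of the protein backbone beads; full 3D by
   default, in-plane-only as an option) onto a centred reference.
2. **Binding sites** (`compute_occupancy_grid`, `extract_sites`,
   `symmetry_filter`, `detect_binding_sites`): a 3D grid (0.2 nm voxels by
   default) stores the fraction of frames in which at least one headgroup
   bead of the species occupies each voxel.  Candidate sites are maximal
   26-connected voxel components at or above a per-species occupancy
   threshold (36% MGDG, 6% PG, 45% DGDG, 30% SQDG by default); components
   below `min_voxels = 2` are treated as noise.  Only sites observed in
   both monomers survive: each blob centroid is mapped through the C2
   rotation and must find a same-species, same-leaflet partner within
   0.5 nm.  Kept pairs are named by species letter, membrane side and
   rank by peak occupancy (e.g. `MS1`), with `*`/`#` marking the two
   monomers.
3. **Site composition** (`build_phrases`, `cluster_phrases`,
   `consensus_site`, `composition_profile`): at 10 ns intervals, each
   lipid near the protein contributes a *phrase* — the set of residues
   (cofactors included) with any bead within 0.8 nm of the lipid
   headgroup; phrases shorter than 5 residues are discarded.  Phrases are
   clustered with a GROMOS-style greedy algorithm: the phrase with the
   most neighbours (≥ 70% shared residues) seeds a cluster, the cluster is
   removed, and the process repeats, so clusters partition the pool.
   Residues present in at least 80% of a cluster's phrases form the
   consensus composition; per-monomer consensus sets combine by union.
   Compositions are reported as percentages and normalized by the
   composition of all residues ever in headgroup contact, so values > 1
   indicate preferential enrichment in sites.
4. **Residence kinetics** (`track_contacts`, `summarize_residence`): a
   dual-cutoff state machine per (lipid, site): binding starts once the
   headgroup is within 0.6 nm of at least 20% of the site beads, and ends
   only when it is beyond 1.6 nm of all of them, suppressing
   "rattling-in-a-cage" re-binding artifacts.  Episodes shorter than
   100 ns are treated as bypassing lipids; episodes still running at the
   trajectory end are censored, and censored episodes longer than 50 μs
   are excluded from the reported mean because their durations are only
   lower bounds.  Histograms are log-binned (3 bins/decade), as counts and
   as total bound time, with censored-containing bins flagged.
5. **Cavity exchange** (`detect_exchange_events`, `compute_flux`,
   `cavity_composition_timeseries`, `classify_cocryst_mobility`): the
   exchange cavity of each monomer is a configured lateral region with
   named channel apertures.  Inside/outside transitions must persist for
   50 ns (debouncing boundary flicker); each crossing is assigned to the
   nearest aperture within 1 nm, otherwise "unassigned".  Fluxes are
   events · monomer⁻¹ · ms⁻¹, exact up to the unit conversion.  Mobility
   of cocrystallized lipids is classified from maximum sustained headgroup
   displacement using explicit thresholds (none < 0.5 nm ≤ limited <
   1.5 nm ≤ large; escape beyond 3 nm sustained ≥ 1 μs; exchange when an
   escaped lipid is replaced by a same-species lipid dwelling within
   0.8 nm for ≥ 1 μs).

`run_pipeline()` wires the stages together behind a validated
configuration (`run_config`), stamps every artifact with a configuration
hash, and is byte-for-byte reproducible under a fixed seed.

## Interpretation choices the source methods leave open

Several parts of the published procedure this package systematizes are
described only qualitatively; the package fixes them as explicit,
documented choices:

- **Blob extraction.** Iso-occupancy sites are usually read visually from
  rendered surfaces.  Here they are maximal connected voxel components;
  26-connectivity is the default (6-connectivity available), and a
  two-voxel minimum suppresses single-voxel noise.
- **Phrase overlap denominator.** "70% of the residues in common" is
  implemented as |P∩Q| / min(|P|, |Q|), so that a short phrase wholly
  contained in a longer one clusters with it; Jaccard overlap is available
  via `method = "jaccard"`.  This is the single most consequential
  ambiguity in the composition stage.  Ties for the biggest cluster break
  toward the smallest centre-phrase index, and the 70% criterion is
  evaluated centre-vs-candidate, the standard greedy formulation.
- **Manual curation.** Published compositions removed residues judged to
  be algorithmic bycatch.  The package reproduces this as a declarative
  `manual_exclusions` list whose effect is recorded in the output — never
  a silent heuristic.
- **The 20% bead-contact threshold** for binding onset applies at the
  inner cutoff and at onset only; release is governed solely by the outer
  cutoff.  Site beads are all beads of the consensus residues.
- **Cavity geometry** is pure configuration: the published analysis
  locates the cavity structurally but gives no coordinates, so for real
  systems the region must be supplied by the user; synthetic runs use the
  generator's geometry.  Mobility classes replace visual inspection with
  the thresholds above, keeping the published class names.
- **Uncertainty of compositions** uses 3 time blocks × 2 monomers = 6
  quasi-independent samples; with correlation times comparable to the
  trajectory length this is an indication, not a robust error bar, and is
  reported as such.

## The synthetic membrane generator

Because no suitable CG trajectory of a dimeric membrane protein is
deposited at analysis scale, every stage is validated against a
Brownian-dynamics generator (`generate_trajectory`) with exactly known
ground truth.  Its defaults are the study conditions:

- **Composition** 40/25/15/10/10 mol % MGDG / DGDG / singly-unsaturated
  SQDG / saturated SQDG / PG, split evenly over the leaflets.
- **Diffusion** D = 0.05 nm²/ns so that a 1 nm lateral displacement takes
  on average 5 ns (2D first-passage: E[T] = r²/4D).
- **Default system size** 800 lipids in a 26 × 26 nm box (≈ 1.7 nm² per
  lipid per leaflet, a realistic bilayer packing once the protein
  footprint is subtracted); 2–8 μs of trajectory at 2 ns/frame for
  site-detection and kinetics scenarios.
- **Protein** a static, exactly C2-symmetric toy dimer: two rings of
  backbone beads (60 angular positions × 7 z-layers per monomer, one fake
  residue per bead cycled over the 20 amino acids) with a lateral
  exclusion disc per monomer.  A static protein makes the raw trajectory
  already protein-fitted, while the fitting machinery is exercised by
  constructed-transform tests.
- **Binding sites** are Markov traps: a free lipid of the target species
  inside the capture radius binds with probability `k_on` per step; a
  bound lipid is tethered near the site centre and unbinds with
  probability 1 − exp(−k_off·Δt) per step, giving geometric (discretized
  exponential) dwell times with mean Δt/(1 − exp(−k_off·Δt)) — 501 ns at
  the standard k_off = 0.002 ns⁻¹ and Δt = 2 ns.  Two release modes
  exist: `eject` (default) re-injects released lipids uniformly into the
  bulk so successive episodes are independent — the clean regime for
  residence-time recovery; `in_place` releases them where they are, which
  preserves local detailed balance so the stationary capture-disc
  enrichment equals `expected_enrichment()` (1 + k_on/p_off for an
  uncapacitated trap; a birth–death stationary law for finite capacity).
  With ejection the trap locally depletes the free pool and realized
  enrichment is lower than the formula — a deliberate trade-off,
  documented here, between kinetic and thermodynamic fidelity.
- **Exchange cavities** are lateral discs anchored to each monomer,
  impenetrable except at channel apertures that are open with a
  configured probability per frame (defaults: channel I rarely, II never,
  III most often, so that channel III dominates the traffic).  Every
  boundary crossing is logged to the ground truth; with all channels
  closed the cavity composition is exactly conserved.

What the generator does *not* emulate: membrane elasticity and curvature,
lipid flip-flop, protein flexibility, solvent and ions, non-ideal mixing,
and any energetic realism — binding is a Markov process, not a potential
well.  Passing tests therefore demonstrate that the *analysis* recovers
planted truth under controlled conditions, not that the physics of a real
thylakoid membrane is reproduced.

## Estimators and numerical choices

- **Censoring-aware residence means.**  Restricting to completed binding
  episodes length-biases the sample short (long dwells are preferentially
  censored by the end of a finite trajectory).  `summarize_residence`
  therefore reports, besides the published-style filtered mean and SD, the
  mean excess over the duration filter and the censoring-corrected
  exponential maximum-likelihood estimate (total excess time at risk /
  number of observed releases).  On synthetic runs the MLE recovers the
  planted 500 ns dwell time within sampling error, while the raw filtered
  mean sits ≈ 100 ns higher (memoryless shift), matching theory.
- **First-passage times on a frame grid** are systematically late because
  the sampled path overshoots the threshold between frames.
  `mean_first_passage` lowers the detection threshold by the expected
  Gaussian-walk overshoot, 0.5826 × step SD (Siegmund's corrected
  diffusion approximation); at Δt = 0.1 ns this removes a ≈ 12% upward
  bias and the 5 ns expectation is recovered within a few percent.
- **Minimum-image convention** puts each displacement component in
  [−edge/2, +edge/2); boxes are orthorhombic only and triclinic input is
  rejected loudly.
- **Kabsch fits** use the SVD construction with the determinant
  correction against reflections; selections with fewer than three
  non-collinear beads are rejected.  Fitting is idempotent to < 1e−9 nm.
- **Normalization of density maps** averages over *all* bins, including
  the protein footprint where lipid density is ≈ 0; this reads the bulk
  plateau slightly above 1, matching the published rendering convention.
  `exclude_footprint = TRUE` averages over non-empty bins instead.  The
  2D bin size (0.25 nm default) is configurable since only the 3D grid
  resolution is prescribed by the source method.  Stored grids are never
  capped; the factor-2 cap is a plotting option.
- **Greedy clustering at scale** uses a sparse phrase × residue incidence
  matrix to obtain all pairwise shared-residue counts, then the greedy
  extraction on adjacency lists; results are identical (tested) to the
  naive all-pairs formulation, which serves as the oracle on small pools.
- **Degenerate inputs**: empty species selections, empty site bead sets,
  inner > outer cutoffs, overlapping cavity regions, triclinic boxes,
  sampling intervals finer than the frame spacing, and structure /
  trajectory bead-count mismatches all fail with specific messages rather
  than propagating nonsense.

## Validation scheme and problem sizes

The test suite validates each stage in three ways: hand-computable
examples (including the published worked arithmetic: 9 entries / 7 exits
over 87.7 μs and 2 monomers → 51 and 40 events · monomer⁻¹ · ms⁻¹; one
residue among 81 or 39 → 1.2% or 2.6%; cavity composition (3,2,2,2) →
(3.0,1.5,3.2,2.5) → +1.2 lipids), independent brute-force oracles
(per-voxel occupancy recount, exhaustive flood-fill components, naive
greedy clustering, single-cutoff tracking as the inner = outer limit), and
parameter recovery on the synthetic scenarios (three mirrored MGDG traps
plus two asymmetric decoys: exactly three symmetric pairs detected with
centroids within 0.3 nm of the planted positions and the decoys rejected;
dwell-time and diffusion recovery as above; entry−exit counts equal to
occupancy changes on every cavity run).

The standard scenarios use 800 lipids, 4000 frames × 2 ns (sites and
kinetics), 3000 frames × 2 ns (cavities) and 500 lipids × 1200 frames ×
0.1 ns (free diffusion).  These sizes put ≈ 300–700 binding episodes and
≈ 50–100 cavity crossings into each run — enough that three-standard-error
recovery bounds are meaningful — while a full suite run stays in the
minutes range on a single core.

## Known limitations

- The C2 machinery assumes the symmetry axis is the membrane normal
  (appropriate for membrane-embedded dimers); arbitrary axes are not
  supported.
- Leaflet assignment is geometric (headgroup vs. tail-terminal midplane
  median, re-evaluated per frame); strongly curved or vesicular membranes
  would need a different assignment.
- Trajectory input is GRO/PDB structure + plain-text fixture format or
  DCD; XTC/TRR are not read natively.
- The residence-time machinery reports estimators but no survival-model
  fits (Kaplan–Meier, multi-exponential mixtures are out of scope).
- The synthetic generator is two-dimensional per leaflet; z coordinates
  are fixed offsets, so flip-flop and interdigitation cannot be studied
  with it.
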