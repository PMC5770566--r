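# lipidsites

Lipid–protein interaction analysis for coarse-grained (CG) molecular
dynamics trajectories of membrane protein complexes — built for the
question of *where and how specifically lipids bind* to a large,
two-fold-symmetric complex such as the Photosystem II dimer in a
thylakoid membrane (MGDG, DGDG, SQDG, PG).  It is aimed at simulators
who have a CG trajectory (or want a controlled synthetic one) and need
reproducible, scriptable versions of the standard lipid-fingerprinting
analyses instead of one-off visual inspection.

The package implements five connected analyses:

- **Bulk-normalized lipid density maps.**  Per species `s` and leaflet,
  the lateral density `ρ_s(x, y)` of the GL1 glycerol bead, divided by
  its mean over the membrane plane, after 2×2 box replication and rigid
  (Kabsch) fitting of every frame on the protein backbone; 1 = bulk
  density.
- **Iso-occupancy binding sites with a C2 dimer filter.**  A 3D voxel
  grid (0.2 nm) of the fraction of frames each voxel holds a headgroup
  bead; candidate sites are 26-connected components above a per-species
  threshold (MGDG 36%, PG 6%, DGDG 45%, SQDG 30%), and only sites whose
  C2 image finds a partner in the other monomer are kept (named `MS1`,
  `SL2`, ..., with `*`/`#` for the two monomers).
- **Binding-site composition from contact phrases.**  Phrases (residues
  within 0.8 nm of a lipid headgroup, sampled every 10 ns, ≥ 5 residues)
  are clustered with a GROMOS-style greedy algorithm (≥ 70% shared
  residues); residues in ≥ 80% of a cluster's phrases form the consensus
  site, and compositions are normalized against all lipid-contacting
  residues (normalized occurrence > 1 ⇒ enrichment).
- **Dual-cutoff residence kinetics.**  A lipid binds a site when within
  0.6 nm of ≥ 20% of the site beads and unbinds only beyond 1.6 nm of
  all of them (suppressing rattling artifacts); events ≥ 100 ns enter
  the statistics, censored events > 50 μs are excluded from means, and
  log-binned count and total-bound-time histograms are produced,
  together with a censoring-corrected exponential MLE of the mean
  residence time.
- **Cavity exchange.**  Entry/exit events for a configured exchange
  cavity per monomer with hysteresis debouncing, channel assignment,
  fluxes in events·monomer⁻¹·ms⁻¹, per-species composition time series,
  and mobility classes (none/limited/large/escape/exchange) for
  cocrystallized lipids.

A Brownian-dynamics **synthetic membrane generator** with planted,
exactly known ground truth (binding sites as Markov traps, gated exchange
cavities, thylakoid composition 40/25/15/10/10 mol %, D = 0.05 nm²/ns)
backs the test suite and provides worked examples; see the methods
vignette (`vignettes/lipidsites-methods.Rmd`) for the model, estimator
and design details.

## Worked example

Simulate a dimer membrane with three mirrored MGDG binding sites and two
asymmetric decoy attractors, then detect sites and measure kinetics:

```r
library(lipidsites)

site <- function(p, lf, mirror = TRUE)
  planted_site(p, leaflet = lf, k_on = 1, k_off = 0.002,   # 500 ns dwells
               capacity = 10, tether_sd = 0.09, mirror = mirror)

cfg <- synthetic_config(
  total_lipids = 800, n_frames = 4000, dt_frame = 2,
  planted_sites = list(site(c(7.2, 13.0), "stromal"),
                       site(c(9.6, 10.6), "stromal"),
                       site(c(9.6, 15.4), "lumenal"),
                       site(c(7.0, 9.0),  "stromal", mirror = FALSE),
                       site(c(18.0, 16.0), "lumenal", mirror = FALSE)),
  seed = 1)
run <- generate_trajectory(cfg)

found <- rbind(
  detect_binding_sites(run$trajectory, run$topology, "MGDG", "stromal"),
  detect_binding_sites(run$trajectory, run$topology, "MGDG", "lumenal"))
found[, c("label", "monomer", "x", "y", "peak_occupancy")]
#>   label monomer    x    y peak_occupancy
#> 1  MS1#       B 18.8 13.0        0.80575
#> 2  MS1*       A  7.2 13.0        0.73725
#> 3  MS2#       B 16.4 15.4        0.66650
#> 4  MS2*       A  9.6 10.6        0.64275
#> 5  ML1*       A  9.6 15.4        0.81225
#> 6  ML1#       B 16.4 10.6        0.76175
```

The three planted pairs come back with mirrored coordinates (the decoys,
present as blobs, are rejected for lacking a C2 partner).  Residence
kinetics at the planted sites:

```r
gt <- run$ground_truth$sites
ev <- do.call(rbind, lapply(which(gt$pair_id <= 3), function(s)
  track_contacts(run$trajectory, run$topology, gt$site_bead_rows[[s]],
                 site_id = paste0("S", s), species = "MGDG", sampling = 2)))
summarize_residence(ev, min_duration = 100)
#> Residence summary: 449 events (duration >= 100 ns); 0 censored-long excluded
#>   mean 0.584 us (sd 0.457 us); filter-corrected mean 0.484 us
```

The censoring-corrected MLE (`$exp_mle_mean_ns`, here 517 ns with a
standard error of ≈ 25 ns) recovers the planted 500 ns mean dwell; the
raw filtered mean sits ≈ 100 ns higher, as expected for exponential
dwells passed through a 100 ns duration filter.  Flux arithmetic for a
cavity with 9 entries and 7 exits over 87.7 μs of dimer trajectory:

```r
compute_flux(c(entry = 9, exit = 7), analysis_duration_us = 87.7, n_monomers = 2)
#>    entry     exit
#> 51.31129 39.90878
```

i.e. 51 entrance and 40 exit events per monomer per millisecond.

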