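Package: lipidsites
Title: Lipid Binding Site Analysis for Coarse-Grained Membrane Protein Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for lipid-protein interactions in coarse-grained
    molecular dynamics trajectories of membrane protein complexes. Computes
    per-leaflet lipid density maps normalized to bulk density, detects lipid
    binding sites as connected regions of high time-averaged headgroup
    occupancy with a two-fold (C2) dimer-symmetry filter, determines binding
    site residue composition via contact phrases and GROMOS-style greedy
    clustering, measures residence-time kinetics with a dual-cutoff contact
    tracker, and quantifies lipid exchange between a protein cavity and the
    bulk membrane (entry/exit events, channel assignment, flux, composition
    time series, mobility classes). Includes a Brownian-dynamics synthetic
    membrane generator with planted binding sites and gated cavities that
    provides ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
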