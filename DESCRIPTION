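Package: sapomem
Title: Saponin-Sterol Membrane Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of saponin-sterol membrane interactions,
    combining trajectory-derived metrics from coarse bilayer coordinate files
    (lateral two-dimensional sterol radial distribution functions with
    first-peak detection, cumulative sterol density maps, leaflet assignment,
    saponin membrane-insertion classification, Shrake-Rupley solvent
    accessible surface area, geometric hydrogen-bond counting, and pairwise
    Lennard-Jones/Coulomb nonbonded energies) with plate-assay metrics
    (dilution-corrected calcein release, four-parameter logistic EC50
    estimation with profile-likelihood confidence intervals and censoring,
    propidium-iodide lysis fractions, internal-standard quantification,
    membrane partition profiles, and group-comparison statistics). A
    synthetic-data module generates toy bilayer trajectories, clustered
    sterol point patterns, two-state saponin binding schedules, and assay
    tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
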