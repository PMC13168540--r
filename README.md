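# sapomem

Quantitative analysis of saponin–sterol membrane interactions.

Saponins — amphiphilic plant glycosides built from a hydrophobic
triterpenoid or steroidal aglycone and one or two sugar chains — disrupt
membranes in a sterol-dependent way: ergosterol- (fungal) and cholesterol-
(animal) containing membranes lyse readily, while phytosterol-rich plant
membranes resist. Quantifying that selectivity requires two kinds of
measurement to be analyzed side by side:

* **Trajectory metrics** from coarse bilayer coordinate files (GRO/XYZ):
  leaflet assignment, lateral 2D sterol–sterol radial distribution
  functions g(r) with first-peak detection (closer sterol packing shifts
  the first peak left), cumulative sterol density maps, saponin
  membrane-insertion classification with population bound fractions,
  aglycone–sugar conformational angles, Shrake–Rupley solvent-accessible
  surface area, geometric hydrogen-bond counts, and pairwise
  Lennard-Jones/Coulomb nonbonded energies
  `E = Σ 4ε[(σ/r)¹² − (σ/r)⁶] + k_C q_i q_j / (ε_r r)`.
* **Assay metrics** from plate-reader-style tables: dilution-corrected
  calcein release `I% = (I1 − f·I0)/(I2 − f·I0) × 100` (f = 0.89),
  four-parameter logistic fits `y = c + (d − c)/(1 + (x/e)^b)` with EC50
  `e`, profile-likelihood confidence intervals, censoring of EC50s beyond
  the tested range, propidium-iodide lysis fractions,
  internal-standard quantification, partition profiles, and Welch
  t / ANOVA + Tukey group comparisons with significance stars.

A synthetic-data module (`gen_membrane_system()`, `gen_point_pattern()`,
`gen_leakage_experiment()`, `gen_viability_experiment()`) generates bead
bilayer trajectories (DOPC:sterol 9:1, five saponins per 200 lipids),
clustered or CSR sterol point patterns, two-state saponin binding
schedules, and assay tables with known ground truth, so every estimator is
validated against exact truth. The package is aimed at membrane
biophysicists and chemical ecologists who need a reproducible, tested
pipeline from raw coordinates/fluorescence triplets to the summary numbers
(first-peak radii, bound fractions, EC50s, lysis percentages) such studies
report.

## Worked example

```r
library(sapomem)

## dose-response: simulate a CHOL-LUV leakage plate and recover the EC50
conc <- c(0, 2, 5, 10, 20, 35, 50, 75, 100)                 # uM
tbl <- gen_leakage_experiment(c(-1.5, 0, 100, 17.5), conc,
                              noise_sd = 0.03, seed = 7,
                              composition = "DOPC:CHOL")
tbl$release <- as.numeric(percent_release(tbl))             # Eq.-corrected %
fit <- fit_4pl(tbl)
fit$ci <- ec50_profile_ci(fit)
fit
#> fourpl_fit: EC50 = 18.04 (SE 0.491), slope -1.5, asymptotes [-0.0385, 102]
#>   95% profile CI: [17.08, 19.12]

## membrane: clustered sterols and saponin binding
sys <- gen_membrane_system(membrane_config(
  seed = 1, clustering = list(mode = "thomas", parent_intensity = 0.05,
                              cluster_sd = 0.3)))
sys$trajectory
#> trajectory: 815 atoms, 50 frame(s), box 8.000 x 8.000 x 10.000 nm
sterols <- select_atoms(sys$trajectory, "resname CHL and name O3")
first_peak(lateral_rdf(sys$trajectory, sterols, leaflet = "both"))
#> rdf_peak: r = 0.325 nm (g = 13.702)
phos <- select_atoms(sys$trajectory, "resname DOPC and name P")
classify_binding(sys$trajectory, phosphate_selection = phos)
#> binding_trace: 5 molecule(s), population bound fraction 0.200
```

Reading the numbers: the fitted EC50 (18.0 µM, CI [17.1, 19.1]) recovers
the generating value 17.5 µM from noisy triplicate fluorescence triplets;
the clustered sterol pattern puts the principal g(r) maximum at small
radius (0.33 nm, g ≈ 13.7 — strong lateral aggregation, where a CSR
pattern would show a flat g ≈ 1); and one of the five saponins (20%)
satisfies the stable-insertion criterion (bound ≥ 80% of the trailing half
of the trajectory) under the generated two-state schedule.

End-to-end runs with logging, per-stage CSV/JSON outputs and a checksummed
manifest go through `run_pipeline()` with a list or YAML configuration;
identical config + seed reproduces every output byte for byte.

See `vignettes/sapomem-methods.Rmd` for the models, parameter defaults,
numerical choices, and known limitations.

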