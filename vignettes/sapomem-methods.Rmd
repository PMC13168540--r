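---
title: "Methods and design notes for sapomem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for sapomem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapomem)
```

## Scope and scientific setting

Saponins are amphiphilic plant glycosides — a hydrophobic triterpenoid or
steroidal aglycone carrying one or two sugar chains — that permeabilize
membranes in a sterol-dependent way: membranes rich in ergosterol (fungi) or
cholesterol (animals) lyse readily, while phytosterol-rich (plant) membranes
resist. `sapomem` implements the quantitative analysis layer used to study
this selectivity from two directions:

* **Trajectory metrics** on coarse bilayer coordinate files (GRO/XYZ):
  leaflet assignment, lateral 2D sterol–sterol radial distribution functions
  (RDFs) with first-peak detection, cumulative sterol density maps, saponin
  insertion classification, aglycone–sugar conformational angles,
  Shrake–Rupley solvent-accessible surface area (SASA), geometric
  hydrogen-bond counts, and pairwise Lennard-Jones/Coulomb interaction
  energies.
* **Assay metrics**: dilution-corrected calcein release from liposome
  leakage assays, four-parameter logistic (4PL) EC50 estimation with
  profile-likelihood confidence intervals and censoring, propidium-iodide
  lysis fractions, internal-standard quantification, membrane partition
  profiles, and group statistics.

Running molecular dynamics itself, force-field parameterization, and
chromatographic data processing are out of scope; the package starts from
coordinates and plate-reader-style tables.

## The synthetic-data generator

Because real trajectories are large external deposits, every analysis here
is validated against a generator with exactly known ground truth
(`gen_membrane_system()`, `gen_point_pattern()`, `gen_leakage_experiment()`,
`gen_viability_experiment()`). The generator encodes the study conditions,
not tunable test knobs:

* **Composition.** DOPC:sterol 9:1 per leaflet (`sterol_fraction = 0.1`)
  and five saponins per 200 lipids (100 lipids per leaflet, `n_saponins =
  5`), matching the simulated bilayer systems the analyses target. The
  default lateral box (8 nm) gives ~0.64 nm² per lipid, a realistic fluid
  bilayer area density.
* **Geometry.** Bead-level pseudo-molecules: the analyses only consume
  selected atoms (phosphate beads, sterol hydroxyl oxygens, moiety
  centroids), so three beads per molecule suffice for desk-scale testing.
  Phosphate planes sit at the midplane ± 2 nm, the right order for a DOPC
  bilayer.
* **Binding kinetics.** Saponin depth follows a two-state (bound/unbound)
  Markov chain parameterized by the stationary bound probability `p_bound`
  and the mean bound dwell time `dwell_frames`; bound molecules place the
  aglycone 0.3 nm below the phosphate plane, unbound ones 1.5 nm above it.
  Only endpoint fractions are reported for the real systems, so the chain
  is the simplest process with a controllable stationary state.
* **Sterol patterns.** `poisson` draws complete spatial randomness; `thomas`
  draws Gaussian clusters around Poisson parents, with offspring wrapped
  periodically (not rejected) so the realized density is exact.
* **Noise.** Per-frame Gaussian jitter (default 0.02 nm) emulates thermal
  positional noise. Leakage tables carry multiplicative Gaussian noise on
  the true release; viability counts are binomial.

What the generator does **not** emulate: membrane undulations, lipid
diffusion, water at liquid density, excluded volume between sterols, and
force-field realism. Passing tests therefore demonstrate correctness of the
estimators on data with the assumed statistical structure, not agreement
with any particular force field or instrument.

## Lateral RDF and first-peak detection

The 2D RDF uses in-plane distances only, with the minimum-image convention
applied in x and y (a bilayer slab is not periodic along its normal for
analysis purposes). Pair counts in annuli `[r, r + dr)` are normalized per
frame by `N * rho * pi ((r+dr)^2 - r^2) / 2` with reference density
`rho = (N - 1) / (Lx Ly)` — the self pair is excluded, which keeps the CSR
expectation at exactly 1 for finite N. Leaflets are analyzed separately by
default; `"both"` pools leaflets without counting inter-leaflet pairs,
since lateral organization is an in-plane property.

`first_peak()` smooths g(r) with a centered moving average (default 5 bins)
and reports the smallest radius at or beyond `r_min` (default 0.3 nm, below
typical sterol contact distances) holding a local maximum with smoothed
g > 1. The g > 1 requirement excludes depletion shoulders: the "first peak"
is the principal correlation maximum. One boundary rule deserves note: a
clustered point process without excluded volume (the Thomas generator) has
a *monotonically decaying* g(r), so its principal maximum is truncated at
`r_min` rather than interior. The first searched bin is therefore accepted
as a peak, but only when the smoothed curve also decreases strictly across
the following full smoothing window. Without that decreasing-run
requirement, the first noise excursion of an unstructured (CSR) pattern
claims the boundary bin in roughly a quarter of realizations, which would
make left/right shift comparisons against a CSR baseline meaningless; with
it, boundary false positives drop to a few percent while genuinely decaying
correlation maxima always qualify.

```{r rdf-demo}
sys <- gen_membrane_system(membrane_config(seed = 1, n_frames = 20))
sterols <- select_atoms(sys$trajectory, "resname CHL and name O3")
rdf <- lateral_rdf(sys$trajectory, sterols, leaflet = "both")
first_peak(rdf)
```

## Saponin insertion classification

Insertion depth is measured from the phosphate mean plane of the *nearest
leaflet* (not the bilayer midplane), signed toward the midplane: this
matches the intuition of "penetrating the bilayer" and stays correct for
asymmetric bilayers. A frame is bound when depth <= 0 (at or below the
phosphate plane). "Stably membrane-inserted" — never formally defined for
the real systems — is operationalized as bound in >= 80% of the frames in
the trailing half of the trajectory; both thresholds are exposed
(`stability_fraction`, `window`) so alternative definitions are one
argument away. On jitter-free generated systems the per-frame
classification reproduces the generator's schedule exactly, because the
bound and unbound depths (−0.3 / +1.5 nm) sit far outside any rounding
error; at 0.05 nm jitter the margins are 6 and 30 standard deviations, so
misclassification is negligible.

## SASA, hydrogen bonds, energies

* **SASA** uses Shrake–Rupley sampling on a deterministic Fibonacci sphere
  (default 960 points, probe 1.4 Å), so results are exactly reproducible
  with no RNG; a single isolated sphere reproduces `4 pi (r + probe)^2` to
  better than 0.5%, and 10-atom clusters agree with a 10,000-point
  evaluation within 2%.
* **Hydrogen bonds** default to the common geometric criterion (D–A
  distance <= 0.35 nm, D–H···A angle >= 150°). These are conventions, not
  reconstructions of any published criterion, and they are configurable.
  When no hydrogen positions exist (bead models), a distance-only fallback
  applies and is flagged in the result.
* **Nonbonded energies** sum Lennard-Jones and Coulomb terms with
  Lorentz–Berthelot combining, full 3D minimum image, optional cutoff, and
  the Coulomb constant 138.935 kJ mol⁻¹ nm e⁻². The "solvation energy" of
  a saponin is computed as its interaction energy with water — an
  interaction energy, not a free-energy estimate, and documented as such.
* **Uncertainty.** Frame series are summarized as mean ± block-averaged SE
  with 5 blocks, a simple guard against frame-to-frame correlation.

## Leakage assay and EC50 estimation

Percent release uses the dilution-corrected form
`I% = (I1 − f·I0) / (I2 − f·I0) × 100` with `f = 0.89` by default; the
factor is a configurable assay constant. Responses are deliberately *not*
clipped to [0, 100] before fitting (clipping biases asymptote estimates);
out-of-range values are flagged instead.

The 4PL model is `y = c + (d − c) / (1 + (x/e)^b)`, fitted by
Levenberg–Marquardt least squares. Self-starting values take the asymptotes
from the mean responses at the extreme concentrations and the EC50 from the
concentration nearest the half-range; the slope starts at ±1 with the sign
chosen from the data direction, because a sign-inconsistent start makes the
Jacobian singular at the initial estimates. After fitting, parameters are
canonicalized to `c <= d` (the transformation `(b, c, d) -> (−b, d, c)`
leaves the curve unchanged). Non-convergence sets a flag rather than
raising, so screening loops over many curves never abort.

The 95% EC50 confidence interval inverts the F test on the profiled
residual sum of squares: `RSS(e) <= RSS_hat (1 + qF(0.95; 1, n−4)/(n−4))`.
Profiling exploits that, at fixed `(b, e)`, the asymptotes enter linearly,
so the inner re-optimization is a 1D slope search plus a linear solve;
crossings are located by bisection to a relative tolerance of 1e-4. On
noiseless data the interval collapses onto the estimate; across 500
simulated noisy curves (additive sd 5 percentage points, 3 replicates,
8 concentrations) the interval covers the true EC50 at close to the
nominal 95%.

Censoring reflects how screening data are reported when no EC50 exists
within the tested range: a fit is censored as `> c_max` when it fails, when
the fitted EC50 exceeds `c_max`, or when no plateau was approached (maximum
observed mean response below half the fitted upper asymptote while that
asymptote's SE exceeds half its value). The thresholds are explicit
configuration because published "no EC50 obtained" statements rarely state
their criteria.

```{r ec50-demo}
conc <- c(0, 2, 5, 10, 20, 35, 50, 75, 100)
tbl <- gen_leakage_experiment(c(-1.5, 0, 100, 17.5), conc,
                              noise_sd = 0.03, seed = 7)
tbl$release <- as.numeric(percent_release(tbl))
fit <- fit_4pl(tbl)
fit$ci <- ec50_profile_ci(fit)
fit
```

## Group statistics

Two groups are compared with the Welch (unequal-variance) t test — the
safer default when "independent t tests" leaves the variance assumption
unstated — and more than two with one-way ANOVA followed by Tukey HSD.
Stars follow the conventional thresholds (0.05 / 0.01 / 0.001). Exactly
identical zero-variance groups report p = 1 with a warning instead of
failing, so automated sweeps survive degenerate inputs.

## Problem sizes and determinism

The bundled validation workloads are sized for a desk machine: RDF null and
shift checks use 400 points × 50 frames per replicate, binding recovery 10
molecules × 40 frames across 20 seeds, CI coverage 500 simulated curves,
and the demo pipeline 60 lipids per leaflet × 10 frames. All stochastic
entry points take explicit seeds (no clock seeding), generators restore the
caller's RNG state, and the pipeline writes a manifest with per-file
checksums; identical config + seed reproduces outputs byte for byte.

## Known limitations

* Orthorhombic boxes only; triclinic GRO boxes are rejected explicitly.
* The point-pattern generator has no excluded volume, so clustered
  patterns have boundary-truncated rather than interior RDF maxima (see
  the first-peak rule above).
* The H-bond and stable-insertion thresholds are conventions; conclusions
  sensitive to them should sweep the configuration.
* `solvation_energy()` is a nonbonded interaction energy, not a
  free-energy method.
* No binary trajectory formats (XTC/TRR); convert to GRO/XYZ first.
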