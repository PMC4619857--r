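---
title: "Seed-based structural covariance on surface meshes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based structural covariance on surface meshes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnsurf)
```

## The scientific problem

Cortical thickness covaries across people: if one person's primary auditory
cortex is thicker than average, other regions tend to be thicker too, and
the pattern of regions that covary with a chosen *seed* region is read as a
structural covariance network (SCN). Case-control studies ask whether that
coupling differs between groups — for example between patients with primary
insomnia (PI) and healthy controls (HC) — and whether it is modulated by a
continuous severity measure such as the Pittsburgh Sleep Quality Index
(PSQI, 0–21, higher = worse sleep).

All fields in this package live on a triangulated surface mesh: one value
per vertex, models fitted independently at every vertex (mass-univariate
analysis), and a random-field-theory (RFT) correction for the tens of
thousands of correlated tests. The package deliberately stops short of
image processing: it consumes a mesh, a subjects-by-vertices thickness
matrix, a cohort table, and seed definitions, and it can simulate all four
so that every stage is testable without imaging data.

## Models

Let $T_i(v)$ be the thickness of subject $i$ at vertex $v$ (mm), and
$T_{seed,i}$ the mean *adjusted* thickness over the seed's vertices.

1. **Covariate adjustment.** Before any covariance model, thickness is
   residualized vertex-wise on age and sex
   (`residualize_covariates()`); the residuals replace the raw values.
2. **Per-group SCN map** (`scn_map()`): within one group,
   $T_i = \beta_0 + \beta_1 T_{seed,i} + \varepsilon_i$, the t field for
   $\beta_1$ with $n-2$ df. Significant correlation is interpreted as
   connectivity.
3. **Group-difference map** (`interaction_map()` with the group
   indicator): $T_i = \beta_0 + \beta_1 T_{seed,i} + \beta_2 G_i +
   \beta_3 T_{seed,i} G_i + \varepsilon_i$ with $G$ coded HC = 0, PI = 1,
   $n-4$ df. Under this coding $\beta_3$ is *exactly* the PI-minus-HC
   difference of per-group slopes, an identity the test suite asserts to
   1e-9.
4. **PSQI modulation** (`interaction_map()` with the PSQI score):
   the same model with the score in place of the indicator.
5. **Vertex-wise thickness comparison** (`thickness_group_map()`,
   `thickness_psqi_map()`): group difference and PSQI partial correlation
   of raw thickness controlling age, sex and the global mean thickness
   (per-subject mean over the supplied mesh), $n-5$ df. With two groups
   the group t is equivalent to the one-way ANOVA $F = t^2$.

The interaction models are fitted on the age/sex-adjusted residuals rather
than with the covariates inside the model, following the pre-
residualization pipeline; since residualization and model fitting are both
linear projections and the moderators are subject-level, the two routes
give nearly identical t fields, and callers who want covariates in the
model can build the design with `design_matrix()` and `fit_vertexwise()`
directly.

Demographics tables use closed-form summary-statistic tests
(`two_sample_t()`, `chi_square_2x2()`): a Pearson chi-square without
continuity correction for the sex split, a two-tailed pooled-variance t
for age, and a one-tailed (PI greater) pooled-variance t for PSQI. Pooled
variance is the default because it reproduces the order of magnitude of
published demographic p-values computed this way; Welch is available and
differs by several orders of magnitude on the PSQI contrast, which is how
the convention was identified.

## Random field theory correction

`estimate_smoothness()` implements the standard residual-based estimator:
per-vertex residual vectors are scaled to unit norm, the mean squared
difference $\Delta^2_e$ across each mesh edge measures local roughness,
and under a Gaussian autocorrelation model
$FWHM_e = \ell_e \sqrt{4\ln 2/\Delta^2_e}$. Resolution elements (resels)
are the mesh measured in FWHM units: dimension 0 is the Euler
characteristic, dimension 1 half the boundary length (zero for a closed
surface), dimension 2 the summed triangle areas computed by Heron's
formula on resel-scaled edges. The global FWHM is the area-weighted
aggregate $\sqrt{area/resels_2}$.

`peak_fwe()` applies the expected-Euler-characteristic bound
$p(t) = \min(1, \sum_d R_d\,\rho_d(t))$ with the closed-form t-field EC
densities (`ec_density_t()`); the bound is evaluated at $\max(t, 0)$
because the excursion approximation is meaningful only for non-negative
thresholds (on a closed surface $E[EC]$ at $t=0$ is exactly 1).
`cluster_fwe()` thresholds the field at the t value whose uncorrected p
equals the cluster-forming threshold, extracts connected components under
mesh-edge adjacency, converts their areas to resels, and assigns
$p_{fwe} = 1 - \exp(-m\,P(S \ge s))$ with $m$ the expected cluster count
($E[EC]$ at the forming threshold) and an exponential extent distribution
with mean $R_2\,\rho_0(t_c)/m$ — the classical expected-cluster framework
for two-dimensional fields. The cluster-forming threshold defaults to
uncorrected p = 0.001 (the de-facto default of the surface toolboxes this
analysis family uses; never stated explicitly in older reports) and is
recorded in every output. Uncorrected p < 0.05 trend masks accompany every
corrected map, mirroring how such studies display sub-threshold structure.

Degenerate vertices (zero residual variance, flagged infinite t) are
excluded from smoothness estimation but kept in thresholding with p = 0;
seed vertices stay in the maps (their covariance with the seed is trivially
high) and are listed in the per-seed metadata rather than silently masked.

### Accuracy and known conservatism

The test suite calibrates the whole chain by Monte Carlo: on null smooth
fields with FWHM eight mean edge lengths, peak FWE rejection at nominal
0.05 lands within three binomial standard errors of nominal (about 0.057
measured over the test's 200 simulations). At coarser smoothness — four
mean edge lengths, about four vertices per FWHM — the same code is
conservative (measured familywise rates near 0.02–0.03): the continuum EC
bound overpredicts the maximum of a lattice-sampled field by roughly
$t\,h^2/(8\sigma^2)$ in t units ($h$ the vertex spacing), which is a
documented property of standard RFT on discrete meshes rather than an
implementation defect. Discrete-local-maxima refinements exist but are not
part of the classical method implemented here.

## The synthetic cohort generator

`simulation_spec()` + `sample_cohort()` + `generate_thickness()` emulate a
two-group thickness study:

$$T_i(v) = \mu(v) + a_{age}(v)\,age_i + a_{sex}(v)\,sex_i +
  [b_0(v) + \Delta b(v)\,G_i]\,L_i + \varepsilon_i(v)$$

* $L_i \sim N(0, \sigma_{seed})$ is a latent per-subject seed factor added
  as-is to every seed vertex; coupling fields $b_0$ (HC slope) and
  $\Delta b$ (PI-minus-HC difference) propagate it to target vertices.
  This construction makes the true covariance slope an explicit,
  recoverable parameter: the per-group SCN slope is $b_0$ or
  $b_0 + \Delta b$ by design.
* $\varepsilon$ is white Gaussian noise (sd `noise_sd`, default 0.1 mm)
  diffused to a target spatial FWHM by calibrated lazy-random-walk
  averaging (`smooth_field()`): one step of mixing weight $\lambda$ adds
  $\lambda\,\langle\ell^2\rangle/2$ variance per tangent axis, so the
  iteration count for a kernel of per-axis variance $FWHM^2/(8\ln 2)$ is
  closed-form, with a fractional last step. Constants are exact fixed
  points; smoothing shrinks the marginal variance of a white field, so
  `noise_sd` is the pre-smoothing sd.
* Demographic defaults emulate a published insomnia cohort: n = 35 per
  group, PI PSQI 12.57 (SD 3.93) on 5–21, HC PSQI 2.26 (SD 1.36) on 0–4
  (every control below 5 by inclusion), ages 39.3 ± 8.6 vs 34.9 ± 10.7
  years truncated to 18–80, male fractions 5/35 vs 9/35. PSQI scores are
  truncated normals rounded to integers, with the location parameter
  moment-matched so the *post*-truncation mean equals the configured
  value (plain truncation would pull the HC mean about 5% low). Published
  summaries of the motivating cohort are inconsistent about the patient
  sex split (a table prints "5/35" where the recruitment description
  gives 5 male / 30 female); the generator follows the 5/30 reading.
* Default effect sizes where no study value exists were fixed once at
  field-realistic values: baseline thickness 2.5 mm, age slope
  -0.005 mm/year (normal-aging cortical thinning is a few thousandths of
  a millimetre per year), sex offset 0.05 mm, latent seed sd 0.3 mm.

What the generator does *not* emulate: cortical folding geometry,
spatially varying smoothness, non-Gaussian thickness distributions,
site/scanner effects, and any group difference in mean thickness (tests
that need one inject it explicitly). Passing tests therefore demonstrate
statistical correctness of the machinery under the stated generative
model, not robustness to real-data artifacts.

## Meshes and geometry

`build_icosphere()` subdivides a regular icosahedron, projecting midpoints
to the sphere: $V = 10\cdot4^s + 2$, $F = 20\cdot4^s$, so level 6 gives
the 40962-vertex / 81920-triangle resolution at which a cortical
hemisphere is conventionally represented. Euler characteristic 2 and
two-triangles-per-edge are asserted for every level in the tests. Seed
patches grow by edge-weighted graph geodesics (`seed_patch()`) — not exact
polyhedral geodesics, which would change patch boundaries by at most a
fraction of an edge length at these resolutions — and are validated
against an independent Dijkstra oracle. Meshes are validated on load
(index ranges, zero-area triangles, non-manifold edges) and rejected
rather than repaired.

Numerical choices worth knowing: vertex indices are 1-based in R and
0-based in every file format (OBJ, GIFTI, TSV); GIFTI support is
restricted to the ASCII encoding so all artifacts stay text; degenerate
Heron radicands in resel counting are clamped at zero; cluster tables are
sorted by corrected p with extent as tie-break.

## Problem sizes in the test suite

Simulation-based tests use icospheres at subdivision 2–4 (162–2562
vertices): large enough that resel counts are in the hundreds and cluster
geometry is nontrivial, small enough that the 500-simulation familywise
calibration and the 50-simulation parameter-recovery study run in minutes
on one core. The one full-resolution object (subdivision 6) is built only
to verify the surface convention.

## Limitations

* One mesh per run; hemispheres are analyzed separately or concatenated
  into a combined mesh file by the caller.
* Global (pooled) FWHM drives all p-values; the per-edge local FWHM field
  is computed and returned but not used (no local-resel variant).
* No permutation inference (permutation appears only as a test oracle),
  no FDR, no threshold-free cluster enhancement, and no graph-theoretic
  network topology.
* RFT is conservative when smoothness approaches the mesh spacing (see
  above); at four vertices per FWHM expect familywise rates somewhat
  below nominal.
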