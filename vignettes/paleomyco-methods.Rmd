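---
title: "Linking late-Quaternary climate change to soil fungal community composition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking late-Quaternary climate change to soil fungal community composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomyco)
```

## The scientific question

Soil fungal communities are shaped by contemporary environment — plant
hosts, soil chemistry, current climate, and spatial processes — but the
climate of the late Quaternary may have left its own imprint. Where the
last glacial maximum (LGM, ~21,000 years ago) differed strongly from the
present, lineages were displaced or filtered, and that legacy can still
be visible in today's community composition. The expectation on a
latitudinal forest transect is a gradient in that legacy: the magnitude
of late-Quaternary oscillation grows with latitude, so paleoclimate
should explain more compositional variance in temperate than in
tropical/subtropical forests.

`paleomyco` implements the full inference chain for this question on
OTU-table-scale data: null-model community dissimilarities, paleoclimate
velocity and anomaly surfaces, distance-matrix regression with
permutation inference, d-separation causal path analysis with Fisher's
C, and multi-group variation partitioning — together with a synthetic
data generator with known causal structure so the whole chain can be
validated end to end without any external downloads.

## The synthetic study design

The generator (`synthetic_config()`, `simulate_dataset()`) emulates a
12-site, 20-quadrat-per-site survey (240 samples) along a latitudinal
forest transect (default span 21.5–51 °N, roughly tropical to cold
temperate):

* **Landscape and climate.** Sites are evenly spaced in latitude.
  Present MAT and MAP decline with latitude over smooth spatial noise
  (sums of random-phase sinusoids, so spatial gradients are well
  defined). LGM grids equal the present minus a shift whose magnitude
  grows with latitude at the relative rate `anomaly_gradient` (default
  0.05 per degree, i.e. the LGM-to-present shift is about 2.5 times
  larger at the northern end — the field expectation of distinctly
  stronger oscillation toward the poles). With `anomaly_gradient = 0`
  the anomaly is spatially uniform.
* **Soils.** Ten variables (pH, total C/N/P/Ca/Mg, C:N, C:P, N:P,
  particle size distribution) driven by two latent factors with site-
  and quadrat-level variation, so a dominant soil PC1 exists. The
  factors are *purely edaphic* — independent of the climatic gradient —
  so that the generator's causal structure is exactly its declared DAG
  and conditional-independence claims about soil are true by
  construction. Real soils of course co-vary with climate; this is a
  deliberate idealization (see *Limitations*).
* **Plants.** Species have temperature optima spread over the transect
  and abundances follow a Gaussian response to site MAT scaled by
  `plant_climate_coupling`, over lognormal noise; baseline abundances
  are set so a quadrat holds roughly half the species list, as in
  forest-plot data. The first `round(frac_em_plants * n_plant_species)`
  species (default 25 of 100) are flagged ectomycorrhizal, so the flag
  count is deterministic.
* **Fungi.** Per-sample OTU counts are multinomial with log relative
  abundances
  $\eta_{os} = a_o + e_P\, L^P_o \cdot p_s + e_S\, L^S_o \cdot u_s +
  e_C\, L^C_o \cdot c_s + e_G\, L^G_o \cdot g_s + \varepsilon_{os}$,
  a log-linear model chosen for tractable null behaviour: with all
  effects zero the composition is exchangeable across samples and
  permutation tests must reject at the nominal rate. The plant scores
  $p_s$ are principal axes of the plant presence/absence matrix — fungi
  track which hosts are present — except for EM-guild OTUs, which load
  on the EM basal-area fraction and so respond to EM plants
  specifically. Guild labels are drawn with frequencies typical of ITS
  surveys (saprotroph 0.41, EM 0.18, pathogen 0.05, and small AM /
  animal-parasite / mycoparasite fractions).
* **Depth.** Sequencing depth is uniform on `depth_range` (default
  5,290–88,715 reads, the range reported for surveys of this design;
  the floor of 1,000 keeps rarefaction meaningful). The distribution
  across samples is not known for real surveys; uniform is a flagged
  assumption, not an inference.
* **Reproducibility.** The landscape, covariate and count stages draw
  from independent RNG streams derived from the master seed, so
  covariates are bit-identical across count-level reruns, and a fixed
  seed reproduces the whole dataset exactly.

## Preprocessing rules

`gate_by_evalue()`, `assign_rank()` and `assign_guild()` encode the
table-level annotation rules for ITS OTUs:

* e-value below 1e−50: reliably fungal (*accept*); between 1e−50 and
  1e−20 inclusive: *manual_check* (retained and flagged, never silently
  dropped — how such records were resolved by inspection is not a
  computable rule); above 1e−20: *exclude*. Boundaries follow the
  printed strict inequality for acceptance and are inclusive elsewhere.
* sequence identity ≥ 90 / 85 / 80 / 75 % assigns genus / family /
  order / class; below 75 % only the kingdom is kept. Thresholds are
  inclusive, and the assignment is monotone in identity.
* guilds: Glomeromycota are AM fungi with highest priority; otherwise a
  best match to a known EM lineage gives EM; otherwise the guild holding
  strictly more than 75 % of the species of the matched genus; exactly
  0.75 is *unknown* (the rule is printed as a strict inequality).

`rarefy()` normalizes every sample to the smallest sample total by
subsampling without replacement; each sample has its own RNG stream
derived from the master seed and the sample's sorted position, so its
rarefied counts do not depend on which other samples are present.
`rarefaction_curve()` is a sample-based accumulation curve (mean
richness over random quadrat orders). `soil_pca()` z-scores the soil
variables first, because their units differ by orders of magnitude.

## Dissimilarities

**Modified Raup-Crick.** For each pair of samples the observed number of
shared taxa is compared to a null that preserves each sample's richness
and draws species without replacement with probability proportional to
their occurrence frequency across the dataset. With
$p = (\#\{\text{null shared} > \text{obs}\} + \tfrac12 \#\text{ties})
/ n_\text{null}$, the index is $RC = 2(p - \tfrac12) \in [-1, 1]$: +1
means the pair shares fewer taxa than the richness-preserving null
expects (turnover), −1 more (convergence). One null assemblage is drawn
per sample per replicate and all pairs are scored from that replicate,
which is marginally identical per pair to drawing per-pair nulls and
makes the computation linear in replicates. Defaults: 999 replicates,
one master seed per matrix. Binarization happens at whatever table is
passed in; the pipeline binarizes per forest-subset (each stratum's
matrix uses occurrence frequencies within that stratum).

**The [0, 1] rescale.** Metric machinery (PCoA, PerMANOVA) operates on
*squared* distances, and on the signed scale −1 and +1 both square
to 1 — convergent and divergent pairs would be indistinguishable.
`rescale_raup_crick()` therefore shifts the index to $(RC+1)/2$ before
ordination. MRM and the path analyses keep the raw signed matrix: a
location shift only moves the regression intercept.

**PCoA.** Gower double-centering and eigendecomposition
(`stats::cmdscale`). Raup-Crick matrices are non-Euclidean, so negative
eigenvalues occur; "axes cumulatively explaining 100 % of the
variation" is interpreted as *all positive-eigenvalue axes*, with
relative variance computed over the positive part only. A Cailliez
correction is available (`correction = "cailliez"`) for users who
prefer an embedding without negative eigenvalues.

**PCNM.** Spatial eigenvectors from the pairwise geographic distance
matrix truncated at the largest minimum-spanning-tree edge, with
beyond-threshold entries set to four times the threshold (the standard
convention), followed by PCoA; positive-eigenvalue vectors are the
spatial predictors. Geographic distance is great-circle (haversine, km)
by default; `distance = "euclidean"` reproduces the simpler convention
of working directly on coordinate degrees.

## Paleoclimate metrics

`anomaly()` is the cellwise absolute difference between present and LGM
grids — a sign-free magnitude of change. When two LGM simulations are
available they are averaged cellwise first (`lgm_ensemble_mean()`);
note that the anomaly of the ensemble mean equals the mean of per-model
anomalies only when the models agree in sign (asserted as a documented
non-identity in the tests). `spatial_gradient()` computes the local
slope (units·km⁻¹) from the 3×3 neighbourhood with the classic
average-maximum (Horn-weight) kernel; a central-difference kernel is
available. East–west cell size is scaled by cos(latitude); edge cells
use their available neighbours. `velocity()` divides the temporal rate
(anomaly / years, default 21,000) by the spatial gradient, flooring the
gradient at `gradient_floor` (default 1e−5 units·km⁻¹) so flat terrain
yields large-but-finite velocities; floored cells are flagged. Velocity
is invariant to rescaling both input grids. Grids are plain-text ESRI
ASCII rasters (`read_esri_ascii()` / `write_esri_ascii()`).

## MRM, forward selection, and the d-separation path analysis

`mrm_fit()` regresses the unfolded response distance matrix (strict
upper triangle in sorted-label order, so the vectorization is canonical
under sample reordering) on unfolded predictor matrices by OLS.
Significance comes from jointly permuting the rows and columns of the
response matrix: the overall p counts permuted R² values reaching the
observed one, per-coefficient p-values count permuted |t|, both with
the add-one rule, so p ≥ 1/(n_perm+1). Default 10,000 permutations;
999 is the usual fast setting.

`forward_select_mrm()` adds, at each step, the candidate with the
largest R² gain whose Bonferroni-corrected coefficient p is below α,
with the divisor equal to the total number of candidate matrices; if an
addition pushes any included term's corrected p to α or above, it is
reverted and selection stops. Candidates collinear with the current
model are skipped, so duplicated matrices are selected once.

`basis_set()` derives Shipley's basis set from a DAG: one independence
claim per non-adjacent pair, conditioned on the union of both members'
parents. Each claim is tested by an MRM of the topologically later
member on the other member plus the conditioning matrices, taking the
permutation p of the claimed-independent term — Shipley's framework
leaves the test family open, and the permutation partial test is the
natural choice for distance matrices. The claim p-values combine into
Fisher's $C = -2\sum_i \ln p_i$, compared with χ² on $2k$ degrees of
freedom; the model is rejected when the resulting p falls below α
(default 0.05). p-values are floored at 1/(n_perm+1) before the logs so
C stays finite. Edges of the model are then refit (each node on its
parents) and reported raw and range-standardized,
$\beta^{std}_{xy} = \beta_{xy} (x_{max}-x_{min})/(y_{max}-y_{min})$,
over the observed dissimilarity ranges — dimensionless and comparable
across paths.

### The default hypothesized model, and what distance matrices can test

`default_composition_graph()` encodes the transect hypothesis: space is
upstream of paleoclimate and current climate (and paleoclimate of
current climate), all three shape soils and the plant community, and
plants, soil, climate, paleoclimate and space all act on the fungal
community. Its basis set reduces to the one substantive claim — is the
plant community independent of soil given their shared abiotic
drivers?

Two structural properties of distance-based d-separation shaped this
default, and both matter for real data:

* **Site-level block structure.** Any variable measured at site level
  induces the same within-site/between-site pattern in its distance
  matrix. Two such variables are therefore dependent *in distance
  space* even when their values are statistically independent, and
  unconditional independence claims between site-level abiotic
  variables reject structurally. The default graph keeps those pairs
  adjacent rather than pretending the test can resolve them.
* **Saturation.** The Raup-Crick index saturates at +1 once turnover is
  complete. Across a continental transect most between-site pairs sit
  on that plateau, the relation between fungal and mediator distances
  becomes strongly nonlinear, and linear matrix conditioning can no
  longer absorb a mediator — conditional claims then reject even when
  the generating process is exactly the chain being tested. The
  chain-recovery validation therefore runs on a regional latitude band
  (27–33°, 12 sites × 5 quadrats, n = 60) where dissimilarities stay in
  the informative regime; on those data the generating chain is
  accepted in ≥ 90 % of seeds and deleting the plant→fungi edge is
  rejected strictly more often. At continental scale, inference should
  lean on the variation-partitioning side of the chain.

## Variation partitioning and PerMANOVA

`rda_r2()` computes the multivariate redundancy R² of ordination scores
on predictors and Ezekiel's adjusted R²,
$1-(1-R^2)(n-1)/(n-p-1)$. `varpart_groups()` evaluates the adjusted R²
of every non-empty union of 2–5 predictor groups and resolves the
unique and shared fractions by Möbius inversion over the subset lattice
(inclusion–exclusion); the fractions sum to the full-model adjusted R²
by construction, and negative adjusted fractions are reported as-is,
following the convention of the ecology literature. Five groups give
up to 31 fractions; common implementations stop at four, so the
general-subset route is implemented here directly.

`forward_select_rda()` is the within-group double-stopping selection:
variables are added greedily by adjusted-R² gain while the partial
pseudo-F permutation p stays below α *and* the cumulative (unadjusted)
R² does not exceed the full group's adjusted R². The cap uses the
unadjusted cumulative R² because the penalized full-group adjusted R²
of a noisy group routinely lies below the adjusted R² of its single
informative member — a literal adjusted-vs-adjusted comparison would
veto every first pick; the cap is applied from the second variable on,
acting as the intended guard against selection creep.

`permanova()` implements the McArdle–Anderson partition of a
Gower-centred distance matrix: sequential (Type I) term sums of squares
(marginal SS available via `by = "margin"`), pseudo-F against the
residual, p by permuting sample labels. On univariate Euclidean
distances it reproduces the classical one-way ANOVA F exactly. Term
order is the order of the supplied list, and is reported.

In the pipeline, PerMANOVA runs on the Euclidean distance over the
positive PCo axes — the Euclidean part of the shifted Raup-Crick
matrix. The raw matrix carries substantial negative-eigenvalue mass
(about a third, measured on default synthetic data), which makes
sequential trace increments sign-indefinite and term fractions
uninterpretable; restricting to the Euclidean part guarantees a
nonnegative partition. For the same reason the PerMANOVA terms are the
forward-selected group variables rather than the raw groups (the
unselected space group alone can approach the sample count in rank).

## The pipeline

`run_pipeline(pipeline_config(...))` executes the whole chain from one
config: simulate (or accept a prebuilt dataset) → rarefy to the
smallest sample total → covariates (soil PC1–PC4, current MAT/MAP at
the sample locations, the four paleoclimate metrics, altitude + PCNM
vectors) → per stratum and guild: fungal Raup-Crick, PCo axes,
within-group forward selection, variation partitioning, PerMANOVA, and
the d-separation path analysis. Strata (default: a median-latitude
split into temperate and tropic–subtropical) are analysed
independently — matrices, PCo axes, PCNM vectors and selections are all
recomputed within each stratum. The plant community enters the
composition analyses as its own Raup-Crick matrix (d-sep node) and as
its leading PCo axes, capped at 10 (varpart group; the cap keeps
within-group selection tractable at quadrat scale). One plant node is
used for all guilds; an EM-specific plant node is a natural refinement
that is not implemented. Every stochastic stage derives its seed from
the master seed, so a rerun reproduces the report exactly (timings
aside). `compare_strata()` tabulates the paleoclimate-attributable
fraction (unique plus shared) per stratum and guild and their
difference. Bonferroni corrections are applied within each stratum ×
guild family of tests, with the divisor equal to the candidate count of
that family.

Reports are written as `report.json` plus `fractions.tsv` and
`dsep.tsv` when an output directory is configured; datasets round-trip
through plain-text formats (TSV tables, ESRI ASCII grids, JSON truth
records) via `write_dataset()`.

## Problem sizes and numerical choices

The default synthetic design (240 samples, 800 OTUs) is the package's
reference scale: the reproduction script runs the full pipeline on it
with 199 Raup-Crick replicates and 499 permutations per test, the
package's desk-scale analysis sizes; the method-validation suite uses
999 permutations where a p-value's resolution matters (null
calibration) and 20,000 null draws where Monte-Carlo error is compared
against exact enumeration. Other numerical choices: symmetry tolerance
1e−12 and exact-zero diagonals for distance matrices; eigenvalues are
treated as positive above 1e−8 of the spectral radius; permutation
p-values use the add-one rule everywhere; duplicate coordinates in
PCNM warn but run; a constant soil variable is dropped with a warning;
an all-zero distance matrix ordinates to a single degenerate axis with
a warning; ties in forward selection break by input order.

## What the synthetic validation does and does not show

Passing the suite shows the machinery is correct (oracles, enumeration,
null calibration) and that the chain recovers known structure under the
generator's assumptions: log-linear multinomial counts, Gaussian plant
responses, independent edaphic factors, smooth climate fields, uniform
depths. Real data differ in ways the generator deliberately omits:
phylogenetic structure among OTUs, zero-inflation beyond multinomial
sampling, soil–climate covariation, topographic buffering of
paleoclimate, sequencing artefacts upstream of the OTU table, and
taxonomic annotation error. Results on real data inherit the caveats
above — especially the block-structure and saturation limits of
distance-based causal testing — and the paleoclimate fractions from
variation partitioning remain descriptive attributions, not effect
sizes.
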