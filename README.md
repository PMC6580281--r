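# paleomyco

Tools for asking whether late-Quaternary climate change left a
detectable imprint on present-day soil fungal communities, alongside
the contemporary drivers (plants, soil, current climate, space), on a
latitudinal forest transect of sites × quadrats with ITS OTU tables.

The package implements the complete inference chain and a synthetic
data generator with known causal structure, so every stage can be
validated end to end:

* **Community preprocessing** — BLAST e-value gating
  (accept < 1e−50 / manual-check 1e−50–1e−20 / exclude > 1e−20),
  identity-threshold rank assignment (≥ 90/85/80/75 % → genus / family
  / order / class), functional-guild rules (Glomeromycota → AM,
  EM-lineage match → EM, > 75 % genus dominance, else unknown),
  rarefaction to the smallest sample total, richness tables,
  sample-based rarefaction curves, soil PCA.
* **Dissimilarities** — the modified Raup-Crick null model
  (richness-preserving, occurrence-weighted; index in [−1, 1], with an
  explicit rescale to [0, 1] for metric machinery), Euclidean
  environmental distances, PCoA with positive-axis selection, PCNM
  spatial eigenvectors with MST truncation.
* **Paleoclimate metrics** — anomaly |present − LGM|, 3×3
  average-maximum spatial gradients with latitude-scaled cell sizes,
  and climate-change velocity

  `velocity (km/yr) = (anomaly / years) / max(gradient, floor)`

  from plain-text ESRI ASCII grids, with LGM model-ensemble averaging.
* **MRM + d-separation** — multiple regression on distance matrices
  with joint row/column permutation of the response, Bonferroni forward
  selection, Shipley basis sets from a causal DAG, Fisher's
  `C = −2 Σ ln pᵢ` against χ²(2k), and range-standardized path
  coefficients `β_std = β (x_max − x_min)/(y_max − y_min)`.
* **Variation partitioning + PerMANOVA** — adjusted-R² fractions for
  2–5 predictor groups by inclusion–exclusion, double-stopping
  within-group forward selection, and the McArdle–Anderson
  distance-based ANOVA (exactly the classical F in the univariate
  Euclidean limit).
* **Pipeline** — `run_pipeline()` drives the whole workflow per forest
  stratum (temperate vs tropic–subtropical) and fungal guild (total,
  saprotroph, EM, pathogen), writes JSON/TSV reports, and
  `compare_strata()` tabulates the paleoclimate contrast.

See the methods vignette (`vignettes/paleomyco-methods.Rmd`) for the
models, assumptions, defaults and limitations.

## Worked example

```r
library(paleomyco)

cfg <- synthetic_config(n_sites = 6, quadrats_per_site = 6, n_otus = 300,
                        n_plant_species = 40, depth_range = c(2000, 6000),
                        seed = 101)
ds <- simulate_dataset(cfg)
ds$otu_table
#> otu_table: 300 OTUs x 36 samples (6 sites), total reads 145,659

rare <- rarefy(ds$otu_table, seed = 101)          # normalize to smallest sample
rc   <- raup_crick(rare, n_null = 199, seed = 101) # null-model dissimilarity

paleo <- paleoclimate_covariates(ds$climate_grids, ds$sites)
round(head(paleo, 3), 4)
#>     mat_anomaly map_anomaly mat_velocity map_velocity
#> S01       2.000     150.000       0.0171       0.0242
#> S02       2.600     195.000       0.0189       0.0166
#> S03       3.175     238.125       0.0264       0.0265

clim <- data.frame(MAT = extract_at(ds$climate_grids$MAT$present, ds$samples),
                   MAP = extract_at(ds$climate_grids$MAP$present, ds$samples),
                   row.names = ds$samples$sample)
fit <- mrm_fit(rc, list(climate = euclidean_env(clim),
                        paleoclimate = euclidean_env(
                          paleoclimate_covariates(ds$climate_grids, ds$samples))),
               n_perm = 999, seed = 101)
fit
#> MRM on 36 samples (630 pairs), R2 = 0.6696, overall p = 0.001 (999 permutations)
#>           term        beta          t p_perm
#> 1  (Intercept) -1.13499644 -29.551707  0.001
#> 2      climate  0.67895073  16.643694  0.001
#> 3 paleoclimate -0.03218399  -1.044997  0.290
```

Reading the output: fungal turnover on this small transect tracks the
current-climate distance (β = 0.68, permutation p = 0.001); given
climate, the paleoclimate matrix adds nothing (p = 0.29) — on this
seed the generator drove composition through present climate, and the
MRM attributes it accordingly. The full study-scale analysis
(stratified variation partitioning, PerMANOVA and causal path models)
runs from one config:

```r
report <- run_pipeline(pipeline_config(simulate = synthetic_config(seed = 1),
                                       n_perm = 499, n_null = 199, seed = 1))
compare_strata(report)
```

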