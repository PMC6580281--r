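# small, fast study design used throughout these tests
tiny_config <- function(...) {
  synthetic_config(n_sites = 6, quadrats_per_site = 4, n_otus = 120,
                   n_plant_species = 40, depth_range = c(1000, 3000), ...)
}

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_sites = 0), "count")
  expect_error(synthetic_config(frac_em_plants = 1.2), "frac_em_plants")
  expect_error(synthetic_config(effect_soil = -1), "nonnegative")
  expect_error(synthetic_config(grid_res = 0), "resolution")
  expect_error(synthetic_config(depth_range = c(500, 2000)), "depth_range")
  expect_s3_class(synthetic_config(), "synthetic_config")
})

test_that("default design yields 240 samples with complete covariates", {
  cfg <- synthetic_config()
  land <- generate_landscape(cfg)
  expect_equal(nrow(land$samples), 240)
  expect_equal(nrow(land$sites), 12)
  cov <- generate_covariates(land, cfg)
  expect_equal(dim(cov$soil), c(240, 10))
  expect_false(anyNA(cov$soil))
  expect_equal(ncol(cov$plant$abundance), 240)
  expect_equal(nrow(cov$plant$abundance), 100)
})

test_that("landscape anomaly tracks latitude at the configured rate", {
  cfg0 <- tiny_config(anomaly_gradient = 0, seed = 3)
  land0 <- generate_landscape(cfg0)
  an0 <- extract_at(anomaly(land0$climate_grids$MAT$present,
                            land0$climate_grids$MAT$lgm), land0$sites)
  expect_lt(diff(range(an0)), 1e-9)
  cfg1 <- tiny_config(anomaly_gradient = 0.05, seed = 3)
  land1 <- generate_landscape(cfg1)
  an1 <- extract_at(anomaly(land1$climate_grids$MAT$present,
                            land1$climate_grids$MAT$lgm), land1$sites)
  expect_gt(cor(land1$sites$lat, an1), 0.9)
  # determinism of grids under the seed
  land2 <- generate_landscape(cfg1)
  expect_identical(land1$climate_grids, land2$climate_grids)
})

test_that("EM flag counts are deterministic from the configured fraction", {
  cfg <- tiny_config(frac_em_plants = 1)
  cov <- generate_covariates(generate_landscape(cfg), cfg)
  expect_true(all(cov$plant$species$em))
  cfg2 <- synthetic_config(n_plant_species = 100, frac_em_plants = 0.3,
                           n_sites = 4, quadrats_per_site = 3,
                           depth_range = c(1000, 2000))
  cov2 <- generate_covariates(generate_landscape(cfg2), cfg2)
  expect_equal(sum(cov2$plant$species$em), 30)
})

test_that("soil variables carry a dominant latent factor", {
  cfg <- tiny_config(seed = 5)
  cov <- generate_covariates(generate_landscape(cfg), cfg)
  p <- soil_pca(cov$soil)
  expect_gt(p$variance_fraction[1], 0.25)
  expect_gt(p$variance_fraction[1] / p$variance_fraction[2], 1.5)
})

test_that("plant-climate coupling strengthens the plant-climate Mantel correlation", {
  stat <- function(coupling, seed) {
    cfg <- tiny_config(plant_climate_coupling = coupling, seed = seed)
    land <- generate_landscape(cfg)
    cov <- generate_covariates(land, cfg)
    rc <- raup_crick(cov$plant$abundance, n_null = 49, seed = seed)
    clim <- euclidean_env(data.frame(
      MAT = extract_at(land$climate_grids$MAT$present, land$samples),
      MAP = extract_at(land$climate_grids$MAP$present, land$samples),
      row.names = land$samples$sample))
    vegan::mantel(as.dist(unclass(rc)), as.dist(unclass(clim)),
                  permutations = 0)$statistic
  }
  on_vals <- vapply(1:8, function(s) stat(1, s), 0)
  off_vals <- vapply(1:8, function(s) stat(0, s), 0)
  expect_gt(mean(on_vals), mean(off_vals))
  expect_gt(mean(on_vals > off_vals), 0.7)
})

test_that("OTU tables are deterministic and depth stays in range", {
  cfg <- tiny_config(seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  tot <- colSums(d1$otu_table$counts)
  expect_true(all(tot >= cfg$depth_range[1] & tot <= cfg$depth_range[2]))
  expect_equal(d1$truth$seed, 11)
  expect_identical(d1$truth, unclass(cfg))
  # covariates are stable across count-level changes (independent streams)
  cfg_b <- tiny_config(seed = 11, effect_plant = 3)
  d3 <- simulate_dataset(cfg_b)
  expect_identical(d1$soil, d3$soil)
  expect_identical(d1$plant, d3$plant)
})

test_that("degenerate all-zero-effect, zero-noise config warns", {
  cfg <- tiny_config(effect_plant = 0, effect_soil = 0, effect_climate = 0,
                     effect_space = 0, otu_noise_sd = 0)
  land <- generate_landscape(cfg)
  cov <- generate_covariates(land, cfg)
  expect_warning(generate_fungal_otu_table(cov$plant, cov$soil, land, cfg),
                 "degenerate")
})

test_that("a dominant plant effect is the first matrix picked by MRM selection", {
  # plants decoupled from climate so the dominant driver is identifiable
  first_pick <- vapply(1:6, function(s) {
    cfg <- tiny_config(effect_plant = 4, effect_soil = 0.2,
                       effect_climate = 0.2, effect_space = 0.2,
                       plant_climate_coupling = 0, seed = s)
    ds <- simulate_dataset(cfg)
    rc <- raup_crick(ds$otu_table$counts, n_null = 99, seed = s)
    land_clim <- data.frame(
      MAT = extract_at(ds$climate_grids$MAT$present, ds$samples),
      MAP = extract_at(ds$climate_grids$MAP$present, ds$samples),
      row.names = ds$samples$sample)
    cands <- list(
      plant = raup_crick(ds$plant$abundance, n_null = 99, seed = s),
      soil = euclidean_env(soil_pca(ds$soil, 4)$scores),
      climate = euclidean_env(land_clim),
      space = euclidean_env(ds$samples[, c("lat", "lon")]))
    sel <- forward_select_mrm(rc, cands, n_perm = 99, seed = s)
    if (length(sel$selected) == 0) "" else sel$selected[1]
  }, "")
  expect_gte(sum(first_pick == "plant"), 5)
})

test_that("plant-effect strength is recovered monotonically by the path model", {
  grid <- c(0, 0.5, 1, 2, 4)
  chain <- causal_graph(c("climate -> plant", "plant -> fungal"))
  one_coef <- function(ep, s) {
    cfg <- tiny_config(effect_plant = ep, effect_soil = 0.3,
                       effect_climate = 0.3, effect_space = 0.3, seed = s)
    ds <- simulate_dataset(cfg)
    rc <- raup_crick(ds$otu_table$counts, n_null = 99, seed = s)
    dat <- list(
      fungal = rc,
      plant = raup_crick(ds$plant$abundance, n_null = 99, seed = s),
      climate = euclidean_env(data.frame(
        MAT = extract_at(ds$climate_grids$MAT$present, ds$samples),
        MAP = extract_at(ds$climate_grids$MAP$present, ds$samples),
        row.names = ds$samples$sample)))
    fit <- dsep_path_analysis(chain, dat, n_perm = 99, seed = s)
    co <- fit$coefficients
    co$beta_std[co$from == "plant" & co$to == "fungal"]
  }
  coefs <- vapply(grid, function(ep)
    mean(vapply(21:23, function(s) one_coef(ep, s), 0)), 0)
  expect_gt(cor(grid, coefs, method = "spearman"), 0.8)
})

test_that("datasets write to plain-text files and grids round-trip", {
  cfg <- tiny_config(seed = 2)
  ds <- simulate_dataset(cfg)
  dir <- file.path(tempdir(), "synthds")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "otu_table.tsv")))
  counts <- as.matrix(utils::read.table(file.path(dir, "otu_table.tsv"),
                                        sep = "\t", header = TRUE, row.names = 1,
                                        check.names = FALSE))
  expect_equal(unname(counts), unname(ds$otu_table$counts))
  g <- read_esri_ascii(file.path(dir, "mat_lgm.asc"), variable = "MAT", slice = "LGM")
  expect_equal(g$values, ds$climate_grids$MAT$lgm$values, tolerance = 1e-10)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 2)
  unlink(dir, recursive = TRUE)
})
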