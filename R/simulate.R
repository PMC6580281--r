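#' Configuration for a synthetic study dataset
#'
#' Describes a latitudinal forest transect emulating a 12-site, 20-quadrat
#' soil-fungal survey: paired present/LGM climate grids with a latitudinal
#' gradient in LGM-to-present anomaly, correlated soil variables with a
#' dominant latent factor, a plant community responding to climate, and an
#' OTU-by-sample count table whose composition is driven by plant, soil,
#' climate and space with configurable strengths.
#'
#' @param n_sites number of sites along the latitudinal transect.
#' @param quadrats_per_site quadrats (samples) per site.
#' @param n_otus number of fungal OTUs.
#' @param n_plant_species number of tree species.
#' @param frac_em_plants proportion of plant species flagged ectomycorrhizal
#'   (EM); the first `round(frac_em_plants * n_plant_species)` species by
#'   index carry the flag, so the count is deterministic.
#' @param effect_plant,effect_soil,effect_climate,effect_space nonnegative
#'   strengths of each driver on fungal log relative abundances.
#' @param anomaly_gradient relative increase of the LGM-to-present climate
#'   shift per degree latitude (0 = spatially uniform anomaly).
#' @param plant_climate_coupling strength of the plant community's Gaussian
#'   response to mean annual temperature (0 = plants independent of climate).
#' @param depth_range two integers, uniform sequencing-depth interval
#'   (minimum at least 1000 so rarefaction is exercised).
#' @param lat_range,lon_range transect extent in decimal degrees.
#' @param grid_res climate-grid cell size in decimal degrees.
#' @param otu_noise_sd standard deviation of OTU-by-sample log-abundance noise.
#' @param seed master integer seed; identical seeds give bit-identical datasets.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_sites = 12L, quadrats_per_site = 20L,
                             n_otus = 800L, n_plant_species = 100L,
                             frac_em_plants = 0.25,
                             effect_plant = 1, effect_soil = 1,
                             effect_climate = 1, effect_space = 1,
                             anomaly_gradient = 0.05,
                             plant_climate_coupling = 1,
                             depth_range = c(5290L, 88715L),
                             lat_range = c(21.5, 51), lon_range = c(101, 128),
                             grid_res = 0.25,
                             otu_noise_sd = 0.6,
                             seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites), quadrats_per_site = as.integer(quadrats_per_site),
    n_otus = as.integer(n_otus), n_plant_species = as.integer(n_plant_species),
    frac_em_plants = frac_em_plants,
    effect_plant = effect_plant, effect_soil = effect_soil,
    effect_climate = effect_climate, effect_space = effect_space,
    anomaly_gradient = anomaly_gradient,
    plant_climate_coupling = plant_climate_coupling,
    depth_range = as.integer(depth_range),
    lat_range = lat_range, lon_range = lon_range, grid_res = grid_res,
    otu_noise_sd = otu_noise_sd,
    seed = as.integer(seed))
  counts <- c("n_sites", "quadrats_per_site", "n_otus", "n_plant_species")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("config error: ", f, " must be a count >= 1")
    }
  }
  if (cfg$frac_em_plants < 0 || cfg$frac_em_plants > 1) {
    stop("config error: frac_em_plants must lie in [0, 1]")
  }
  for (f in c("effect_plant", "effect_soil", "effect_climate", "effect_space")) {
    if (cfg[[f]] < 0) stop("config error: ", f, " must be nonnegative")
  }
  if (cfg$grid_res <= 0) stop("config error: grid resolution must be positive")
  if (length(cfg$depth_range) != 2L || cfg$depth_range[1] < 1000L ||
      diff(cfg$depth_range) < 0) {
    stop("config error: depth_range must be an increasing interval with floor >= 1000")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# smooth low-frequency field over a grid, deterministic given the active RNG:
# a few random-phase sinusoids so spatial gradients are well behaved
smooth_field <- function(lat, lon, amplitude, n_waves = 4L) {
  f <- matrix(0, length(lat), length(lon))
  for (k in seq_len(n_waves)) {
    a <- stats::runif(4, -pi, pi)
    sc <- stats::runif(2, 0.1, 0.4)
    f <- f + outer(sin(lat * sc[1] + a[1]), sin(lon * sc[2] + a[2])) +
      0.5 * outer(cos(lat * sc[1] * 1.7 + a[3]), cos(lon * sc[2] * 1.3 + a[4]))
  }
  amplitude * f / n_waves
}

#' Generate the synthetic landscape: site/quadrat coordinates and climate grids
#'
#' Sites are spaced evenly along the latitudinal span (with small
#' deterministic jitter in longitude); each site holds `quadrats_per_site`
#' quadrats jittered within ~0.02 degrees. Present-day MAT and MAP decline
#' with latitude over smooth spatial noise; LGM grids equal the present
#' minus a shift whose magnitude grows with latitude at relative rate
#' `anomaly_gradient` per degree, so the LGM-to-present anomaly increases
#' towards the poleward end of the transect.
#'
#' @param config a [synthetic_config()].
#' @return list with `sites`, `samples` (data frames with lat/lon/altitude)
#'   and `climate_grids` (`$MAT`/`$MAP`, each with `$present` and `$lgm`
#'   [climate_grid()] objects).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "landscape"))
  ns <- config$n_sites; nq <- config$quadrats_per_site
  site_lat <- seq(config$lat_range[1], config$lat_range[2], length.out = max(ns, 2L))[seq_len(ns)]
  site_lon <- seq(config$lon_range[1], config$lon_range[2], length.out = max(ns, 2L))[seq_len(ns)] +
    stats::runif(ns, -1, 1)
  site_alt <- stats::runif(ns, 200, 1500)
  sites <- data.frame(site = sprintf("S%02d", seq_len(ns)),
                      lat = site_lat, lon = site_lon, altitude = site_alt,
                      stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(ns), function(i) {
    data.frame(sample = sprintf("S%02d_Q%02d", i, seq_len(nq)),
               site = sites$site[i], quadrat = seq_len(nq),
               lat = sites$lat[i] + stats::runif(nq, -0.02, 0.02),
               lon = sites$lon[i] + stats::runif(nq, -0.02, 0.02),
               altitude = sites$altitude[i] + stats::runif(nq, -50, 50),
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- samples$sample

  res <- config$grid_res
  glat <- seq(config$lat_range[1] - 1, config$lat_range[2] + 1, by = res)
  glon <- seq(min(site_lon) - 2, max(site_lon) + 2, by = res)
  # rows run north -> south as in ESRI ASCII rasters
  lat_desc <- rev(glat)
  mat_present <- outer(lat_desc, glon, function(la, lo) 26 - 0.62 * (la - config$lat_range[1])) +
    smooth_field(lat_desc, glon, amplitude = 1.5)
  map_present <- outer(lat_desc, glon, function(la, lo) 1900 - 42 * (la - config$lat_range[1])) +
    smooth_field(lat_desc, glon, amplitude = 120)
  shift_scale <- 1 + config$anomaly_gradient * (lat_desc - config$lat_range[1])
  mat_shift <- matrix(2.0 * shift_scale, length(glat), length(glon))
  map_shift <- matrix(150 * shift_scale, length(glat), length(glon))

  mk <- function(vals, variable, slice) {
    climate_grid(vals, xll = min(glon) - res / 2, yll = min(glat) - res / 2,
                 cellsize = res, variable = variable, slice = slice)
  }
  grids <- list(
    MAT = list(present = mk(mat_present, "MAT", "present"),
               lgm = mk(mat_present - mat_shift, "MAT", "LGM")),
    MAP = list(present = mk(map_present, "MAP", "present"),
               lgm = mk(pmax(map_present - map_shift, 50), "MAP", "LGM")))
  list(sites = sites, samples = samples, climate_grids = grids)
}

#' Generate plant and soil covariate tables for a synthetic landscape
#'
#' Ten soil variables are driven by two latent factors: a dominant factor
#' (site-level, mildly correlated with latitude) loading on pH, nutrient
#' and base-cation variables — so a clear soil PC1 exists — and a second
#' factor loading on total C and C:N. Plant species have temperature optima
#' spread over the transect's MAT range and abundances follow a Gaussian
#' response to site MAT scaled by `plant_climate_coupling`, plus lognormal
#' noise; basal area is abundance times a species-specific stem size. The
#' first `round(frac_em_plants * n_plant_species)` species are flagged EM.
#'
#' @param landscape output of [generate_landscape()].
#' @param config the same [synthetic_config()].
#' @return list with `plant` (list: `abundance` and `basal_area`
#'   species-by-sample matrices, `species` data frame with `em` flags) and
#'   `soil` (sample-by-10 data frame).
#' @export
generate_covariates <- function(landscape, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$frac_em_plants < 0 || config$frac_em_plants > 1) {
    stop("config error: frac_em_plants must lie in [0, 1]")
  }
  set.seed(derive_seed(config$seed, "covariates"))
  smp <- landscape$samples
  n <- nrow(smp)
  mat_site <- extract_at(landscape$climate_grids$MAT$present, smp)

  # soil: dominant latent factor u1 + secondary u2, purely edaphic
  # (site- and quadrat-level variation independent of the climatic
  # gradient, so the generating causal structure is exactly the declared DAG)
  site_id <- match(smp$site, landscape$sites$site)
  u1_site <- stats::rnorm(nrow(landscape$sites), 0, 1)
  u2_site <- stats::rnorm(nrow(landscape$sites))
  u1 <- u1_site[site_id] + stats::rnorm(n, 0, 0.4)
  u2 <- u2_site[site_id] + stats::rnorm(n, 0, 0.4)
  e <- function(sd = 1) stats::rnorm(n, 0, sd)
  soil <- data.frame(
    pH      = 5.2 - 0.55 * u1 + e(0.25),
    total_C = 12 + 1.2 * u1 + 4.0 * u2 + e(1.0),
    total_N = 1.1 + 0.30 * u1 + e(0.12),
    total_P = 0.8 + 0.35 * u1 + e(0.10),
    total_Ca = 6 + 2.4 * u1 + e(0.8),
    total_Mg = 3 + 1.1 * u1 + e(0.4),
    CN_ratio = 12 + 2.8 * u2 + e(0.9),
    CP_ratio = 16 + 3.2 * u1 + e(1.1),
    NP_ratio = 1.5 + 0.45 * u1 + e(0.2),
    PSD = 2.55 + 0.03 * u1 + e(0.02),
    row.names = smp$sample)

  # plants: Gaussian response to MAT around species optima
  np <- config$n_plant_species
  n_em <- round(config$frac_em_plants * np)
  optima <- seq(min(mat_site), max(mat_site), length.out = max(np, 2L))[seq_len(np)] +
    stats::runif(np, -1, 1)
  width <- stats::runif(np, 3, 6)
  log_size <- stats::rnorm(np, 0, 0.5)
  # baseline abundances tuned so a quadrat holds roughly half the species
  # list, as in forest-plot data; off-optimum species drop out entirely
  eta <- config$plant_climate_coupling *
    (-(outer(optima, mat_site, "-")^2) / (2 * matrix(width, np, n)^2)) +
    matrix(stats::rnorm(np * n, 0, 0.7), np, n) + stats::rnorm(np, 0.3, 1)
  abundance <- matrix(stats::rpois(np * n, lambda = exp(eta)), np, n,
                      dimnames = list(sprintf("plant%03d", seq_len(np)), smp$sample))
  basal <- abundance * exp(log_size + matrix(stats::rnorm(np * n, 0, 0.2), np, n)) * 0.05
  species <- data.frame(species = rownames(abundance),
                        em = seq_len(np) <= n_em,
                        stringsAsFactors = FALSE)
  list(plant = list(abundance = abundance, basal_area = basal, species = species),
       soil = soil)
}

#' Per-sample plant community summary
#'
#' Species richness and total basal area of all, EM, and non-EM plants —
#' the six plant covariates used as predictors throughout the pipeline.
#'
#' @param plant the `plant` element of [generate_covariates()] output.
#' @return data frame, one row per sample.
#' @export
plant_summary <- function(plant) {
  ab <- plant$abundance; ba <- plant$basal_area; em <- plant$species$em
  data.frame(
    plant_richness = colSums(ab > 0),
    plant_basal = colSums(ba),
    em_richness = colSums(ab[em, , drop = FALSE] > 0),
    em_basal = colSums(ba[em, , drop = FALSE]),
    nonem_richness = colSums(ab[!em, , drop = FALSE] > 0),
    nonem_basal = colSums(ba[!em, , drop = FALSE]),
    row.names = colnames(ab))
}

#' Generate the fungal OTU count table with known guild structure
#'
#' Per-sample counts are multinomial with log relative abundances
#' \deqn{\eta_{os} = a_o + e_P L^P_o \cdot p_s + e_S L^S_o \cdot u_s +
#'       e_C L^C_o \cdot c_s + e_G L^G_o \cdot g_s + \epsilon_{os},}
#' where \eqn{p_s} are the leading principal-component scores of the
#' plant presence/absence matrix — fungi track which hosts are present —
#' (EM-guild OTUs instead load on the EM basal
#' fraction, so they track EM plants specifically), \eqn{u_s} soil PC
#' scores, \eqn{c_s} standardized MAT/MAP, \eqn{g_s} standardized
#' lat/lon, the \eqn{L} loadings are standard-normal per OTU, and the
#' effect strengths \eqn{e_\cdot} come from the config. Sequencing depth is
#' uniform on `depth_range`. Guild labels are assigned with realistic
#' frequencies (saprotroph 0.41, EM 0.18, pathogen 0.05, AM 0.008, animal
#' parasite 0.013, mycoparasite 0.008, remainder unknown).
#'
#' @param plant,soil covariate tables from [generate_covariates()].
#' @param landscape from [generate_landscape()].
#' @param config the [synthetic_config()].
#' @return list with `otu_table` (an [otu_table()]) and `guilds` (named
#'   character vector OTU -> guild).
#' @export
generate_fungal_otu_table <- function(plant, soil, landscape, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "counts"))
  smp <- landscape$samples
  n <- nrow(smp); no <- config$n_otus
  eff <- c(config$effect_plant, config$effect_soil, config$effect_climate, config$effect_space)
  if (all(eff == 0) && config$otu_noise_sd == 0) {
    warning("all effects zero with zero noise: OTU table is degenerate (identical expected composition)")
  }

  guild_p <- c(saprotroph = 0.41, EM = 0.18, pathogen = 0.05,
               animal_parasite = 0.013, AM = 0.008, mycoparasite = 0.008)
  guild_p <- c(guild_p, unknown = 1 - sum(guild_p))
  guilds <- sample(names(guild_p), no, replace = TRUE, prob = guild_p)
  names(guilds) <- sprintf("OTU%05d", seq_len(no))

  zs <- function(x) if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  # fungi track host presence composition: principal axes of the plant
  # presence/absence matrix are the plant driver scores
  plant_pc <- stats::prcomp(t(plant$abundance > 0), center = TRUE, scale. = FALSE)
  p_s <- apply(plant_pc$x[, seq_len(min(2, ncol(plant_pc$x))), drop = FALSE], 2, zs)
  em_frac <- colSums(plant$basal_area[plant$species$em, , drop = FALSE]) /
    pmax(colSums(plant$basal_area), .Machine$double.eps)
  em_s <- zs(em_frac)
  soil_pc <- stats::prcomp(soil, center = TRUE, scale. = TRUE)
  u_s <- apply(soil_pc$x[, 1:2, drop = FALSE], 2, zs)
  mat <- extract_at(landscape$climate_grids$MAT$present, smp)
  map <- extract_at(landscape$climate_grids$MAP$present, smp)
  c_s <- cbind(zs(mat), zs(map))
  g_s <- cbind(zs(smp$lat), zs(smp$lon))

  L <- function(k) matrix(stats::rnorm(no * k), no, k) / sqrt(k)
  eta <- matrix(stats::rnorm(no, 0, 1), no, n) +   # OTU base abundance
    config$effect_soil * (L(2) %*% t(u_s)) +
    config$effect_climate * (L(2) %*% t(c_s)) +
    config$effect_space * (L(2) %*% t(g_s)) +
    matrix(stats::rnorm(no * n, 0, config$otu_noise_sd), no, n)
  Lp <- L(2); Lem <- stats::rnorm(no)
  is_em <- guilds == "EM"
  plant_part <- Lp %*% t(p_s)
  plant_part[is_em, ] <- outer(Lem[is_em], em_s)
  eta <- eta + config$effect_plant * plant_part

  depth <- config$depth_range[1] +
    floor(stats::runif(n) * (config$depth_range[2] - config$depth_range[1] + 1L))
  counts <- matrix(0L, no, n, dimnames = list(names(guilds), smp$sample))
  prob <- exp(eta - matrix(apply(eta, 2, max), no, n, byrow = TRUE))
  for (s in seq_len(n)) counts[, s] <- stats::rmultinom(1, depth[s], prob[, s])

  list(otu_table = otu_table(counts, smp[, c("sample", "site", "quadrat")]),
       guilds = guilds)
}

#' Generate a complete synthetic study dataset
#'
#' Runs [generate_landscape()], [generate_covariates()] and
#' [generate_fungal_otu_table()] under independent RNG streams derived from
#' the master seed (so covariates are stable across count-level reruns) and
#' bundles the result with a `truth` record echoing the generating config.
#'
#' @param config a [synthetic_config()].
#' @return object of class `"synthetic_dataset"`: list with `otu_table`,
#'   `guilds`, `plant`, `soil`, `samples`, `sites`, `climate_grids`, `truth`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  landscape <- generate_landscape(config)
  cov <- generate_covariates(landscape, config)
  fun <- generate_fungal_otu_table(cov$plant, cov$soil, landscape, config)
  structure(list(
    otu_table = fun$otu_table, guilds = fun$guilds,
    plant = cov$plant, soil = cov$soil,
    samples = landscape$samples, sites = landscape$sites,
    climate_grids = landscape$climate_grids,
    truth = unclass(config)), class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' OTU counts and covariates as TSV, climate grids as ESRI ASCII (.asc),
#' and the truth record as JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                         quote = FALSE, col.names = NA)
  w(dataset$otu_table$counts, "otu_table.tsv")
  w(dataset$soil, "soil.tsv")
  w(dataset$plant$abundance, "plant_abundance.tsv")
  w(dataset$plant$basal_area, "plant_basal_area.tsv")
  utils::write.table(dataset$plant$species, file.path(dir, "plant_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(otu = names(dataset$guilds), guild = dataset$guilds),
                     file.path(dir, "guilds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (v in names(dataset$climate_grids)) {
    for (t in names(dataset$climate_grids[[v]])) {
      write_esri_ascii(dataset$climate_grids[[v]][[t]],
                       file.path(dir, paste0(tolower(v), "_", t, ".asc")))
    }
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
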