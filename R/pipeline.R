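#' Pipeline configuration
#'
#' One object driving the full workflow: simulate (or accept) a dataset,
#' preprocess, build dissimilarities and paleoclimate covariates, then run
#' variation partitioning, PerMANOVA and d-separation path analysis per
#' forest stratum and fungal guild.
#'
#' @param simulate a [synthetic_config()] (ignored when `dataset` is
#'   passed to [run_pipeline()] directly).
#' @param guilds guild subsets to analyse.
#' @param strata named character vector `sample -> stratum`, or
#'   `"latitude"` to split sites at the median site latitude into
#'   `"temperate"` (north) and `"tropic_subtropical"` (south).
#' @param n_perm permutations for MRM / PerMANOVA / selection.
#' @param n_null Raup-Crick null replicates.
#' @param alpha significance level.
#' @param graph a [causal_graph()]; default is the hypothesized model in
#'   which paleoclimate, current climate and space drive both the plant
#'   and the fungal community, and soil and plants drive fungi.
#' @param run_dsep,run_varpart,run_permanova stage switches.
#' @param out_dir optional output directory for the JSON/TSV report.
#' @param seed master seed (mandatory).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = synthetic_config(),
                            guilds = c("total", "saprotroph", "EM", "pathogen"),
                            strata = "latitude",
                            n_perm = 999L, n_null = 199L, alpha = 0.05,
                            graph = default_composition_graph(),
                            run_dsep = TRUE, run_varpart = TRUE,
                            run_permanova = TRUE,
                            out_dir = NULL, seed = 1L) {
  if (missing(seed) || is.null(seed)) stop("config error: seed is mandatory")
  structure(list(simulate = simulate, guilds = guilds, strata = strata,
                 n_perm = as.integer(n_perm), n_null = as.integer(n_null),
                 alpha = alpha, graph = graph,
                 run_dsep = run_dsep, run_varpart = run_varpart,
                 run_permanova = run_permanova,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default hypothesized causal model for community composition
#'
#' On a latitudinal transect the abiotic drivers are interconnected:
#' geographic position is upstream of paleoclimate and current climate
#' (with the paleoclimate also shaping the present climate), and all
#' three shape the soils; paleoclimate, climate and space shape the plant
#' community; and plants, soil, climate, paleoclimate and space all act
#' on the fungal community. The single testable independence claim is
#' whether the plant community is independent of soil given their shared
#' climatic and spatial drivers — i.e. whether a direct soil-plant path
#' is needed. (Pairs of site-level abiotic variables are deliberately
#' kept adjacent: on a transect their distances share the between-site
#' block structure, so their mutual independence is not resolvable by
#' matrix conditioning.)
#'
#' @return a [causal_graph()].
#' @export
default_composition_graph <- function() {
  causal_graph(c("space -> paleoclimate", "space -> climate",
                 "paleoclimate -> climate",
                 "space -> soil", "paleoclimate -> soil", "climate -> soil",
                 "space -> plant", "paleoclimate -> plant", "climate -> plant",
                 "space -> fungal", "paleoclimate -> fungal",
                 "climate -> fungal", "soil -> fungal", "plant -> fungal"))
}

assign_strata <- function(dataset, strata) {
  smp <- dataset$samples
  if (identical(strata, "latitude")) {
    cut_lat <- stats::median(dataset$sites$lat)
    s <- ifelse(smp$lat > cut_lat, "temperate", "tropic_subtropical")
    names(s) <- smp$sample
    return(s)
  }
  if (is.null(names(strata)) || !all(smp$sample %in% names(strata))) {
    stop("config error: strata must name every sample")
  }
  strata[smp$sample]
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (unless a dataset is supplied) -> rarefy to the
#' smallest sample depth -> per-sample covariates (soil PC1-4, current
#' MAT/MAP, paleoclimate velocity/anomaly, altitude + PCNM; the plant
#' community enters as its Raup-Crick dissimilarity and leading PCo axes,
#' recomputed per stratum) -> per stratum and guild: fungal Raup-Crick
#' matrix, PCoA axes, within-group forward selection, variation
#' partitioning, PerMANOVA, and d-separation path analysis on the
#' composite distance matrices. Every
#' stochastic stage is seeded from the master seed, so a rerun with the
#' same config reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional pre-built `synthetic_dataset` (skips simulate).
#' @return list of class `"run_report"`: `strata` (nested results),
#'   `covariates`, `stratum_of`, `provenance`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  report <- list(strata = list(), provenance = list(
    seed = config$seed, n_perm = config$n_perm, n_null = config$n_null,
    alpha = config$alpha, timings = list()))
  t0 <- proc.time()[["elapsed"]]
  tick <- function(name) {
    report$provenance$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }
  out <- tryCatch({
    if (is.null(dataset)) dataset <- simulate_dataset(config$simulate)
    tick("simulate")

    stage <- "preprocess"
    rare <- rarefy(dataset$otu_table, seed = derive_seed(config$seed, "rarefy"))
    stratum_of <- assign_strata(dataset, config$strata)
    tick("preprocess")

    stage <- "covariates"
    smp <- dataset$samples
    plant_vars <- plant_summary(dataset$plant)
    soil_scores <- soil_pca(dataset$soil, n_components = 4)$scores
    climate_vars <- data.frame(
      MAT = extract_at(dataset$climate_grids$MAT$present, smp),
      MAP = extract_at(dataset$climate_grids$MAP$present, smp),
      row.names = smp$sample)
    paleo_vars <- paleoclimate_covariates(dataset$climate_grids, smp)
    covariates <- list(plant = plant_vars, soil = as.data.frame(soil_scores),
                       climate = climate_vars, paleoclimate = paleo_vars)
    tick("covariates")

    for (st in sort(unique(stratum_of))) {
      stage <- paste0("stratum:", st)
      keep <- names(stratum_of)[stratum_of == st]
      res_st <- list()
      # space predictors recomputed within the stratum
      sp_pcnm <- pcnm(smp[keep, ], distance = "greatcircle")
      space_vars <- cbind(altitude = smp[keep, "altitude"], sp_pcnm$vectors)
      rownames(space_vars) <- keep
      cov_st <- lapply(covariates, function(v) v[keep, , drop = FALSE])
      cov_st$space <- as.data.frame(space_vars)
      # plant community composition within the stratum: Raup-Crick matrix
      # for the path analyses, leading PCo axes as the varpart plant group
      plant_rc <- raup_crick(dataset$plant$abundance[, keep, drop = FALSE],
                             n_null = config$n_null,
                             seed = derive_seed(config$seed, paste0(st, "plantrc")))
      plant_axes <- select_axes(pcoa(rescale_raup_crick(plant_rc)))
      plant_axes <- plant_axes[, seq_len(min(10L, ncol(plant_axes))), drop = FALSE]
      cov_st$plant <- as.data.frame(plant_axes)

      for (gd in config$guilds) {
        stage <- paste0("stratum:", st, " guild:", gd)
        counts <- rare$counts[, keep, drop = FALSE]
        if (!identical(gd, "total")) {
          sel <- names(dataset$guilds)[dataset$guilds == gd]
          counts <- counts[intersect(rownames(counts), sel), , drop = FALSE]
        }
        counts <- counts[rowSums(counts) > 0, , drop = FALSE]
        empty <- colSums(counts) == 0
        if (any(empty)) counts <- counts[, !empty, drop = FALSE]
        if (nrow(counts) < 5 || ncol(counts) < 10) {
          res_st[[gd]] <- list(skipped = paste("too few OTUs or samples for guild", gd))
          next
        }
        gkeep <- colnames(counts)
        rc <- raup_crick(counts, n_null = config$n_null,
                         seed = derive_seed(config$seed, paste0(st, gd, "rc")))
        rc01 <- rescale_raup_crick(rc)
        axes <- select_axes(pcoa(rc01))
        res <- list(n_samples = length(gkeep), n_otus = nrow(counts))

        groups <- lapply(cov_st, function(v) v[gkeep, , drop = FALSE])
        sel_groups <- NULL
        if (config$run_varpart || config$run_permanova) {
          sel_groups <- list()
          for (gn in names(groups)) {
            fs <- forward_select_rda(axes, groups[[gn]], alpha = config$alpha,
                                     n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, paste0(st, gd, gn)))
            if (length(fs$selected) > 0) sel_groups[[gn]] <- fs$X_selected
          }
          res$selected <- lapply(sel_groups, colnames)
        }
        if (config$run_varpart) {
          if (length(sel_groups) >= 2) {
            vp <- varpart_groups(axes, sel_groups)
            res$varpart <- list(fractions = vp$fractions,
                                total_explained = vp$total_explained,
                                paleo_total = paleo_fraction(vp))
          } else {
            res$varpart <- list(skipped = "fewer than two groups survived forward selection")
          }
        }
        if (config$run_permanova) {
          # terms are the forward-selected group variables, in group order;
          # the response is the Euclidean distance over the positive PCo
          # axes (the matrix's Euclidean part), so term sums of squares
          # partition nonnegatively
          pm_groups <- if (length(sel_groups) >= 1) sel_groups else
            lapply(groups, as.matrix)
          pm <- permanova(euclidean_env(axes, standardize = FALSE), pm_groups,
                          n_perm = config$n_perm,
                          seed = derive_seed(config$seed, paste0(st, gd, "pm")))
          res$permanova <- pm$table
        }
        if (config$run_dsep) {
          data_nodes <- list(fungal = rc,
                             plant = as_dist_matrix(unclass(plant_rc)[gkeep, gkeep]),
                             soil = euclidean_env(groups$soil),
                             climate = euclidean_env(groups$climate),
                             paleoclimate = euclidean_env(groups$paleoclimate),
                             space = euclidean_env(groups$space))
          ds <- dsep_path_analysis(config$graph, data_nodes,
                                   n_perm = config$n_perm,
                                   seed = derive_seed(config$seed, paste0(st, gd, "ds")),
                                   alpha = config$alpha)
          res$dsep <- list(C = ds$C, df = ds$df, p = ds$p, verdict = ds$verdict,
                           claims = ds$claims, coefficients = ds$coefficients)
        }
        res_st[[gd]] <- res
      }
      report$strata[[st]] <- res_st
      tick(paste0("stratum_", st))
    }
    report$stratum_of <- stratum_of
    report$covariates <- covariates
    class(report) <- "run_report"
    report
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

# total variance fraction attributable to paleoclimate = sum of all
# varpart atoms whose group set includes the paleoclimate group
paleo_fraction <- function(vp) {
  fr <- vp$fractions
  sum(fr$adj_r2[grepl("(^|,)paleoclimate(,|$)", fr$groups)])
}

#' Compare the paleoclimate contribution between strata
#'
#' Tabulates, per stratum and guild, the total variation-partitioning
#' fraction attributable to paleoclimate (unique plus shared), and the
#' difference between the first two strata.
#'
#' @param report a [run_pipeline()] report with at least two strata.
#' @return list with `table` (stratum x guild data frame of paleoclimate
#'   fractions) and `difference` (named vector per guild, first stratum
#'   minus second).
#' @export
compare_strata <- function(report) {
  sts <- names(report$strata)
  if (length(sts) < 2) {
    warning("fewer than two strata: empty comparison")
    return(list(table = data.frame(), difference = numeric(0)))
  }
  guilds <- unique(unlist(lapply(report$strata, names)))
  tab <- do.call(rbind, lapply(sts, function(st) {
    vals <- vapply(guilds, function(gd) {
      r <- report$strata[[st]][[gd]]
      if (is.null(r) || !is.null(r$skipped) || is.null(r$varpart$paleo_total)) NA_real_
      else r$varpart$paleo_total
    }, 0)
    data.frame(stratum = st, t(vals), check.names = FALSE)
  }))
  diffs <- vapply(guilds, function(gd) tab[1, gd] - tab[2, gd], 0)
  list(table = tab, difference = diffs)
}

#' Write a run report as JSON plus TSV tables
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(strip_for_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fr <- list(); ds <- list()
  for (st in names(report$strata)) {
    for (gd in names(report$strata[[st]])) {
      r <- report$strata[[st]][[gd]]
      if (!is.null(r$varpart$fractions)) {
        fr[[length(fr) + 1]] <- cbind(stratum = st, guild = gd, r$varpart$fractions)
      }
      if (!is.null(r$dsep)) {
        ds[[length(ds) + 1]] <- data.frame(stratum = st, guild = gd,
                                           C = r$dsep$C, df = r$dsep$df,
                                           p = r$dsep$p, verdict = r$dsep$verdict)
      }
    }
  }
  if (length(fr)) utils::write.table(do.call(rbind, fr), file.path(dir, "fractions.tsv"),
                                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(ds)) utils::write.table(do.call(rbind, ds), file.path(dir, "dsep.tsv"),
                                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

strip_for_json <- function(x) {
  if (inherits(x, "data.frame")) return(x)
  if (is.list(x)) {
    x <- x[!vapply(x, function(e) is.matrix(e) && length(e) > 1e4, TRUE)]
    return(lapply(unclass(x), strip_for_json))
  }
  x
}
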