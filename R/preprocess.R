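#' Construct an OTU table
#'
#' Nonnegative integer counts, OTUs in rows and samples in columns, with
#' per-sample metadata (site, quadrat).
#'
#' @param counts numeric matrix with unique row (OTU) and column (sample)
#'   names.
#' @param sample_meta data frame with columns `sample`, `site` (and
#'   optionally `quadrat`), one row per sample; defaults to a single site.
#' @return object of class `"otu_table"`: list with `counts` and
#'   `sample_meta`.
#' @export
otu_table <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("input error: negative counts")
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("OTU%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("input error: duplicate OTU labels")
  if (anyDuplicated(colnames(counts))) stop("input error: duplicate sample labels")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample = colnames(counts), site = "site1",
                              quadrat = seq_len(ncol(counts)), stringsAsFactors = FALSE)
  }
  if (!all(colnames(counts) %in% sample_meta$sample)) {
    stop("input error: sample_meta is missing samples present in counts")
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- sample_meta$sample
  structure(list(counts = counts, sample_meta = sample_meta), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%d sites), total reads %s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$sample_meta$site)),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

as_counts <- function(x) if (inherits(x, "otu_table")) x$counts else as.matrix(x)

#' Gate OTUs by BLAST best-hit e-value
#'
#' Decides whether an OTU's best database hit is reliable enough to assign
#' it to the fungal kingdom: e-values below 1e-50 are accepted, values
#' between 1e-50 and 1e-20 (inclusive) are flagged for manual checking,
#' and values above 1e-20 are excluded.
#'
#' @param evalue numeric vector of best-hit e-values (> 0).
#' @return factor with levels `accept`, `manual_check`, `exclude`.
#' @export
gate_by_evalue <- function(evalue) {
  if (any(is.na(evalue)) || any(evalue <= 0)) {
    stop("input error: e-values must be positive")
  }
  out <- ifelse(evalue < 1e-50, "accept",
                ifelse(evalue <= 1e-20, "manual_check", "exclude"))
  factor(out, levels = c("accept", "manual_check", "exclude"))
}

#' Deepest taxonomic rank assignable from sequence identity
#'
#' Identity thresholds of 90, 85, 80 and 75 percent assign OTUs to genus,
#' family, order and class respectively (inclusive at the boundary); below
#' 75 only the kingdom is retained.
#'
#' @param identity numeric vector of percent identities in \[0, 100\].
#' @return factor with levels `genus`, `family`, `order`, `class`,
#'   `kingdom` (shallowest).
#' @export
assign_rank <- function(identity) {
  if (any(is.na(identity)) || any(identity < 0 | identity > 100)) {
    stop("input error: identity must lie in [0, 100]")
  }
  out <- cut(identity, breaks = c(-Inf, 75, 80, 85, 90, Inf), right = FALSE,
             labels = c("kingdom", "class", "order", "family", "genus"))
  factor(out, levels = c("genus", "family", "order", "class", "kingdom"))
}

GUILD_LEVELS <- c("AM", "EM", "saprotroph", "pathogen", "animal_parasite",
                  "mycoparasite", "unknown")

#' Assign functional guilds from annotation records
#'
#' Rules, in priority order: Glomeromycota are arbuscular mycorrhizal (AM);
#' OTUs best-matching a known ectomycorrhizal lineage are EM; otherwise an
#' OTU takes the guild to which strictly more than 75% of the species in
#' its matched genus belong; if no guild dominates, its ecology is unknown.
#'
#' @param records data frame with logical columns `is_glomeromycota` and
#'   `matches_em_lineage`, plus one column of genus-level fractions per
#'   guild among `saprotroph`, `pathogen`, `animal_parasite`,
#'   `mycoparasite` (missing columns are treated as zero).
#' @param dominance dominance threshold, default 0.75 (strict).
#' @return factor of guild labels with the closed vocabulary
#'   `AM`, `EM`, `saprotroph`, `pathogen`, `animal_parasite`,
#'   `mycoparasite`, `unknown`.
#' @export
assign_guild <- function(records, dominance = 0.75) {
  frac_cols <- intersect(c("saprotroph", "pathogen", "animal_parasite", "mycoparasite"),
                         names(records))
  fr <- as.matrix(records[, frac_cols, drop = FALSE])
  if (length(fr) == 0) fr <- matrix(0, nrow(records), 0)
  if (any(fr < 0 | fr > 1, na.rm = TRUE)) stop("input error: guild fractions must lie in [0, 1]")
  if (ncol(fr) > 0 && any(rowSums(fr, na.rm = TRUE) > 1 + 1e-8)) {
    stop("input error: guild fractions sum to more than 1")
  }
  out <- rep("unknown", nrow(records))
  if (ncol(fr) > 0) {
    best <- max.col(cbind(fr, 0), ties.method = "first")
    dominant <- best <= ncol(fr) & apply(cbind(fr, 0), 1, max) > dominance
    out[dominant] <- frac_cols[best[dominant]]
  }
  em <- isTRUE_vec(records$matches_em_lineage)
  out[em] <- "EM"
  glo <- isTRUE_vec(records$is_glomeromycota)
  out[glo] <- "AM"
  factor(out, levels = GUILD_LEVELS)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`.
#' Each sample draws from its own RNG stream derived from the master seed
#' and the sample's (sorted) position, so a sample's rarefied counts do not
#' depend on the presence or order of other samples.
#'
#' @param table an [otu_table()] or count matrix.
#' @param depth target reads per sample; defaults to the smallest sample
#'   total (the usual normalization).
#' @param seed master integer seed.
#' @return rarefied object of the same kind as the input.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  counts <- as_counts(table)
  totals <- colSums(counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (any(totals < depth)) {
    stop("input error: depth ", depth, " exceeds the total of sample(s): ",
         paste(colnames(counts)[totals < depth], collapse = ", "))
  }
  out <- counts
  ord <- rank(colnames(counts), ties.method = "first")
  for (j in seq_len(ncol(counts))) {
    tot <- totals[j]
    if (tot == depth) next
    set.seed(derive_seed(seed, ord[j]))
    cs <- cumsum(counts[, j])
    picked <- sort(sample.int(tot, depth))
    idx <- findInterval(picked - 1L, cs) + 1L  # OTU owning each picked read
    out[, j] <- tabulate(idx, nbins = nrow(counts))
  }
  storage.mode(out) <- "integer"
  if (inherits(table, "otu_table")) otu_table(out, table$sample_meta) else out
}

#' OTU richness per sample and per site
#'
#' Counts OTUs with nonzero reads, optionally restricted to one guild.
#' Per-site richness pools all of a site's samples.
#'
#' @param table an [otu_table()] (or count matrix, in which case all
#'   samples form one site).
#' @param guilds optional named vector OTU -> guild label.
#' @param guild optional guild to restrict to (requires `guilds`); one of
#'   the closed vocabulary, or `"total"` for no restriction.
#' @param warn_unrarefied warn when sample depths are uneven.
#' @return list with data frames `per_sample` (`sample`, `richness`) and
#'   `per_site` (`site`, `richness`).
#' @export
richness <- function(table, guilds = NULL, guild = "total", warn_unrarefied = TRUE) {
  tab <- if (inherits(table, "otu_table")) table else otu_table(as_counts(table))
  counts <- tab$counts
  if (!identical(guild, "total")) {
    if (is.null(guilds)) stop("input error: guild filter requires a guilds vector")
    if (!guild %in% GUILD_LEVELS) {
      stop("input error: unknown guild label '", guild, "'")
    }
    sel <- names(guilds)[guilds == guild]
    counts <- counts[intersect(rownames(counts), sel), , drop = FALSE]
  }
  tot <- colSums(tab$counts)
  if (warn_unrarefied && length(unique(tot)) > 1) {
    warning("sample depths are uneven; rarefy before comparing richness")
  }
  per_sample <- data.frame(sample = colnames(counts),
                           richness = unname(colSums(counts > 0)),
                           stringsAsFactors = FALSE)
  site <- tab$sample_meta$site
  per_site <- do.call(rbind, lapply(unique(site), function(s) {
    sub <- counts[, site == s, drop = FALSE]
    data.frame(site = s, richness = sum(rowSums(sub) > 0), stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, per_site = per_site)
}

#' Sample-based rarefaction curve for one site
#'
#' Expected accumulated OTU richness when the site's quadrat samples are
#' added in random order, averaged over `reps` random accumulation orders.
#'
#' @param table an [otu_table()].
#' @param site site label present in the table's metadata.
#' @param sizes numbers of samples to accumulate (default 1..n_site).
#' @param reps random accumulation orders to average over (>= 1).
#' @param seed integer seed.
#' @return data frame with `size` and `richness` (mean accumulated count),
#'   monotone nondecreasing in `size`.
#' @export
rarefaction_curve <- function(table, site, sizes = NULL, reps = 100L, seed = 1L) {
  if (reps < 1) stop("config error: reps must be at least 1")
  tab <- if (inherits(table, "otu_table")) table else otu_table(as_counts(table))
  keep <- tab$sample_meta$site == site
  if (!any(keep)) stop("input error: unknown site '", site, "'")
  pres <- tab$counts[, keep, drop = FALSE] > 0
  n <- ncol(pres)
  if (is.null(sizes)) sizes <- seq_len(n)
  if (any(sizes < 1 | sizes > n)) stop("input error: sizes must lie in 1..", n)
  set.seed(derive_seed(seed, site))
  acc <- matrix(0, reps, length(sizes))
  for (r in seq_len(reps)) {
    ordn <- sample.int(n)
    seen <- matrixStats_cummax(pres[, ordn, drop = FALSE])
    acc[r, ] <- colSums(seen)[sizes]
  }
  data.frame(size = sizes, richness = colMeans(acc))
}

# running "has been seen" per OTU across accumulated samples
matrixStats_cummax <- function(pres) {
  out <- pres
  if (ncol(pres) > 1) {
    for (j in 2:ncol(pres)) out[, j] <- out[, j] | out[, j - 1]
  }
  out
}

#' Principal component analysis of soil variables
#'
#' Variables are z-scored (units differ wildly across soil measurements)
#' and decomposed with [stats::prcomp]; constant variables are dropped with
#' a warning.
#'
#' @param soil sample-by-variable data frame or matrix.
#' @param n_components number of components to return (default all).
#' @return list with `scores` (samples x components), `loadings`,
#'   `variance_fraction`, and `dropped` (names of constant variables).
#' @export
soil_pca <- function(soil, n_components = NULL) {
  x <- as.matrix(soil)
  if (nrow(x) < 2 || ncol(x) < 2) stop("input error: PCA needs >= 2 samples and >= 2 variables")
  if (anyNA(x)) stop("input error: soil table contains missing values")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant variable(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(n_components %||% ncol(p$x), ncol(p$x))
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       variance_fraction = vf[seq_len(k)],
       dropped = dropped)
}
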