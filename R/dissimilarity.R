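#' Modified Raup-Crick dissimilarity
#'
#' Null-model-standardized presence/absence dissimilarity in \[-1, 1\]
#' expressing whether two communities share fewer or more taxa than
#' expected given their richness. For each null replicate, one null
#' assemblage is drawn per sample preserving its observed richness, with
#' species selected without replacement with probability proportional to
#' their occurrence frequency across the dataset; all pairs are scored
#' against that replicate. For each pair,
#' `p = (#null shared > observed + 0.5 * ties) / n_null` and
#' `RC = (p - 0.5) * 2`, so values near 1 mean the pair shares fewer
#' species than the richness-preserving null expects (turnover) and values
#' near -1 more (convergence).
#'
#' @param x an [otu_table()] or OTU-by-sample matrix; counts are binarized.
#' @param n_null number of null replicates (default 999).
#' @param seed integer seed.
#' @return a [as_dist_matrix()] with entries in \[-1, 1\].
#' @export
raup_crick <- function(x, n_null = 999L, seed = 1L) {
  counts <- as_counts(x)
  pres <- counts > 0
  storage.mode(pres) <- "integer"
  occ <- rowSums(pres)
  pool <- occ > 0
  pres <- pres[pool, , drop = FALSE]
  w <- occ[pool]
  S <- nrow(pres); n <- ncol(pres)
  k <- colSums(pres)
  if (any(k == 0)) {
    stop("input error: empty sample(s): ",
         paste(colnames(pres)[k == 0], collapse = ", "))
  }
  if (any(k > S)) stop("input error: sample richer than the species pool")
  obs_shared <- crossprod(pres)
  more <- matrix(0, n, n); ties <- matrix(0, n, n)
  set.seed(derive_seed(seed, "raup_crick"))
  null <- matrix(0L, S, n)
  for (r in seq_len(n_null)) {
    null[] <- 0L
    for (j in seq_len(n)) {
      null[sample.int(S, k[j], prob = w), j] <- 1L
    }
    ns <- crossprod(null)
    more <- more + (ns > obs_shared)
    ties <- ties + (ns == obs_shared)
  }
  p <- (more + 0.5 * ties) / n_null
  rc <- (p - 0.5) * 2
  dimnames(rc) <- dimnames(obs_shared)
  diag(rc) <- 0
  as_dist_matrix((rc + t(rc)) / 2)
}

#' Rescale a Raup-Crick matrix from [-1, 1] to the [0, 1] dissimilarity scale
#'
#' Metric ordination (PCoA) and PerMANOVA operate on squared distances, so
#' the signed index — where -1 (more shared than the null) and +1 (fewer)
#' both square to 1 — must first be shifted to `(RC + 1) / 2`. The
#' diagonal stays 0.
#'
#' @param dm a Raup-Crick `dist_matrix` with entries in \[-1, 1\].
#' @return a `dist_matrix` with entries in \[0, 1\].
#' @export
rescale_raup_crick <- function(dm) {
  dm <- as_dist_matrix(dm)
  if (any(dm < -1 - 1e-12) || any(dm > 1 + 1e-12)) {
    stop("input error: entries outside [-1, 1]")
  }
  m <- (unclass(dm) + 1) / 2
  diag(m) <- 0
  as_dist_matrix(m)
}

#' Euclidean environmental distance matrix
#'
#' @param x sample-by-variable numeric data frame or matrix with row names.
#' @param standardize z-score the variables first (default TRUE; variables
#'   are typically on incommensurate scales).
#' @return a [as_dist_matrix()].
#' @export
euclidean_env <- function(x, standardize = TRUE) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("input error: non-numeric variables")
  bad <- rownames(m)[rowSums(is.na(m)) > 0]
  if (length(bad) > 0) {
    stop("input error: missing values in rows: ", paste(bad, collapse = ", "))
  }
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    m <- scale(m[, sds > 0, drop = FALSE])
  }
  as_dist_matrix(stats::dist(m))
}

#' Principal coordinate analysis
#'
#' Metric ordination by Gower double-centering and eigendecomposition.
#' Axes with positive eigenvalues are returned; relative variance is
#' computed over the positive eigenvalues only (non-Euclidean matrices
#' such as Raup-Crick produce negative eigenvalues, which are excluded
#' from the denominator). The Cailliez correction adds the smallest
#' constant making the matrix Euclidean-embeddable.
#'
#' @param dm a [as_dist_matrix()] (or coercible).
#' @param correction `"none"` or `"cailliez"`.
#' @return list of class `"pcoa_result"`: `scores` (samples x positive
#'   axes), `eigenvalues` (all, descending), `relative_variance` and
#'   `cumulative_variance` over positive axes.
#' @export
pcoa <- function(dm, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  dm <- as_dist_matrix(dm)
  n <- nrow(dm)
  if (all(dm == 0)) {
    warning("all-zero distance matrix: degenerate single axis")
    return(structure(list(scores = matrix(0, n, 1, dimnames = list(rownames(dm), "PCo1")),
                          eigenvalues = rep(0, n), relative_variance = 1,
                          cumulative_variance = 1, correction = correction),
                     class = "pcoa_result"))
  }
  d <- stats::as.dist(unclass(dm))
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are expected for non-Euclidean input and handled below
  fit <- suppressWarnings(
    stats::cmdscale(d, k = n - 1, eig = TRUE, add = (correction == "cailliez")))
  ev <- fit$eig
  tol <- 1e-8 * max(abs(ev))
  pos <- which(ev > tol)
  scores <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(scores) <- paste0("PCo", seq_along(pos))
  rownames(scores) <- rownames(dm)
  rv <- ev[pos] / sum(ev[pos])
  structure(list(scores = scores, eigenvalues = ev,
                 relative_variance = rv, cumulative_variance = cumsum(rv),
                 correction = correction),
            class = "pcoa_result")
}

#' Select ordination axes explaining all the (positive) variation
#'
#' Returns the scores of every positive-eigenvalue axis — together they
#' cumulatively explain 100% of the representable variation and are the
#' response table for variation partitioning.
#'
#' @param p a [pcoa()] result.
#' @return numeric matrix of scores.
#' @export
select_axes <- function(p) {
  stopifnot(inherits(p, "pcoa_result"))
  p$scores
}

#' Principal coordinates of neighbour matrices (spatial eigenvectors)
#'
#' Builds spatial predictors from point coordinates: pairwise geographic
#' distances are truncated at the largest edge of their minimum spanning
#' tree, beyond-threshold entries are set to four times the threshold, and
#' the truncated matrix is subjected to PCoA; eigenvectors with positive
#' eigenvalues are the PCNM spatial variables.
#'
#' @param coords data frame with `lat`/`lon` (decimal degrees) or `x`/`y`.
#' @param distance `"greatcircle"` (haversine, km) or `"euclidean"`
#'   (raw coordinate units, the convention of analyses run directly on
#'   lat/lon degrees).
#' @return list of class `"pcnm_result"`: `vectors` (samples x PCNMs),
#'   `eigenvalues` (positive ones), `threshold` (truncation distance).
#' @export
pcnm <- function(coords, distance = c("greatcircle", "euclidean")) {
  distance <- match.arg(distance)
  if (!is.null(coords$lat)) xy <- cbind(coords$lon, coords$lat) else xy <- cbind(coords$x, coords$y)
  ids <- coords$sample %||% rownames(coords) %||% paste0("s", seq_len(nrow(xy)))
  if (nrow(unique(xy)) < 3) stop("input error: need at least 3 distinct locations")
  if (nrow(unique(xy)) < nrow(xy)) warning("duplicate coordinates present")
  d <- if (distance == "greatcircle") {
    as.dist(geosphere::distm(xy, fun = geosphere::distHaversine) / 1000)
  } else {
    stats::dist(xy)
  }
  threshold <- max(vegan::spantree(d)$dist)
  m <- as.matrix(d)
  m[m > threshold] <- 4 * threshold
  dimnames(m) <- list(ids, ids)
  fit <- pcoa(as_dist_matrix(m))
  keep <- which(fit$eigenvalues > 1e-8 * max(abs(fit$eigenvalues)))
  vectors <- fit$scores
  colnames(vectors) <- paste0("PCNM", seq_len(ncol(vectors)))
  structure(list(vectors = vectors, eigenvalues = fit$eigenvalues[keep],
                 threshold = threshold, distance = distance),
            class = "pcnm_result")
}

#' Write / read a distance matrix as labelled TSV
#'
#' @param dm a `dist_matrix`.
#' @param path file path.
#' @export
write_dist_tsv <- function(dm, path) {
  utils::write.table(unclass(as_dist_matrix(dm)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  as_dist_matrix(m)
}
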