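# model matrix without intercept column from a matrix / data frame of
# predictors (factors expanded); rows kept in input order
expand_predictors <- function(x) {
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    return(x)
  }
  if (is.null(dim(x))) x <- data.frame(x = x)
  x <- as.data.frame(x)
  names(x) <- make.unique(names(x))
  stats::model.matrix(~ ., data = x)[, -1, drop = FALSE]
}

# hat matrix of cbind(1, X), with aliased columns dropped
hat_matrix <- function(X, warn_alias = TRUE) {
  Xf <- cbind(1, X)
  q <- qr(Xf)
  if (q$rank < ncol(Xf) && warn_alias) {
    warning("rank-deficient predictors: ", ncol(Xf) - q$rank,
            " aliased column(s) dropped")
  }
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = q$rank - 1L)  # rank excludes intercept
}

#' Redundancy-analysis R-squared of ordination scores on predictors
#'
#' Multivariate R-squared (trace of the fitted sum of squares over the
#' total, response centred) and Ezekiel's adjusted R-squared
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` with `p` the predictor rank.
#'
#' @param Y numeric matrix of response scores (samples x axes).
#' @param X predictor columns (matrix or data frame; factors expanded).
#' @param warn_alias warn when aliased predictor columns are dropped.
#' @return list with `r2`, `adj_r2`, `rank`.
#' @export
rda_r2 <- function(Y, X, warn_alias = TRUE) {
  Y <- as.matrix(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  X <- expand_predictors(X)
  if (nrow(Yc) != nrow(X)) stop("input error: row mismatch between response and predictors")
  hm <- hat_matrix(X, warn_alias = warn_alias)
  n <- nrow(Yc); p <- hm$rank
  if (n <= p + 1) stop("input error: need n > p + 1")
  fitted <- hm$H %*% Yc
  r2 <- sum(fitted^2) / sum(Yc^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(r2 = r2, adj_r2 = adj, rank = p)
}

#' Forward selection of variables within one predictor group
#'
#' Greedy double-stopping selection against multivariate ordination
#' scores: a variable is added when it gives the largest adjusted-R-squared
#' gain, its partial pseudo-F permutation p-value is below `alpha`, and
#' the cumulative (unadjusted) R-squared does not exceed the full group's
#' adjusted R-squared — the usual guard against selection creep in noisy
#' groups.
#'
#' @param Y response score matrix.
#' @param X candidate columns (data frame or matrix).
#' @param alpha per-variable significance level.
#' @param n_perm permutations for the partial-F test.
#' @param seed integer seed.
#' @return list with `selected` (column names, entry order), `X_selected`
#'   (matrix, possibly zero columns), `log`.
#' @export
forward_select_rda <- function(Y, X, alpha = 0.05, n_perm = 499L, seed = 1L) {
  Y <- as.matrix(Y)
  X <- expand_predictors(X)
  if (ncol(X) == 0) stop("input error: empty predictor group")
  full_adj <- rda_r2(Y, X, warn_alias = FALSE)$adj_r2
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Yc)
  selected <- integer(0)
  cur_adj <- 0
  log <- list()
  set.seed(derive_seed(seed, "fsel"))
  # permutation p of the partial pseudo-F for adding `cand` to `sel`;
  # orthonormal bases are fixed across permutations, only Y permutes
  perm_p <- function(sel, cand) {
    q0 <- qr(cbind(1, X[, sel, drop = FALSE]))
    Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
    q1 <- qr(cbind(1, X[, c(sel, cand), drop = FALSE]))
    Q1 <- qr.Q(q1)[, seq_len(q1$rank), drop = FALSE]
    df1 <- q1$rank - q0$rank
    df2 <- max(n - q1$rank, 1)
    fstat <- function(Ym) {
      tot <- sum(Ym^2)
      rss0 <- tot - sum(crossprod(Q0, Ym)^2)
      rss1 <- tot - sum(crossprod(Q1, Ym)^2)
      ((rss0 - rss1) / df1) / (rss1 / df2)
    }
    f_obs <- fstat(Yc)
    ge <- 0
    for (b in seq_len(n_perm)) {
      ge <- ge + (fstat(Yc[sample.int(n), , drop = FALSE]) >= f_obs - 1e-12)
    }
    (ge + 1) / (n_perm + 1)
  }
  cur_r2 <- 0
  repeat {
    remaining <- setdiff(seq_len(ncol(X)), selected)
    if (length(remaining) == 0) break
    fits <- lapply(remaining, function(j) {
      tryCatch(rda_r2(Y, X[, c(selected, j), drop = FALSE], warn_alias = FALSE),
               error = function(e) NULL)
    })
    # skip candidates aliased with the current model (no rank gain)
    rank_now <- if (length(selected)) hat_matrix(X[, selected, drop = FALSE], warn_alias = FALSE)$rank else 0L
    ok <- vapply(fits, function(f) !is.null(f) && f$rank > rank_now, TRUE)
    if (!any(ok)) break
    gains <- vapply(fits, function(f) if (is.null(f)) -Inf else f$adj_r2 - cur_adj, 0)
    pick <- which(ok)[which.max(gains[ok])]
    j <- remaining[pick]
    # cap cumulative R2 at the full-group adjusted R2 from the second
    # variable on; the first significant variable is always admissible
    if (length(selected) > 0 && fits[[pick]]$r2 > full_adj + 1e-10) break
    new_adj <- fits[[pick]]$adj_r2
    p <- perm_p(selected, j)
    if (p >= alpha) break
    selected <- c(selected, j)
    cur_adj <- new_adj
    log[[length(log) + 1]] <- data.frame(variable = colnames(X)[j],
                                         adj_r2 = cur_adj, p = p)
  }
  list(selected = colnames(X)[selected],
       X_selected = X[, selected, drop = FALSE],
       log = if (length(log)) do.call(rbind, log) else
         data.frame(variable = character(), adj_r2 = numeric(), p = numeric()))
}

#' Variation partitioning among 2-5 predictor groups
#'
#' Adjusted R-squared is computed for every non-empty union of groups and
#' decomposed into the 2^g - 1 unique and shared fractions by Moebius
#' inversion over the subset lattice (inclusion-exclusion). Negative
#' adjusted fractions are reported as-is, as is conventional.
#'
#' @param Y response score matrix (e.g. positive-eigenvalue PCo scores).
#' @param groups named list of 2-5 predictor column sets.
#' @return list of class `"varpart_result"`: `fractions` (data frame:
#'   `groups` — comma-joined group names of the atom —, `adj_r2`),
#'   `subset_adj_r2` (per union), `total_explained` (full-model adjusted
#'   R-squared), `residual`.
#' @export
varpart_groups <- function(Y, groups) {
  g <- length(groups)
  if (g < 2 || g > 5) stop("unsupported: varpart needs 2-5 groups")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_len(g))
  groups <- lapply(groups, expand_predictors)
  subsets <- lapply(seq_len(2^g - 1), function(mask) which(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0))
  key <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  R <- vapply(subsets, function(s) {
    rda_r2(Y, do.call(cbind, groups[s]), warn_alias = FALSE)$adj_r2
  }, 0)
  names(R) <- key
  allg <- seq_len(g)
  Rfull <- R[[paste(allg, collapse = ",")]]
  # Q(U) = Rfull - R(complement of U); Moebius inversion gives the atoms
  Q <- vapply(subsets, function(u) {
    comp <- setdiff(allg, u)
    if (length(comp) == 0) Rfull else Rfull - R[[paste(comp, collapse = ",")]]
  }, 0)
  names(Q) <- key
  fractions <- vapply(seq_along(subsets), function(i) {
    s <- subsets[[i]]
    subsub <- lapply(seq_len(2^length(s) - 1), function(mask)
      s[which(bitwAnd(mask, 2^(seq_along(s) - 1)) > 0)])
    sum(vapply(subsub, function(t)
      (-1)^(length(s) - length(t)) * Q[[paste(sort(t), collapse = ",")]], 0))
  }, 0)
  atom_names <- vapply(subsets, function(s) paste(names(groups)[s], collapse = ","), "")
  structure(list(
    fractions = data.frame(groups = atom_names, n_groups = lengths(subsets),
                           adj_r2 = fractions, stringsAsFactors = FALSE),
    subset_adj_r2 = stats::setNames(R, vapply(subsets, function(s)
      paste(names(groups)[s], collapse = ","), "")),
    total_explained = Rfull, residual = 1 - Rfull),
    class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("variation partitioning: total explained (adj R2) = %.4f, residual = %.4f\n",
              x$total_explained, x$residual))
  print(x$fractions, ...)
  invisible(x)
}

#' Distance-based permutational multivariate ANOVA (PerMANOVA)
#'
#' McArdle-Anderson partitioning of a Gower-centred distance matrix:
#' sequential (Type I) sums of squares per term, pseudo-F against the
#' residual, and p-values by permuting sample labels. With `by =
#' "margin"`, each term's SS is instead its marginal contribution given
#' all other terms.
#'
#' @param dm a `dist_matrix`.
#' @param terms named list of term predictor sets (each a vector, factor,
#'   matrix or data frame aligned with the matrix labels), or a data frame
#'   whose columns are the terms.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param by `"terms"` (sequential) or `"margin"`.
#' @return list of class `"permanova_result"`: `table` (data frame with
#'   `term`, `df`, `ss`, `r2`, `pseudo_f`, `p`), `n_perm`, `seed`.
#' @export
permanova <- function(dm, terms, n_perm = 999L, seed = 1L,
                      by = c("terms", "margin")) {
  by <- match.arg(by)
  if (n_perm < 99) stop("input error: n_perm must be at least 99")
  dm <- as_dist_matrix(dm)
  n <- nrow(dm)
  if (is.data.frame(terms)) terms <- as.list(terms)
  if (is.null(names(terms)) || any(names(terms) == "")) {
    names(terms) <- paste0("t", seq_along(terms))
  }
  Xs <- lapply(terms, function(t) {
    m <- expand_predictors(t)
    if (nrow(m) != n) stop("input error: term length does not match matrix")
    if (qr(cbind(1, m))$rank <= 1) stop("input error: constant term")
    m
  })
  A <- -0.5 * unclass(dm)^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  k <- length(Xs)
  hats <- vector("list", k)       # cumulative hats for sequential SS
  ranks <- integer(k)
  for (i in seq_len(k)) {
    hm <- hat_matrix(do.call(cbind, Xs[seq_len(i)]), warn_alias = FALSE)
    hats[[i]] <- hm$H
    ranks[i] <- hm$rank
  }
  H0 <- matrix(1 / n, n, n)
  Hfull <- hats[[k]]
  df_res <- n - 1L - ranks[k]
  ss_of <- function(Gm) {
    tr <- function(H) sum(H * Gm)   # tr(HG), both symmetric
    total <- sum(diag(Gm))
    if (by == "terms") {
      prev <- c(list(H0), hats[-k])
      ss <- vapply(seq_len(k), function(i) tr(hats[[i]]) - tr(prev[[i]]), 0)
    } else {
      ss <- vapply(seq_len(k), function(i) {
        others <- hat_matrix(do.call(cbind, Xs[-i]), warn_alias = FALSE)$H
        tr(Hfull) - tr(others)
      }, 0)
    }
    res <- total - tr(Hfull)
    list(ss = ss, res = res)
  }
  obs <- ss_of(G)
  df_term <- if (by == "terms") diff(c(0L, ranks)) else
    vapply(seq_len(k), function(i)
      ranks[k] - hat_matrix(do.call(cbind, Xs[-i]), warn_alias = FALSE)$rank, 0L)
  f_obs <- (obs$ss / df_term) / (obs$res / df_res)
  set.seed(derive_seed(seed, "permanova"))
  ge <- numeric(k)
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    st <- ss_of(G[pm, pm])
    fb <- (st$ss / df_term) / (st$res / df_res)
    ge <- ge + (fb >= f_obs - 1e-12)
  }
  p <- (ge + 1) / (n_perm + 1)
  total <- sum(diag(G))
  tab <- data.frame(term = c(names(terms), "Residual", "Total"),
                    df = c(df_term, df_res, n - 1L),
                    ss = c(obs$ss, obs$res, total),
                    r2 = c(obs$ss, obs$res, total) / total,
                    pseudo_f = c(f_obs, NA, NA),
                    p = c(p, NA, NA),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = n_perm, seed = seed, by = by),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PerMANOVA (%s SS, %d permutations)\n", x$by, x$n_perm))
  print(x$table, ...)
  invisible(x)
}
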