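#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of an unfolded response distance matrix on one
#' or more unfolded predictor matrices, with significance assessed by
#' jointly permuting the rows and columns of the response matrix: the
#' overall p-value counts permuted R-squared values reaching the observed
#' one, and per-coefficient p-values count permuted |t| statistics
#' reaching the observed |t|. Both use the add-one rule
#' `p = (#{perm >= obs} + 1) / (n_perm + 1)`.
#'
#' @param response a `dist_matrix` (or coercible).
#' @param predictors named list of `dist_matrix` objects sharing the
#'   response's sample labels.
#' @param n_perm number of permutations (default 10000; 999 is a usual
#'   fast setting).
#' @param seed integer seed.
#' @return list of class `"mrm_result"`: `coefficients` (data frame with
#'   `term`, `beta`, `t`, `p_perm`), `r_squared`, `p_overall`, `n_perm`,
#'   `seed`, `n` (samples), `labels`.
#' @export
mrm_fit <- function(response, predictors, n_perm = 10000L, seed = 1L) {
  if (inherits(predictors, "dist_matrix") || inherits(predictors, "dist")) {
    predictors <- list(x = predictors)
  }
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("x", seq_along(predictors))
  }
  response <- as_dist_matrix(response)
  labels <- sort(rownames(response))
  preds <- lapply(predictors, function(p) {
    p <- as_dist_matrix(p)
    if (!setequal(rownames(p), labels)) stop("input error: predictor labels do not match response")
    unfold(p)
  })
  y <- as.numeric(unfold(response))
  n <- length(labels)
  N <- length(y)
  X <- cbind(`(Intercept)` = 1, do.call(cbind, lapply(preds, as.numeric)))
  colnames(X) <- c("(Intercept)", names(predictors))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    alias <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("input error: collinear predictors: ", paste(alias, collapse = ", "))
  }
  XtXi <- chol2inv(chol(crossprod(X)))
  Px <- XtXi %*% t(X)                  # (p+1) x N projector onto coefficients
  stats_of <- function(Y) {            # Y: N x m matrix of responses
    B <- Px %*% Y
    FITTED <- X %*% B
    RSS <- colSums((Y - FITTED)^2)
    ybar <- colMeans(Y)
    TSS <- colSums(Y^2) - N * ybar^2
    r2 <- 1 - RSS / TSS
    sigma2 <- RSS / (N - ncol(X))
    tmat <- B / sqrt(outer(diag(XtXi), sigma2))
    list(r2 = r2, t = tmat, beta = B)
  }
  obs <- stats_of(matrix(y, N, 1))
  set.seed(derive_seed(seed, "mrm"))
  idx <- unfold_index(n)
  ut <- which(lower.tri(idx))          # positions matching unfold's order via t()
  idx_t <- t(idx)
  ge_r2 <- 0
  ge_t <- numeric(ncol(X))
  chunk <- max(1L, min(n_perm, as.integer(2e7 / N)))
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    Y <- matrix(0, N, m)
    for (j in seq_len(m)) {
      pm <- sample.int(n)
      Y[, j] <- y[idx_t[pm, pm][ut]]
    }
    st <- stats_of(Y)
    ge_r2 <- ge_r2 + sum(st$r2 >= obs$r2[1] - 1e-12)
    ge_t <- ge_t + rowSums(abs(st$t) >= abs(obs$t[, 1]) - 1e-12)
    done <- done + m
  }
  p_overall <- (ge_r2 + 1) / (n_perm + 1)
  p_coef <- (ge_t + 1) / (n_perm + 1)
  coefs <- data.frame(term = colnames(X), beta = obs$beta[, 1],
                      t = obs$t[, 1], p_perm = p_coef,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, r_squared = obs$r2[1],
                 p_overall = p_overall, n_perm = n_perm, seed = seed,
                 n = n, labels = labels),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM on %d samples (%d pairs), R2 = %.4f, overall p = %.4g (%d permutations)\n",
              x$n, x$n * (x$n - 1) / 2, x$r_squared, x$p_overall, x$n_perm))
  print(x$coefficients, ...)
  invisible(x)
}

#' Forward selection of predictor distance matrices for MRM
#'
#' Greedy selection: at each step the candidate giving the largest
#' R-squared increase whose Bonferroni-corrected per-coefficient
#' permutation p-value is below `alpha` is added; selection stops when no
#' candidate qualifies, or when an addition pushes any included term's
#' corrected p to `alpha` or above (that addition is reverted). The
#' Bonferroni divisor is the total number of candidate matrices.
#' Candidates collinear with the current model are skipped, so of two
#' duplicated matrices only the first (input order) can be selected.
#'
#' @param response a `dist_matrix`.
#' @param candidates named list of `dist_matrix` candidates.
#' @param alpha significance level after correction (default 0.05).
#' @param n_perm,seed passed to [mrm_fit()].
#' @return list of class `"mrm_selection"`: `selected` (names in order of
#'   entry), `fit` (final [mrm_fit()] result, or NULL if empty), `log`
#'   (data frame of steps).
#' @export
forward_select_mrm <- function(response, candidates, alpha = 0.05,
                               n_perm = 999L, seed = 1L) {
  if (length(candidates) < 1) stop("input error: at least one candidate required")
  if (is.null(names(candidates))) names(candidates) <- paste0("x", seq_along(candidates))
  divisor <- length(candidates)
  selected <- character(0)
  fit <- NULL
  cur_r2 <- 0
  log <- list()
  step <- 0L
  remaining <- names(candidates)
  repeat {
    step <- step + 1L
    best <- NULL
    for (nm in remaining) {
      trial_preds <- candidates[c(selected, nm)]
      fit_try <- tryCatch(
        mrm_fit(response, trial_preds, n_perm = n_perm,
                seed = derive_seed(seed, paste0(step, nm))),
        error = function(e) NULL)   # collinear with current model: skip
      if (is.null(fit_try)) next
      p_new <- fit_try$coefficients$p_perm[fit_try$coefficients$term == nm]
      p_adj <- min(1, p_new * divisor)
      gain <- fit_try$r_squared - cur_r2
      if (p_adj < alpha && (is.null(best) || gain > best$gain)) {
        best <- list(name = nm, fit = fit_try, gain = gain, p_adj = p_adj)
      }
    }
    if (is.null(best)) break
    # revert if the addition degrades an already-included term
    p_adj_all <- pmin(1, best$fit$coefficients$p_perm * divisor)
    terms <- best$fit$coefficients$term
    incl <- terms %in% c(selected, best$name)
    if (any(p_adj_all[incl] >= alpha)) break
    selected <- c(selected, best$name)
    fit <- best$fit
    cur_r2 <- fit$r_squared
    log[[length(log) + 1]] <- data.frame(step = step, added = best$name,
                                         r_squared = cur_r2, p_adj = best$p_adj)
    remaining <- setdiff(remaining, best$name)
    if (length(remaining) == 0) break
  }
  structure(list(selected = selected, fit = fit,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(step = integer(), added = character(),
                              r_squared = numeric(), p_adj = numeric())),
            class = "mrm_selection")
}

#' Range-standardized path coefficient
#'
#' `beta_std = beta * (max(x) - min(x)) / (max(y) - min(y))`, using the
#' observed ranges of the (unfolded) predictor and response
#' dissimilarities; the result is dimensionless and reads as the
#' proportional change in y across the observed range of x.
#'
#' @param beta raw regression coefficient of y on x.
#' @param x,y numeric vectors of observed predictor and response values.
#' @return numeric scalar.
#' @export
range_standardize <- function(beta, x, y) {
  rx <- diff(range(x)); ry <- diff(range(y))
  if (ry == 0) stop("input error: zero response range")
  if (rx == 0) stop("input error: constant predictor")
  beta * rx / ry
}
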