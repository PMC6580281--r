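#' Labelled symmetric dissimilarity matrices
#'
#' `as_dist_matrix()` coerces a square numeric matrix or a [stats::dist]
#' object into the validated form used throughout the package: a symmetric
#' numeric matrix with unique sample labels, zero diagonal, and symmetry
#' within `1e-12`.
#'
#' @param x a square numeric matrix with `dimnames`, or a `dist` object.
#' @param labels optional character vector of sample labels, used when `x`
#'   carries none.
#' @return a numeric matrix of class `"dist_matrix"`.
#' @export
as_dist_matrix <- function(x, labels = NULL) {
  if (inherits(x, "dist")) {
    lab <- attr(x, "Labels")
    x <- as.matrix(x)
    if (!is.null(lab)) dimnames(x) <- list(lab, lab)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("distance input must be a numeric matrix or 'dist' object")
  }
  if (nrow(x) != ncol(x)) stop("distance matrix must be square")
  if (is.null(rownames(x))) {
    if (is.null(labels)) labels <- paste0("s", seq_len(nrow(x)))
    dimnames(x) <- list(labels, labels)
  }
  if (anyDuplicated(rownames(x))) stop("sample labels must be unique")
  if (!identical(rownames(x), colnames(x))) {
    stop("row and column labels of a distance matrix must agree")
  }
  if (anyNA(x)) stop("distance matrix contains missing values")
  if (max(abs(x - t(x))) > 1e-12) {
    stop("matrix is not symmetric within 1e-12")
  }
  x <- (x + t(x)) / 2
  diag(x) <- 0
  class(x) <- c("dist_matrix", class(unclass(x)))
  x
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix:", nrow(x), "samples\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))], ...)
  invisible(x)
}

#' Unfold a distance matrix into its canonical pair vector
#'
#' Samples are put in sorted label order and the strict upper triangle is
#' read row-major, i.e. pairs (1,2), (1,3), ..., (1,n), (2,3), ...  The
#' vector carries the pair labels, so `refold()` reconstructs the matrix
#' exactly and the result is invariant to the input's sample ordering.
#'
#' @param dm a `dist_matrix` (or coercible).
#' @return numeric vector of length `n*(n-1)/2` with attributes `labels`
#'   (sorted sample labels) and class `"unfolded_dist"`.
#' @export
unfold <- function(dm) {
  dm <- as_dist_matrix(dm)
  ord <- order(rownames(dm))
  m <- unclass(dm)[ord, ord, drop = FALSE]
  v <- t(m)[lower.tri(m)]
  structure(v, labels = rownames(m), class = "unfolded_dist")
}

#' Refold an unfolded pair vector into a distance matrix
#'
#' @param v vector produced by [unfold()], or any numeric vector of length
#'   `n*(n-1)/2` with `labels` supplied.
#' @param labels sample labels (taken from `v` if absent).
#' @return a `dist_matrix`.
#' @export
refold <- function(v, labels = attr(v, "labels")) {
  if (is.null(labels)) stop("labels required to refold")
  n <- length(labels)
  if (length(v) != n * (n - 1) / 2) stop("length does not match label count")
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- as.numeric(v)  # fills column-major = row-major upper
  m <- m + t(m)
  as_dist_matrix(m)
}

# index matrix: IDX[i,j] = position of pair (i,j) in the unfolded vector
# (labels assumed already sorted); used to permute unfolded responses fast.
unfold_index <- function(n) {
  m <- matrix(0L, n, n)
  m[lower.tri(m)] <- seq_len(n * (n - 1) / 2)
  m + t(m)
}

# deterministic child seed below 2^31, so independent stages of a pipeline
# draw from reproducible, non-overlapping streams
derive_seed <- function(seed, salt) {
  if (is.character(salt)) salt <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.double(seed) * 48271 + as.double(salt) * 16807 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
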