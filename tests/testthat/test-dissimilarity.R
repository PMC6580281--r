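test_that("distance matrices validate symmetry, labels and diagonal", {
  m <- labelled_dist(5, seed = 1)
  expect_s3_class(m, "dist_matrix")
  expect_equal(diag(m), setNames(rep(0, 5), rownames(m)))
  bad <- unclass(m); bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(as_dist_matrix(bad), "symmetric")
  expect_error(as_dist_matrix(matrix(0, 2, 3)), "square")
})

test_that("unfold is canonical under sample reordering and refold inverts it", {
  m <- labelled_dist(6, seed = 2)
  v <- unfold(m)
  expect_length(v, 15)
  expect_equal(refold(v), m)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(as.numeric(unfold(as_dist_matrix(unclass(m)[perm, perm]))),
               as.numeric(v))
  m3 <- labelled_dist(3, seed = 3)
  expect_length(unfold(m3), 3)
})

test_that("Raup-Crick output is a valid dissimilarity in [-1, 1]", {
  counts <- small_counts(seed = 5, lambda = 1.5)
  rc <- raup_crick(counts, n_null = 99, seed = 1)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_equal(unclass(rc), t(unclass(rc)))
  expect_equal(unname(diag(rc)), rep(0, ncol(counts)))
  # determinism under seed
  expect_identical(raup_crick(counts, n_null = 99, seed = 1), rc)
  empty <- counts; empty[, 2] <- 0
  expect_error(raup_crick(empty, n_null = 9), "empty")
})

test_that("Raup-Crick matches exact enumeration on small pools", {
  # identical communities over a 3-species equal-occurrence pool
  pres <- matrix(c(1, 1,
                   1, 1,
                   0, 0), 3, 2, byrow = TRUE,
                 dimnames = list(letters[1:3], c("A", "B")))
  # make all 3 species occur so the pool has equal weights
  pres3 <- rbind(pres[1:2, ], c = c(1, 1))
  exact <- rc_exact(pres3)
  mc <- raup_crick(pres3, n_null = 20000, seed = 3)["A", "B"]
  expect_lt(abs(mc - exact), 0.02)
  # disjoint maximal pair shares fewer species than identical pair
  disj <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2, byrow = TRUE,
                 dimnames = list(letters[1:4], c("A", "B")))
  ident <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2, byrow = TRUE,
                  dimnames = list(letters[1:4], c("A", "B")))
  expect_gt(rc_exact(disj), rc_exact(ident))
  expect_gt(raup_crick(disj, n_null = 5000, seed = 1)["A", "B"],
            raup_crick(ident, n_null = 5000, seed = 1)["A", "B"])
})

test_that("Euclidean environmental distances match the naive double loop", {
  set.seed(8)
  x <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(sprintf("s%02d", 1:12), NULL))
  d <- euclidean_env(x, standardize = FALSE)
  naive <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) naive[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  expect_lt(max(abs(unclass(d) - naive)), 1e-10)
  expect_equal(euclidean_env(matrix(c(1, 4), 2, 1,
                                    dimnames = list(c("a", "b"), NULL)),
                             standardize = FALSE)["a", "b"], 3)
  dup <- x[c(1, 1, 2), ]; rownames(dup) <- c("a", "b", "c")
  expect_equal(euclidean_env(dup, standardize = FALSE)["a", "b"], 0)
  xna <- x; xna[3, 2] <- NA
  expect_error(euclidean_env(xna), "s03")
})

test_that("PCoA recovers collinear points and embeds Euclidean input exactly", {
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- pcoa(as_dist_matrix(m))
  expect_equal(ncol(p$scores), 1)
  expect_equal(abs(as.numeric(p$scores)), c(1, 0, 1), tolerance = 1e-8)
  expect_equal(p$relative_variance, 1)
  # planar points: inter-score distances reproduce the input
  set.seed(10)
  pts <- matrix(rnorm(14), 7, 2, dimnames = list(sprintf("s%d", 1:7), NULL))
  d <- euclidean_env(pts, standardize = FALSE)
  p2 <- pcoa(d)
  expect_equal(unname(as.matrix(dist(p2$scores))), unname(unclass(d)),
               tolerance = 1e-8)
  # no negative eigenvalues beyond numerical noise for Euclidean input
  expect_gt(min(p2$eigenvalues), -1e-8 * max(p2$eigenvalues))
  # relabelling invariance of the spectrum
  perm <- sample(7)
  p3 <- pcoa(as_dist_matrix(unclass(d)[perm, perm]))
  expect_equal(p3$eigenvalues, p2$eigenvalues, tolerance = 1e-8)
  expect_warning(pcoa(as_dist_matrix(matrix(0, 3, 3))), "degenerate")
})

test_that("select_axes returns every positive axis, cumulating to 1", {
  d <- labelled_dist(9, seed = 11)
  p <- pcoa(d)
  ax <- select_axes(p)
  expect_equal(ncol(ax), sum(p$eigenvalues > 1e-8 * max(p$eigenvalues)))
  expect_lte(ncol(ax), 8)
  expect_equal(tail(p$cumulative_variance, 1), 1)
})

test_that("PCNM vectors are centred, orthogonal, and match direct eigendecomposition", {
  coords <- data.frame(x = seq(0, 9), y = 0,
                       sample = sprintf("s%02d", 1:10))
  res <- pcnm(coords, distance = "euclidean")
  v <- res$vectors
  expect_lt(max(abs(colMeans(v))), 1e-8)
  g <- crossprod(v); diag(g) <- 0
  expect_lt(max(abs(g)), 1e-8)
  # direct oracle: eigendecomposition of the Gower-centred truncated matrix
  m <- as.matrix(dist(cbind(coords$x, coords$y)))
  thr <- res$threshold
  expect_equal(thr, 1)  # equidistant line: MST edge = 1
  m[m > thr] <- 4 * thr
  A <- -0.5 * m^2
  n <- 10; J <- diag(n) - 1 / n
  ev <- eigen(J %*% A %*% J, symmetric = TRUE)
  pos <- ev$values > 1e-8 * max(ev$values)
  expect_equal(ncol(v), sum(pos))
  oracle <- ev$vectors[, pos] %*% diag(sqrt(ev$values[pos]))
  for (k in seq_len(ncol(v))) {
    expect_equal(abs(unname(v[, k])), abs(oracle[, k]), tolerance = 1e-6)
  }
  expect_error(pcnm(data.frame(x = c(1, 1), y = c(2, 2))), "3 distinct")
  expect_warning(pcnm(data.frame(x = c(0, 0, 1, 2), y = 0)), "duplicate")
})

test_that("PCNM agrees with the vegan reference on great-circle input", {
  set.seed(12)
  coords <- data.frame(lat = runif(12, 20, 50), lon = runif(12, 100, 120),
                       sample = sprintf("s%02d", 1:12))
  res <- pcnm(coords)
  d <- as.dist(geosphere::distm(cbind(coords$lon, coords$lat),
                                fun = geosphere::distHaversine) / 1000)
  ref <- vegan::pcnm(d)
  expect_equal(ncol(res$vectors), ncol(ref$vectors))
  for (k in seq_len(ncol(res$vectors))) {
    a <- res$vectors[, k] / sqrt(sum(res$vectors[, k]^2))
    b <- ref$vectors[, k] / sqrt(sum(ref$vectors[, k]^2))
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-6)
  }
})

test_that("distance TSV round-trips", {
  m <- labelled_dist(5, seed = 13)
  f <- tempfile(fileext = ".tsv")
  write_dist_tsv(m, f)
  expect_equal(read_dist_tsv(f), m, tolerance = 1e-12)
})
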