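test_that("RDA R2 matches the hat-matrix oracle and vegan's adjusted R2", {
  set.seed(1)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  X <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("a", "b")))
  r <- rda_r2(Y, X)
  # brute-force projection
  Xf <- cbind(1, X)
  H <- Xf %*% solve(crossprod(Xf)) %*% t(Xf)
  Yc <- scale(Y, scale = FALSE)
  expect_equal(r$r2, sum((H %*% Yc)^2) / sum(Yc^2), tolerance = 1e-10)
  ref <- vegan::RsquareAdj(vegan::rda(Y ~ X))
  expect_equal(r$r2, ref$r.squared, tolerance = 1e-8)
  expect_equal(r$adj_r2, ref$adj.r.squared, tolerance = 1e-8)
  # exact linear response and orthogonal predictors
  Ylin <- X %*% matrix(rnorm(6), 2, 3)
  expect_equal(rda_r2(Ylin, X)$r2, 1, tolerance = 1e-10)
  Xo <- qr.Q(qr(cbind(1, Y)))[, -1]  # orthogonal to nothing useful
  Yortho <- qr.resid(qr(cbind(1, Xo)), Y)
  ro <- rda_r2(Yortho, Xo)
  expect_equal(ro$r2, 0, tolerance = 1e-10)
  expect_lte(ro$adj_r2, 0)
})

test_that("forward selection finds an informative column and rejects pure noise", {
  hits <- 0; null_empty <- 0
  for (s in 1:20) {
    set.seed(s)
    Y <- matrix(rnorm(30 * 2), 30, 2)
    X <- cbind(info = Y[, 1] + rnorm(30, 0, 0.3),
               matrix(rnorm(30 * 5), 30, 5,
                      dimnames = list(NULL, paste0("n", 1:5))))
    fs <- forward_select_rda(Y, X, n_perm = 99, seed = s)
    if ("info" %in% fs$selected) hits <- hits + 1
    fs0 <- forward_select_rda(Y, X[, -1], n_perm = 99, seed = s)
    if (length(fs0$selected) == 0) null_empty <- null_empty + 1
  }
  expect_gte(hits, 18)
  expect_gte(null_empty, 16)
  # duplicated column selected once
  set.seed(99)
  Y <- matrix(rnorm(30 * 2), 30, 2)
  Xd <- cbind(a = Y[, 1], b = Y[, 1])
  fsd <- forward_select_rda(Y, Xd, n_perm = 99, seed = 1)
  expect_lte(length(fsd$selected), 1)
})

test_that("varpart fractions obey inclusion-exclusion and match vegan", {
  set.seed(2)
  Y <- matrix(rnorm(40 * 4), 40, 4)
  A <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a1", "a2")))
  B <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("b1", "b2")))
  vp <- varpart_groups(Y, list(A = A, B = B))
  expect_equal(sum(vp$fractions$adj_r2), vp$total_explained, tolerance = 1e-8)
  ref <- vegan::varpart(Y, A, B)$part
  frac <- setNames(vp$fractions$adj_r2, vp$fractions$groups)
  expect_equal(unname(frac["A"]), ref$indfract$Adj.R.square[1], tolerance = 1e-8)
  expect_equal(unname(frac["B"]), ref$indfract$Adj.R.square[2], tolerance = 1e-8)
  expect_equal(unname(frac["A,B"]), ref$indfract$Adj.R.square[3], tolerance = 1e-8)
  # duplicated group: uniques zero, all variance shared
  vpd <- suppressWarnings(varpart_groups(Y, list(A = A, A2 = A)))
  fd <- setNames(vpd$fractions$adj_r2, vpd$fractions$groups)
  expect_lt(abs(fd[["A"]]), 1e-8)
  expect_lt(abs(fd[["A2"]]), 1e-8)
  expect_equal(fd[["A,A2"]], vpd$total_explained, tolerance = 1e-8)
  expect_error(varpart_groups(Y, list(A)), "2-5")
})

test_that("five-group varpart reduces to per-subset adjusted R2 identities", {
  set.seed(3)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  groups <- lapply(1:5, function(i) matrix(rnorm(60), 60, 1,
                                           dimnames = list(NULL, paste0("g", i))))
  names(groups) <- paste0("G", 1:5)
  vp <- varpart_groups(Y, groups)
  expect_equal(nrow(vp$fractions), 31)
  expect_equal(sum(vp$fractions$adj_r2), vp$total_explained, tolerance = 1e-8)
  # unique fraction of G1 = R(all) - R(all minus G1)
  u1 <- vp$fractions$adj_r2[vp$fractions$groups == "G1"]
  expect_equal(u1, vp$total_explained - vp$subset_adj_r2[["G2,G3,G4,G5"]],
               tolerance = 1e-10)
  # unadjusted total explained is monotone when a group is added
  r_sub <- rda_r2(Y, do.call(cbind, groups[1:2]))$r2
  r_all <- rda_r2(Y, do.call(cbind, groups))$r2
  expect_gte(r_all, r_sub - 1e-10)
})

test_that("PerMANOVA matches hand computation on a two-group toy", {
  # two groups of 3, within-distance 0.1, between-distance 1.0
  m <- matrix(1, 6, 6); diag(m) <- 0
  m[1:3, 1:3][m[1:3, 1:3] == 1] <- 0.1
  m[4:6, 4:6][m[4:6, 4:6] == 1] <- 0.1
  dimnames(m) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  grp <- factor(rep(c("x", "y"), each = 3))
  r <- permanova(as_dist_matrix(m), list(group = grp), n_perm = 719, seed = 1)
  # Gower-trace oracle: SS_total = sum(d^2)/n, SS_within = per-group sum(d^2)/n_g
  ss_tot <- sum(m[lower.tri(m)]^2) / 6
  ss_within <- 2 * sum((0.1^2) * 3) / 3  # each group: 3 pairs of 0.1
  ss_betw <- ss_tot - ss_within
  f_hand <- (ss_betw / 1) / (ss_within / 4)
  expect_equal(r$table$ss[1], ss_betw, tolerance = 1e-10)
  expect_equal(r$table$pseudo_f[1], f_hand, tolerance = 1e-10)
  expect_equal(sum(r$table$r2[1:2]), 1, tolerance = 1e-8)
})

test_that("PerMANOVA agrees with vegan::adonis2 and classical ANOVA", {
  set.seed(4)
  y <- rnorm(18)
  grp <- factor(rep(letters[1:3], each = 6))
  d <- as.matrix(dist(y)); dimnames(d) <- list(sprintf("s%d", 1:18), sprintf("s%d", 1:18))
  r <- permanova(as_dist_matrix(d), list(group = grp), n_perm = 999, seed = 1)
  f_classic <- summary(aov(y ~ grp))[[1]]$`F value`[1]
  expect_equal(r$table$pseudo_f[1], f_classic, tolerance = 1e-8)
  ref <- vegan::adonis2(as.dist(d) ~ grp, permutations = 999)
  expect_equal(r$table$pseudo_f[1], ref$F[1], tolerance = 1e-8)
  expect_equal(r$table$r2[1], ref$R2[1], tolerance = 1e-8)
  # two continuous terms, sequential SS against adonis2 by = "terms"
  x1 <- rnorm(18); x2 <- rnorm(18)
  r2 <- permanova(as_dist_matrix(d), list(x1 = x1, x2 = x2), n_perm = 199, seed = 1)
  ref2 <- vegan::adonis2(as.dist(d) ~ x1 + x2, permutations = 199, by = "terms")
  expect_equal(r2$table$ss[1:2], ref2$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(r2$table$pseudo_f[1:2], ref2$F[1:2], tolerance = 1e-8)
  expect_error(permanova(as_dist_matrix(d), list(c = rep(1, 18)), n_perm = 99),
               "constant")
})

test_that("permutation engines reproduce exactly under a fixed seed", {
  d <- labelled_dist(12, seed = 5)
  x <- labelled_dist(12, seed = 6)
  f1 <- mrm_fit(d, list(x = x), n_perm = 199, seed = 9)
  f2 <- mrm_fit(d, list(x = x), n_perm = 199, seed = 9)
  expect_identical(f1$p_overall, f2$p_overall)
  expect_identical(f1$coefficients, f2$coefficients)
  grp <- rnorm(12)
  p1 <- permanova(d, list(g = grp), n_perm = 199, seed = 9)
  p2 <- permanova(d, list(g = grp), n_perm = 199, seed = 9)
  expect_identical(p1$table, p2$table)
})
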