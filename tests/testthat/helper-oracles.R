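# Independent oracles used across the suite. Each is a brute-force or
# closed-form computation kept deliberately separate from the package's
# own code paths.

# --- exact Raup-Crick by enumeration -----------------------------------
# probability of drawing subset `sub` (indices) of size k by successive
# weighted sampling without replacement with weights w: sum over orderings
subset_prob <- function(sub, w) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  tot <- 0
  for (ord in perms(sub)) {
    p <- 1; rem <- sum(w)
    for (i in ord) {
      p <- p * w[i] / rem
      rem <- rem - w[i]
    }
    tot <- tot + p
  }
  tot
}

# exact modified Raup-Crick for a 2-sample binary community: enumerate all
# pairs of null assemblages with their probabilities
rc_exact <- function(pres) {
  stopifnot(ncol(pres) == 2)
  occ <- rowSums(pres)
  pool <- which(occ > 0)
  w <- occ[pool]
  kA <- sum(pres[, 1]); kB <- sum(pres[, 2])
  obs <- sum(pres[, 1] & pres[, 2])
  subsA <- combn(seq_along(pool), kA, simplify = FALSE)
  subsB <- combn(seq_along(pool), kB, simplify = FALSE)
  pA <- vapply(subsA, subset_prob, 0, w = w)
  pB <- vapply(subsB, subset_prob, 0, w = w)
  p_more <- 0; p_tie <- 0
  for (i in seq_along(subsA)) {
    for (j in seq_along(subsB)) {
      sh <- length(intersect(subsA[[i]], subsB[[j]]))
      pr <- pA[i] * pB[j]
      if (sh > obs) p_more <- p_more + pr
      if (sh == obs) p_tie <- p_tie + pr
    }
  }
  ((p_more + 0.5 * p_tie) - 0.5) * 2
}

# --- brute-force basis set over a DAG given as an adjacency matrix -----
# adj[i, j] = 1 means i -> j; vertex order is topological by construction
basis_set_bruteforce <- function(adj) {
  n <- nrow(adj)
  claims <- list()
  if (n < 2) return(claims)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j] == 1 || adj[j, i] == 1) next
      z <- sort(unique(c(which(adj[, i] == 1), which(adj[, j] == 1))))
      z <- setdiff(z, c(i, j))
      claims[[length(claims) + 1]] <- list(x = i, y = j, z = z)
    }
  }
  claims
}

# all permutations of 1..n, one per column
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- NULL
  for (pos in seq_len(n)) {
    out <- cbind(out, rbind(sub, n)[order(c(seq_len(n - 1), pos - 0.5)), , drop = FALSE])
  }
  out
}

# --- small fixture builders -------------------------------------------
labelled_dist <- function(n, seed) {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(rnorm(n * 3), n, 3)))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("s%02d", seq_len(n)))
  as_dist_matrix(m)
}

small_counts <- function(seed = 1, n_otus = 25, n_samples = 8, lambda = 6) {
  set.seed(seed)
  m <- matrix(rpois(n_otus * n_samples, lambda), n_otus, n_samples,
              dimnames = list(sprintf("OTU%03d", seq_len(n_otus)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# tiny chain-structured distance data: climate -> plant -> fungal, with
# independent per-stage noise; strong or absent coupling
chain_dist_data <- function(n = 30, coupling = 2, seed = 1) {
  set.seed(seed)
  clim <- rnorm(n)
  plant <- coupling * clim + rnorm(n)
  fungal <- coupling * plant + rnorm(n)
  labs <- sprintf("s%02d", seq_len(n))
  mk <- function(v) {
    m <- as.matrix(dist(v))
    dimnames(m) <- list(labs, labs)
    as_dist_matrix(m)
  }
  list(climate = mk(clim), plant = mk(plant), fungal = mk(fungal))
}
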