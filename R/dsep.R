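#' Construct a causal graph (DAG) over named matrix variables
#'
#' Edges may be given as a two-column data frame / matrix
#' (`from`, `to`), or as text lines of the form `"a -> b"`.
#'
#' @param edges edge specification (may be empty).
#' @param nodes optional character vector of node names (needed for
#'   isolated nodes).
#' @return list of class `"causal_graph"`: `nodes`, `edges` (data frame),
#'   `topological_order`.
#' @export
causal_graph <- function(edges = NULL, nodes = NULL) {
  if (is.character(edges)) {
    edges <- edges[nzchar(trimws(edges))]
    parts <- strsplit(sub("^\\s*edge\\s*:\\s*", "", edges), "->")
    if (any(lengths(parts) != 2)) stop("input error: edges must look like 'a -> b'")
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1)),
                        to = trimws(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  } else if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges)[1:2] <- c("from", "to")
  }
  nodes <- unique(c(nodes, edges$from, edges$to))
  if (length(nodes) == 0) stop("input error: empty graph")
  if (anyDuplicated(nodes)) stop("input error: duplicate node names")
  if (any(edges$from == edges$to)) stop("input error: self-loop")
  if (anyDuplicated(edges[, c("from", "to")])) edges <- unique(edges[, c("from", "to")])
  # Kahn's algorithm; report a cycle if one exists
  topo <- character(0)
  indeg <- table(factor(edges$to, levels = nodes))
  rem <- edges
  avail <- nodes[indeg == 0]
  while (length(avail) > 0) {
    v <- avail[1]; avail <- avail[-1]
    topo <- c(topo, v)
    out <- rem$to[rem$from == v]
    rem <- rem[rem$from != v, , drop = FALSE]
    for (w in out) if (!w %in% rem$to) avail <- c(avail, w)
  }
  if (length(topo) < length(nodes)) {
    stop("input error: graph is cyclic; cycle among: ",
         paste(setdiff(nodes, topo), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges, topological_order = topo),
            class = "causal_graph")
}

graph_parents <- function(graph, node) graph$edges$from[graph$edges$to == node]

#' Basis set of independence claims implied by a DAG
#'
#' One claim per pair of non-adjacent nodes, conditioned on the union of
#' both nodes' parents (Shipley's basis set). The member of each pair that
#' comes later in topological order is recorded as the response of the
#' conditional-independence test.
#'
#' @param graph a [causal_graph()].
#' @return list of claims, each a list with `x` (earlier node), `y`
#'   (later node, the test response), `z` (conditioning set).
#' @export
basis_set <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  nodes <- graph$topological_order
  adj <- paste(graph$edges$from, graph$edges$to)
  claims <- list()
  if (length(nodes) < 2) return(claims)
  for (i in seq_len(length(nodes) - 1)) {
    for (j in (i + 1):length(nodes)) {
      a <- nodes[i]; b <- nodes[j]
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      z <- setdiff(unique(c(graph_parents(graph, a), graph_parents(graph, b))),
                   c(a, b))
      claims[[length(claims) + 1]] <- list(x = a, y = b, z = z)
    }
  }
  claims
}

#' Fisher's C statistic and goodness-of-fit test
#'
#' Combines the k independence-claim p-values of a basis set as
#' `C = -2 * sum(log(p_i))`, compared with a chi-square distribution with
#' `2k` degrees of freedom. Large p (conventionally > 0.05) means the data
#' do not depart from the causal model.
#'
#' @param p_values numeric vector of claim p-values in (0, 1].
#' @param floor optional lower clamp (e.g. `1/(n_perm+1)`); zero p-values
#'   are clamped to it with a warning, and are an error without it.
#' @return list with `C`, `df` (= 2k), `p`.
#' @export
fisher_c <- function(p_values, floor = NULL) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("input error: p-values must lie in (0, 1]")
  }
  if (any(p == 0)) {
    if (is.null(floor)) stop("input error: p-values must lie in (0, 1]")
    warning("zero p-value(s) clamped to ", floor)
    p[p == 0] <- floor
  }
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df, p = stats::pchisq(C, df = df, lower.tail = FALSE))
}

#' d-separation path analysis over distance matrices
#'
#' Tests a causal model whose variables are distance matrices: every
#' independence claim of the DAG's basis set is evaluated by an MRM of the
#' claim's response matrix on the claimed-independent matrix plus the
#' conditioning matrices, taking the permutation p-value of the
#' claimed-independent term; the claim p-values combine into Fisher's C.
#' The model's edges are then refit (each node regressed on its parents)
#' and reported with raw and range-standardized coefficients.
#'
#' @param graph a [causal_graph()].
#' @param data named list mapping every node to a `dist_matrix`.
#' @param n_perm permutations per MRM (default 10000).
#' @param seed integer seed.
#' @param alpha rejection level for the goodness-of-fit verdict.
#' @return list of class `"dsep_result"`: `claims` (data frame with `x`,
#'   `y`, `z`, `p`), `C`, `df`, `p`, `verdict` (`"accepted"` or
#'   `"rejected"`), `coefficients` (data frame: `from`, `to`, `beta`,
#'   `beta_std`, `p_perm`), `alpha`, `n_perm`, `seed`.
#' @export
dsep_path_analysis <- function(graph, data, n_perm = 10000L, seed = 1L,
                               alpha = 0.05) {
  stopifnot(inherits(graph, "causal_graph"))
  missing_nodes <- setdiff(graph$nodes, names(data))
  if (length(missing_nodes) > 0) {
    stop("input error: missing data for node(s): ",
         paste(missing_nodes, collapse = ", "))
  }
  claims <- basis_set(graph)
  claim_rows <- list()
  p_i <- numeric(0)
  for (ci in seq_along(claims)) {
    cl <- claims[[ci]]
    preds <- data[c(cl$x, cl$z)]
    fit <- mrm_fit(data[[cl$y]], preds, n_perm = n_perm,
                   seed = derive_seed(seed, paste0("claim", ci)))
    p <- fit$coefficients$p_perm[fit$coefficients$term == cl$x]
    p_i <- c(p_i, p)
    claim_rows[[ci]] <- data.frame(x = cl$x, y = cl$y,
                                   z = paste(cl$z, collapse = ","),
                                   p = p, stringsAsFactors = FALSE)
  }
  fc <- if (length(p_i) > 0) {
    fisher_c(p_i, floor = 1 / (n_perm + 1))
  } else {
    list(C = 0, df = 0L, p = 1)   # saturated model: nothing to test
  }
  coef_rows <- list()
  for (node in graph$topological_order) {
    parents <- graph_parents(graph, node)
    if (length(parents) == 0) next
    fit <- mrm_fit(data[[node]], data[parents], n_perm = n_perm,
                   seed = derive_seed(seed, paste0("edge", node)))
    yv <- as.numeric(unfold(data[[node]]))
    for (pa in parents) {
      b <- fit$coefficients$beta[fit$coefficients$term == pa]
      pp <- fit$coefficients$p_perm[fit$coefficients$term == pa]
      xv <- as.numeric(unfold(data[[pa]]))
      coef_rows[[length(coef_rows) + 1]] <- data.frame(
        from = pa, to = node, beta = b,
        beta_std = range_standardize(b, xv, yv),
        p_perm = pp, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    claims = if (length(claim_rows)) do.call(rbind, claim_rows) else
      data.frame(x = character(), y = character(), z = character(), p = numeric()),
    C = fc$C, df = fc$df, p = fc$p,
    verdict = if (fc$p > alpha) "accepted" else "rejected",
    coefficients = if (length(coef_rows)) do.call(rbind, coef_rows) else
      data.frame(from = character(), to = character(), beta = numeric(),
                 beta_std = numeric(), p_perm = numeric()),
    alpha = alpha, n_perm = n_perm, seed = seed),
    class = "dsep_result")
}

#' @export
print.dsep_result <- function(x, ...) {
  cat(sprintf("d-sep test: C = %.3f on %d df, p = %.4g -> model %s (alpha = %g)\n",
              x$C, x$df, x$p, x$verdict, x$alpha))
  if (nrow(x$claims)) {
    cat("independence claims:\n"); print(x$claims, ...)
  }
  if (nrow(x$coefficients)) {
    cat("path coefficients:\n"); print(x$coefficients, ...)
  }
  invisible(x)
}
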