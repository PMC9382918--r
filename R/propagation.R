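#' Propagation configuration
#'
#' Controls the iterative neighbour-weighted-mean interpolation. `weight_mode`
#' selects the edge weight entering the mean: the number of attesting
#' languages (default, the headline variant), the number of language
#' families, or unweighted. Convergence is declared when the summed absolute
#' change of all non-seed estimates in one synchronous sweep falls below
#' `convergence_tol`.
#'
#' @param weight_mode `"language"`, `"family"` or `"unweighted"`
#' @param convergence_tol positive; summed absolute change threshold
#' @param max_iterations maximum number of synchronous sweeps
#' @param neighbor_threshold minimum neighbour count used downstream when
#'   filtering correlation samples (never applied to propagation itself)
#' @return object of class `propagation_config`
#' @export
propagation_config <- function(weight_mode = c("language", "family", "unweighted"),
                               convergence_tol = 1e-6,
                               max_iterations = 10000L,
                               neighbor_threshold = 0L) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(convergence_tol > 0, max_iterations >= 1L, neighbor_threshold >= 0L)
  structure(list(weight_mode = weight_mode,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 neighbor_threshold = as.integer(neighbor_threshold)),
            class = "propagation_config")
}

# Sparse symmetric weight matrix of the network under a weight mode,
# in the node order of net$nodes.
weight_matrix <- function(net, weight_mode = "language") {
  n <- length(net$nodes)
  e <- net$edges
  if (!nrow(e))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  w <- switch(weight_mode,
              language = as.numeric(e$language_weight),
              family = as.numeric(e$family_weight),
              unweighted = rep(1, nrow(e)))
  ia <- match(e$node_a, net$nodes)
  ib <- match(e$node_b, net$nodes)
  Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = c(w, w), dims = c(n, n))
}

# Seed matrix (nodes x dims) from a seed specification: either a data.frame
# with a `node` column plus dimension columns, or a match_result.
seed_matrix <- function(net, seeds, dims = NULL) {
  if (inherits(seeds, "match_result")) {
    if (is.null(dims)) dims <- seeds$dims
    seeds <- seeds$ratings
  }
  stopifnot(is.data.frame(seeds), "node" %in% names(seeds))
  if (is.null(dims)) dims <- intersect(c("valence", "arousal", "dominance"), names(seeds))
  if (!length(dims)) stop("no rating dimensions found in seeds")
  idx <- match(seeds$node, net$nodes)
  if (anyNA(idx)) {
    seeds <- seeds[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  m <- matrix(NA_real_, length(net$nodes), length(dims),
              dimnames = list(net$nodes, dims))
  for (d in dims) m[idx, d] <- seeds[[d]]
  m
}

#' Weighted mean of a node's neighbour values
#'
#' The estimate of a node is the mean of its neighbours' values, weighted by
#' the connecting edge's language weight, family weight, or 1, depending on
#' the mode. Neighbours without a defined value are omitted from the mean;
#' if no neighbour has a value the result is `NA` (signalled, never zero).
#'
#' @param node a node label
#' @param values named numeric vector of node values (may contain `NA`)
#' @param net a `colex_network`
#' @param weight_mode see [propagation_config()]
#' @return the weighted mean, or `NA_real_` if no valued neighbour exists
#' @export
weighted_neighbor_mean <- function(node, values, net,
                                   weight_mode = c("language", "family", "unweighted")) {
  weight_mode <- match.arg(weight_mode)
  e <- net$edges
  at_a <- e$node_a == node
  at_b <- e$node_b == node
  nb <- c(e$node_b[at_a], e$node_a[at_b])
  if (!length(nb)) return(NA_real_)
  w <- switch(weight_mode,
              language = as.numeric(e$language_weight),
              family = as.numeric(e$family_weight),
              unweighted = rep(1, nrow(e)))
  w <- c(w[at_a], w[at_b])
  v <- values[nb]
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * v[ok]) / sum(w[ok])
}

#' Interpolate affective ratings over a colexification network
#'
#' Nodes with known ratings (the seeds, typically the matching words of an
#' affective lexicon) keep their true values fixed. All other nodes in a
#' connected component containing at least one seed receive estimates by
#' repeated synchronous sweeps: each sweep replaces every non-seed value by
#' the weighted mean of its neighbours' current values (undefined neighbours
#' omitted). Iteration stops when the summed absolute change over all
#' non-seed nodes and dimensions falls below the configured tolerance, or at
#' the iteration cap (flagged). Components without any seed are discarded;
#' their nodes receive no estimate and are reported.
#'
#' The converged values solve the harmonic boundary problem
#' \eqn{v_i = \sum_j w_{ij} v_j / \sum_j w_{ij}} with seeds as boundary
#' values, so every estimate lies within the range of the seed values of its
#' component (maximum principle).
#'
#' @param net a `colex_network`
#' @param seeds a `match_result` or a data.frame with a `node` column plus
#'   rating columns (`valence`, `arousal`, `dominance` as available)
#' @param cfg a [propagation_config()]
#' @return object of class `propagation_result` with elements `estimates`
#'   (data.frame `node`, one column per dimension, `n_neighbors`,
#'   `is_matching`), `iterations` (named per dimension), `converged` (named
#'   logical), `discarded_nodes`, `coverage`, `dims`, `seed_nodes`.
#' @export
propagate <- function(net, seeds, cfg = propagation_config()) {
  S <- seed_matrix(net, seeds)
  dims <- colnames(S)
  n <- length(net$nodes)
  is_seed <- rowSums(!is.na(S)) > 0
  if (!any(is_seed)) stop("no seeded nodes present in the network")
  W <- weight_matrix(net, cfg$weight_mode)
  deg <- as.integer(Matrix::rowSums(W != 0))
  g <- as_igraph(net)
  comp <- igraph::components(g)$membership
  seeded_comps <- unique(comp[is_seed])
  keep <- comp %in% seeded_comps
  discarded <- net$nodes[!keep]

  V <- S  # working values; non-seeds NA until first defined
  kept_idx <- which(keep)
  Wk <- W[kept_idx, kept_idx, drop = FALSE]
  Vk <- V[kept_idx, , drop = FALSE]
  seed_k <- is_seed[kept_idx]
  iterations <- stats::setNames(rep(NA_integer_, length(dims)), dims)
  converged <- stats::setNames(rep(FALSE, length(dims)), dims)
  active <- stats::setNames(rep(TRUE, length(dims)), dims)
  # a seed may lack one dimension (e.g. lexicon without dominance SDs); such
  # entries are treated as non-seed for that dimension
  seed_mask <- !is.na(S[kept_idx, , drop = FALSE])

  for (it in seq_len(cfg$max_iterations)) {
    defined <- !is.na(Vk)
    num <- Wk %*% ifelse(defined, Vk, 0)
    den <- Wk %*% (defined + 0)
    newV <- as.matrix(num / den)
    newV[as.matrix(den) == 0] <- NA_real_
    newV[seed_mask] <- Vk[seed_mask]
    for (j in seq_along(dims)) {
      if (!active[j]) { newV[, j] <- Vk[, j]; next }
      ns <- !seed_mask[, j]
      both <- !is.na(Vk[ns, j]) & !is.na(newV[ns, j])
      change <- sum(abs(newV[ns, j][both] - Vk[ns, j][both]))
      newly <- sum(is.na(Vk[ns, j]) & !is.na(newV[ns, j]))
      still_na <- sum(is.na(newV[ns, j]))
      if (newly == 0L && still_na == 0L && change < cfg$convergence_tol) {
        converged[j] <- TRUE
        iterations[j] <- it
        active[j] <- FALSE
      }
    }
    Vk <- newV
    if (!any(active)) break
  }
  if (any(active)) {
    iterations[active] <- cfg$max_iterations
    warning("propagation hit max_iterations (", cfg$max_iterations,
            ") before convergence for: ",
            paste(dims[active], collapse = ", "))
  }

  est <- data.frame(node = net$nodes[kept_idx], stringsAsFactors = FALSE)
  for (j in seq_along(dims)) est[[dims[j]]] <- Vk[, j]
  est$n_neighbors <- deg[kept_idx]
  est$is_matching <- seed_k
  estimated <- rowSums(!is.na(Vk)) > 0
  structure(list(estimates = est,
                 iterations = iterations,
                 converged = converged,
                 discarded_nodes = discarded,
                 coverage = sum(estimated) / n,
                 dims = dims,
                 weight_mode = cfg$weight_mode,
                 seed_nodes = net$nodes[is_seed]),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("<propagation_result> %d nodes estimated (coverage %.1f%%), %d discarded\n",
              nrow(x$estimates), 100 * x$coverage, length(x$discarded_nodes)))
  cat("  iterations:", paste(sprintf("%s=%d", names(x$iterations), x$iterations),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Leave-self-out estimates for the seeded (matching) nodes
#'
#' After convergence, each seeded node receives its own estimate as the
#' weighted mean of its neighbours' values, where a neighbour contributes its
#' true rating if it is itself seeded and its converged estimate otherwise.
#' The node's own true value never enters its estimate. Seeded nodes with no
#' neighbour carrying a value are excluded (and reduce coverage).
#'
#' @param net a `colex_network`
#' @param seeds same seed specification given to [propagate()]
#' @param result the corresponding `propagation_result`
#' @param cfg the [propagation_config()] used
#' @return data.frame `node` + one estimate column per dimension +
#'   `n_neighbors`, containing only seeded nodes with at least one valued
#'   neighbour
#' @export
estimate_matching <- function(net, seeds, result, cfg = propagation_config()) {
  S <- seed_matrix(net, seeds)
  dims <- colnames(S)
  W <- weight_matrix(net, cfg$weight_mode)
  # full value vector: seeds at true values, others at converged estimates
  V <- matrix(NA_real_, length(net$nodes), length(dims),
              dimnames = list(net$nodes, dims))
  idx <- match(result$estimates$node, net$nodes)
  for (d in dims) V[idx, d] <- result$estimates[[d]]
  V[!is.na(S)] <- S[!is.na(S)]
  defined <- !is.na(V)
  num <- as.matrix(W %*% ifelse(defined, V, 0))
  den <- as.matrix(W %*% (defined + 0))
  est <- num / den
  est[den == 0] <- NA_real_
  seed_rows <- which(rowSums(!is.na(S)) > 0)
  keep <- seed_rows[rowSums(!is.na(est[seed_rows, , drop = FALSE])) > 0]
  out <- data.frame(node = net$nodes[keep], stringsAsFactors = FALSE)
  for (j in seq_along(dims)) out[[dims[j]]] <- est[keep, j]
  out$n_neighbors <- as.integer(Matrix::rowSums(W != 0))[keep]
  out
}

#' Standard deviation of a node's neighbour values
#'
#' Unweighted sample standard deviation of the defined values of a node's
#' neighbours; used to diagnose polysemy (bimodally spread neighbourhoods).
#' Undefined (`NA`) for nodes with fewer than two valued neighbours.
#'
#' @inheritParams weighted_neighbor_mean
#' @return sample SD, or `NA_real_`
#' @export
neighbor_sd <- function(net, node, values) {
  e <- net$edges
  nb <- c(e$node_b[e$node_a == node], e$node_a[e$node_b == node])
  v <- values[nb]
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v)
}

#' Neighbour-value standard deviations for all nodes
#'
#' Vectorised companion of [neighbor_sd()]: returns the sample SD of the
#' valued neighbours of every node with at least two of them.
#'
#' @param net a `colex_network`
#' @param values named numeric vector of node values
#' @return named numeric vector (nodes with >= 2 valued neighbours)
#' @export
neighbor_sd_all <- function(net, values) {
  v <- values[net$nodes]
  names(v) <- net$nodes
  W <- weight_matrix(net, "unweighted")
  defined <- !is.na(v)
  v0 <- ifelse(defined, v, 0)
  cnt <- as.numeric(W %*% (defined + 0))
  s1 <- as.numeric(W %*% v0)
  s2 <- as.numeric(W %*% v0^2)
  ok <- cnt >= 2
  sds <- sqrt(pmax(0, (s2[ok] - s1[ok]^2 / cnt[ok]) / (cnt[ok] - 1)))
  stats::setNames(sds, net$nodes[ok])
}
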