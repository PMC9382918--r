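# Independent oracles the implementation is checked against.

# Direct solution of the harmonic boundary problem: non-seed values solve
# v_i = sum_j w_ij v_j / sum_j w_ij with seeded nodes as boundary values.
# Dense linear algebra, independent of the iterative code path.
harmonic_solve_oracle <- function(net, seeds, weight_mode = "language",
                                  dim = "valence") {
  nodes <- net$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- net$edges
  w <- switch(weight_mode,
              language = e$language_weight,
              family = e$family_weight,
              unweighted = rep(1, nrow(e)))
  for (k in seq_len(nrow(e))) {
    ia <- match(e$node_a[k], nodes); ib <- match(e$node_b[k], nodes)
    W[ia, ib] <- W[ia, ib] + w[k]
    W[ib, ia] <- W[ib, ia] + w[k]
  }
  v <- rep(NA_real_, n)
  idx <- match(seeds$node, nodes)
  v[idx] <- seeds[[dim]]
  is_seed <- !is.na(v)
  # restrict to components containing a seed
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep <- comp %in% unique(comp[is_seed])
  free <- which(keep & !is_seed)
  if (length(free)) {
    D <- diag(rowSums(W)[free], nrow = length(free))
    A <- D - W[free, free, drop = FALSE]
    b <- W[free, is_seed, drop = FALSE] %*% v[is_seed]
    v[free] <- solve(A, b)
  }
  stats::setNames(v, nodes)
}

# Exact dip statistic by linear programming over every mode placement
# (boot::simplex; small n only). For each candidate mode, the CDF values at
# the unique sample points are LP variables constrained to the sup-band of
# half-width d around the ecdf, with convexity left of the mode, concavity
# right of it, monotonicity, and ordered junction values; an atom of the
# fitted CDF at the mode is modelled by a separate left-limit variable.
# Minimise d; the dip is the minimum over modes.
dip_lp_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  r <- rle(x)
  u <- r$values
  m <- length(u)
  if (m == 1) return(0)
  hi <- cumsum(r$lengths) / n
  lo <- c(0, hi[-m])
  solve_mode <- function(kind, p) {
    atom <- kind == "atom"
    nv <- m + atom + 1
    di <- nv
    ai <- if (atom) m + 1 else NA
    A1 <- NULL; b1 <- NULL  # <= constraints (nonnegative rhs)
    A2 <- NULL; b2 <- NULL  # >= constraints
    add <- function(coef, rhs) { A1 <<- rbind(A1, coef); b1 <<- c(b1, rhs) }
    addge <- function(coef, rhs) { A2 <<- rbind(A2, coef); b2 <<- c(b2, rhs) }
    row <- function() numeric(nv)
    for (t in 1:m) {
      if (atom && t == p) next
      rr <- row(); rr[t] <- 1; rr[di] <- -1; add(rr, lo[t])
      rr <- row(); rr[t] <- 1; rr[di] <- 1; addge(rr, hi[t])
    }
    if (atom) {
      rr <- row(); rr[ai] <- 1; rr[di] <- -1; add(rr, lo[p])
      rr <- row(); rr[ai] <- 1; rr[di] <- 1; addge(rr, lo[p])
      rr <- row(); rr[p] <- 1; rr[di] <- -1; add(rr, hi[p])
      rr <- row(); rr[p] <- 1; rr[di] <- 1; addge(rr, hi[p])
    }
    for (t in 1:m) { rr <- row(); rr[t] <- 1; add(rr, 1) }
    if (atom) { rr <- row(); rr[ai] <- 1; add(rr, 1) }
    lv <- function(t) if (atom && t == p) ai else t
    P <- p
    if (P >= 2) for (t in 1:(P - 1)) {
      rr <- row(); rr[lv(t)] <- 1; rr[lv(t + 1)] <- rr[lv(t + 1)] - 1; add(rr, 0)
    }
    if (P >= 3) for (t in 1:(P - 2)) {
      i <- t; j <- t + 1; l <- t + 2
      lam <- (u[l] - u[j]) / (u[l] - u[i])
      rr <- row()
      rr[lv(j)] <- rr[lv(j)] + 1
      rr[lv(i)] <- rr[lv(i)] - lam
      rr[lv(l)] <- rr[lv(l)] - (1 - lam)
      add(rr, 0)
    }
    Q <- if (atom) p else p + 1
    if (Q <= m - 1) for (t in Q:(m - 1)) {
      rr <- row(); rr[t] <- 1; rr[t + 1] <- rr[t + 1] - 1; add(rr, 0)
    }
    if (Q <= m - 2) for (t in Q:(m - 2)) {
      i <- t; j <- t + 1; l <- t + 2
      lam <- (u[l] - u[j]) / (u[l] - u[i])
      rr <- row()
      rr[j] <- rr[j] - 1
      rr[i] <- rr[i] + lam
      rr[l] <- rr[l] + (1 - lam)
      add(rr, 0)
    }
    if (!atom && p >= 1 && p < m) { rr <- row(); rr[p] <- 1; rr[p + 1] <- -1; add(rr, 0) }
    if (atom) { rr <- row(); rr[ai] <- 1; rr[p] <- -1; add(rr, 0) }
    obj <- row(); obj[di] <- 1
    s <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = FALSE, n.iter = 2000)
    if (s$solved != 1) return(Inf)
    s$value
  }
  best <- solve_mode("gap", 0)
  for (p in 1:m) best <- min(best, solve_mode("gap", p), solve_mode("atom", p))
  best
}
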