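#' Fisher Z transform and back-transform
#'
#' `fisher_z()` is `atanh`; `fisher_z_inv()` is `tanh`. `fisher_mean_rho()`
#' averages correlation coefficients on the Z scale and back-transforms,
#' the standard way to aggregate correlations across repetitions.
#'
#' @param rho correlation coefficient(s)
#' @param z Fisher Z value(s)
#' @return transformed value(s)
#' @export
fisher_z <- function(rho) atanh(rho)

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' @rdname fisher_z
#' @param na.rm drop missing values before averaging
#' @export
fisher_mean_rho <- function(rho, na.rm = TRUE) {
  if (na.rm) rho <- rho[!is.na(rho)]
  if (!length(rho)) return(NA_real_)
  tanh(mean(atanh(pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15))))
}

#' Pearson correlation with Fisher confidence interval
#'
#' Correlates true against estimated ratings over the nodes whose neighbour
#' count is at least `neighbor_threshold` (the threshold filters the
#' correlation sample only; it plays no role in the estimation itself). The
#' 95% confidence interval is Fisher-based, `tanh(atanh(r) +/- 1.96 /
#' sqrt(n - 3))`; the two-sided p-value is the usual t-test for a Pearson
#' correlation.
#'
#' @param true_vals,est_vals numeric vectors, paired by position
#' @param neighbor_threshold minimum neighbour count (requires `n_neighbors`)
#' @param n_neighbors optional integer vector parallel to the values
#' @param method `"pearson"` (default) or `"spearman"` (no CI for spearman)
#' @return object of class `correlation_report`: `rho`, `ci` (length 2),
#'   `p_value`, `n`, `neighbor_threshold`
#' @export
correlate <- function(true_vals, est_vals, neighbor_threshold = 0L,
                      n_neighbors = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(true_vals) == length(est_vals))
  keep <- !is.na(true_vals) & !is.na(est_vals)
  if (neighbor_threshold > 0L) {
    if (is.null(n_neighbors))
      stop("neighbor_threshold > 0 requires n_neighbors")
    keep <- keep & n_neighbors >= neighbor_threshold
  }
  x <- true_vals[keep]; y <- est_vals[keep]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 paired values after filtering (n = ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in true or estimated values")
  rho <- stats::cor(x, y, method = method)
  if (method == "pearson") {
    z <- atanh(rho)
    ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    ci <- c(NA_real_, NA_real_)
    p <- stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  }
  structure(list(rho = rho, ci = ci, p_value = p, n = n,
                 neighbor_threshold = as.integer(neighbor_threshold),
                 method = method),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("rho = %.3f (c.i. = [%.3f, %.3f], p = %.3g, n = %d, threshold = %d)\n",
              x$rho, x$ci[1], x$ci[2], x$p_value, x$n, x$neighbor_threshold))
  invisible(x)
}

# internal: full-network analysis for a given seed set; returns the
# leave-self-out estimates of the seeded nodes joined with their true values
matching_estimates <- function(net, seeds, cfg) {
  res <- propagate(net, seeds, cfg)
  est <- estimate_matching(net, seeds, res, cfg)
  seeds_df <- if (inherits(seeds, "match_result")) seeds$ratings else seeds
  dims <- res$dims
  m <- match(est$node, seeds_df$node)
  truth <- seeds_df[m, , drop = FALSE]
  list(est = est, truth = truth, dims = dims, result = res)
}

#' Full-network analysis: estimate matching words and correlate
#'
#' Runs propagation seeded with all matching words, computes leave-self-out
#' estimates for them, and correlates against the true ratings per dimension.
#'
#' @param net a `colex_network`
#' @param match a `match_result` (or seed data.frame)
#' @param cfg a [propagation_config()]
#' @param neighbor_threshold threshold applied to the correlation sample
#' @return list with `correlations` (one `correlation_report` per dimension),
#'   `estimates`, `truth`, `coverage`, `result`
#' @export
full_network_analysis <- function(net, match, cfg = propagation_config(),
                                  neighbor_threshold = cfg$neighbor_threshold) {
  me <- matching_estimates(net, match, cfg)
  cors <- lapply(me$dims, function(d)
    correlate(me$truth[[d]], me$est[[d]], neighbor_threshold,
              n_neighbors = me$est$n_neighbors))
  names(cors) <- me$dims
  list(correlations = cors, estimates = me$est, truth = me$truth,
       coverage = me$result$coverage, result = me$result)
}

#' 75/25 split cross-validation of the interpolation
#'
#' Repeatedly splits the matching words uniformly at random into a training
#' fraction (seeds) and a held-out test set, propagates from the training
#' ratings only, reads the converged estimates at the test words, and
#' correlates them with the truth. Test words whose component contains no
#' training word cannot be estimated; they are excluded and counted in the
#' percent-computable statistic. Per-dimension correlations are aggregated
#' across repetitions by Fisher-Z averaging. With `train_frac = 1` the
#' procedure degenerates to the full-network analysis path.
#'
#' @param net a `colex_network`
#' @param match a `match_result` (or seed data.frame)
#' @param cfg a [propagation_config()]
#' @param train_frac fraction of matching words used as seeds
#' @param reps number of random splits
#' @param seed integer RNG seed
#' @param keep_last keep the last repetition's test-set truth/estimates
#'   (used to feed the null models)
#' @return object of class `cv_report`: `per_rep` (data.frame rep x dim ->
#'   rho), `rho` (Fisher-averaged, per dimension), `pct_computable`,
#'   `n_test`, and optionally `last_split`
#' @export
cross_validate <- function(net, match, cfg = propagation_config(),
                           train_frac = 0.75, reps = 10L, seed = NULL,
                           keep_last = FALSE) {
  seeds_df <- if (inherits(match, "match_result")) match$ratings else match
  dims <- intersect(c("valence", "arousal", "dominance"), names(seeds_df))
  nm <- nrow(seeds_df)
  if (nm < 8L) stop("need at least 8 matching nodes for cross-validation")
  if (!is.null(seed)) set.seed(seed)
  if (train_frac >= 1) {
    fa <- full_network_analysis(net, match, cfg)
    rho <- vapply(fa$correlations, `[[`, numeric(1), "rho")
    return(structure(list(per_rep = as.data.frame(as.list(rho)),
                          rho = rho, pct_computable = 100,
                          n_test = nrow(fa$estimates), reps = 1L),
                     class = "cv_report"))
  }
  per_rep <- matrix(NA_real_, reps, length(dims), dimnames = list(NULL, dims))
  pct <- numeric(reps)
  last_split <- NULL
  for (r in seq_len(reps)) {
    tr <- sample.int(nm, size = floor(train_frac * nm))
    train <- seeds_df[tr, , drop = FALSE]
    test <- seeds_df[-tr, , drop = FALSE]
    res <- propagate(net, train, cfg)
    m <- match(test$node, res$estimates$node)
    computable <- !is.na(m)
    pct[r] <- 100 * mean(computable)
    if (sum(computable) < 3L) {
      warning("repetition ", r, " has fewer than 3 computable test words; skipped")
      next
    }
    est <- res$estimates[m[computable], , drop = FALSE]
    truth <- test[computable, , drop = FALSE]
    for (d in dims) {
      ok <- !is.na(truth[[d]]) & !is.na(est[[d]])
      if (sum(ok) >= 3L && stats::sd(truth[[d]][ok]) > 0 && stats::sd(est[[d]][ok]) > 0)
        per_rep[r, d] <- stats::cor(truth[[d]][ok], est[[d]][ok])
    }
    if (keep_last && r == reps)
      last_split <- list(truth = truth, est = est,
                         n_neighbors = est$n_neighbors, dims = dims)
  }
  if (all(is.na(per_rep)))
    stop("no repetition produced a defined correlation (constant ratings?)")
  rho <- apply(per_rep, 2, fisher_mean_rho)
  structure(list(per_rep = as.data.frame(per_rep), rho = rho,
                 pct_computable = mean(pct), n_test = nm - floor(train_frac * nm),
                 reps = reps, last_split = last_split),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d repetition(s); %% computable = %.1f\n",
              x$reps, x$pct_computable))
  cat("  Fisher-averaged rho:",
      paste(sprintf("%s=%.3f", names(x$rho), x$rho), collapse = ", "), "\n")
  invisible(x)
}

# Summarise a vector of null-model correlations against an observed rho.
null_summary <- function(model, null_rho, observed, reps) {
  flag <- anyNA(null_rho)
  null_rho_f <- ifelse(is.na(null_rho), 0, null_rho)
  p_emp <- if (!is.null(observed) && !is.na(observed))
    (sum(null_rho_f >= observed) + 1) / (reps + 1) else NA_real_
  structure(list(model = model,
                 reps = reps,
                 mean_rho = fisher_mean_rho(null_rho_f),
                 interval = stats::quantile(null_rho_f, c(0.025, 0.975), names = FALSE),
                 p_empirical = p_emp,
                 observed_rho = observed,
                 undefined_flag = flag,
                 null_rho = null_rho_f),
            class = "null_model_report")
}

#' @export
print.null_model_report <- function(x, ...) {
  cat(sprintf("<null_model_report> %s: %d reps, mean rho = %.4f [%.3f, %.3f]",
              x$model, x$reps, x$mean_rho, x$interval[1], x$interval[2]))
  if (!is.na(x$p_empirical))
    cat(sprintf(", empirical p = %.4g vs observed rho = %.3f", x$p_empirical,
                x$observed_rho))
  cat(if (x$undefined_flag) " [undefined correlations set to 0]\n" else "\n")
  invisible(x)
}

#' Random-neighbours null model
#'
#' Degree-preserving null: each evaluated node keeps its degree and its
#' original edge weights (assigned to the sampled neighbours in input order)
#' but its neighbours are replaced by nodes drawn uniformly without
#' replacement from the non-matching nodes, whose converged estimates supply
#' the values averaged. The resulting estimates are correlated with the true
#' ratings once per repetition; the summary aggregates by Fisher back-
#' transformed mean, and the empirical p-value of the observed correlation
#' uses the add-one rule.
#'
#' @param net a `colex_network`
#' @param match a `match_result`
#' @param cfg a [propagation_config()]
#' @param reps repetitions
#' @param seed RNG seed
#' @param dim dimension evaluated (default `"valence"`)
#' @param eval_nodes,eval_true optionally restrict evaluation to these nodes
#'   with these true values (e.g. a CV test set); defaults to all matching
#'   nodes with their lexicon ratings
#' @param observed_rho observed correlation to compare against (for the
#'   empirical p-value); default recomputed from the full-network analysis
#' @return a `null_model_report`
#' @export
null_random_neighbors <- function(net, match, cfg = propagation_config(),
                                  reps = 1000L, seed = NULL, dim = "valence",
                                  eval_nodes = NULL, eval_true = NULL,
                                  observed_rho = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds_df <- match$ratings
  res <- propagate(net, match, cfg)
  if (is.null(eval_nodes)) {
    eval_nodes <- seeds_df$node
    eval_true <- seeds_df[[dim]]
  }
  stopifnot(length(eval_nodes) == length(eval_true))
  if (is.null(observed_rho)) {
    est <- estimate_matching(net, match, res, cfg)
    m <- match(est$node, seeds_df$node)
    observed_rho <- stats::cor(seeds_df[[dim]][m], est[[dim]])
  }
  # value pool: converged estimates of non-matching nodes
  em <- res$estimates
  pool_v <- em[[dim]][!em$is_matching & !is.na(em[[dim]])]
  if (!length(pool_v)) stop("no non-matching nodes with estimates to sample from")
  P <- length(pool_v)
  # original weights per evaluated node, in edge input order
  e <- net$edges
  w_all <- switch(cfg$weight_mode,
                  language = as.numeric(e$language_weight),
                  family = as.numeric(e$family_weight),
                  unweighted = rep(1, nrow(e)))
  wlist <- vector("list", length(eval_nodes))
  for (i in seq_along(eval_nodes)) {
    sel <- e$node_a == eval_nodes[i] | e$node_b == eval_nodes[i]
    wlist[[i]] <- w_all[sel]
  }
  degs <- lengths(wlist)
  usable <- degs > 0L
  if (any(degs > P))
    message(sum(degs > P), " node(s) have degree above the non-matching pool ",
            "size; sampled with the full pool")
  null_rho <- numeric(reps)
  tv <- eval_true[usable]
  for (r in seq_len(reps)) {
    estv <- vapply(which(usable), function(i) {
      k <- min(degs[i], P)
      idx <- sample.int(P, k)
      w <- wlist[[i]][seq_len(k)]
      sum(w * pool_v[idx]) / sum(w)
    }, numeric(1))
    null_rho[r] <- if (stats::sd(estv) > 0 && stats::sd(tv) > 0)
      stats::cor(tv, estv) else NA_real_
  }
  null_summary("random_neighbors", null_rho, observed_rho, reps)
}

#' Permuted-values null model
#'
#' Keeps the network (and hence the estimates) unchanged but permutes the
#' estimated ratings across the evaluated nodes before correlating with the
#' truth. Distribution-free: its mean correlation approaches zero as the
#' number of repetitions grows regardless of the rating marginals.
#'
#' @param true_vals,est_vals paired numeric vectors
#' @param reps repetitions
#' @param seed RNG seed
#' @param observed_rho observed correlation for the empirical p (default:
#'   `cor(true_vals, est_vals)`)
#' @return a `null_model_report`
#' @export
null_permuted_values <- function(true_vals, est_vals, reps = 10000L,
                                 seed = NULL, observed_rho = NULL) {
  stopifnot(length(true_vals) == length(est_vals))
  keep <- !is.na(true_vals) & !is.na(est_vals)
  x <- true_vals[keep]; y <- est_vals[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired values")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(observed_rho))
    observed_rho <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  null_rho <- if (degenerate) rep(NA_real_, reps) else
    vapply(seq_len(reps), function(r) stats::cor(x, y[sample.int(n)]), numeric(1))
  null_summary("permuted_values", null_rho, observed_rho, reps)
}

#' Language-threshold robustness sweep
#'
#' For each threshold `t`, filters the network to edges attested in at least
#' `t` languages (family threshold 1), reruns the full-network estimation and
#' correlation, and reports one row per threshold. Thresholds that empty the
#' network or leave too few matched nodes yield a flagged row rather than an
#' error.
#'
#' @param net a `colex_network` carrying language weights
#' @param lex an `affective_lexicon`
#' @param cfg a [propagation_config()]
#' @param thresholds integer vector of minimum language weights
#' @param mode matching mode, see [match_nodes()]
#' @param dim dimension reported
#' @return data.frame with columns `threshold`, `n_edges`, `n_nodes`,
#'   `n_matching`, `rho`, `ci_low`, `ci_high`, `p_value`, `n`, `flagged`
#' @export
language_threshold_sweep <- function(net, lex, cfg = propagation_config(),
                                     thresholds = c(1L, 2L, 3L),
                                     mode = c("word", "concept"),
                                     dim = "valence") {
  mode <- match.arg(mode)
  rows <- lapply(thresholds, function(t) {
    nf <- filter_network(net, min_languages = t, min_families = 1L)
    base <- data.frame(threshold = t, n_edges = nrow(nf$edges),
                       n_nodes = length(nf$nodes), n_matching = NA_integer_,
                       rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p_value = NA_real_, n = NA_integer_, flagged = TRUE)
    if (!nrow(nf$edges)) return(base)
    mt <- match_nodes(nf, lex, mode)
    base$n_matching <- nrow(mt$ratings)
    if (nrow(mt$ratings) < 3L) return(base)
    fa <- try(full_network_analysis(nf, mt, cfg, neighbor_threshold = 0L),
              silent = TRUE)
    if (inherits(fa, "try-error")) return(base)
    cr <- fa$correlations[[dim]]
    if (is.null(cr)) return(base)
    base$rho <- cr$rho; base$ci_low <- cr$ci[1]; base$ci_high <- cr$ci[2]
    base$p_value <- cr$p_value; base$n <- cr$n; base$flagged <- FALSE
    base
  })
  do.call(rbind, rows)
}

#' Dominance-residual analysis
#'
#' Valence and dominance ratings are substantially collinear in affective
#' lexica, so a good dominance estimate must be shown to add information
#' beyond valence. Two nested least-squares models are compared: M1 regresses
#' true dominance on true valence; M2 adds the estimated dominance. The
#' statistic is the percentage of M1's residual variance removed by M2,
#' `100 * (1 - SSR(M2) / SSR(M1))`, together with the p-value of the
#' estimated-dominance coefficient in M2. If the estimate is collinear with
#' valence to machine precision the statistic is 0 with a flag.
#'
#' @param true_V,true_D,est_D numeric vectors (true valence, true dominance,
#'   estimated dominance), paired by position
#' @return list `pct_residual_explained`, `p_value`, `collinear_flag`, `n`
#' @export
dominance_residual_analysis <- function(true_V, true_D, est_D) {
  keep <- !is.na(true_V) & !is.na(true_D) & !is.na(est_D)
  V <- true_V[keep]; D <- true_D[keep]; Dh <- est_D[keep]
  n <- length(V)
  if (n < 10L) stop("need at least 10 complete observations")
  if (stats::sd(V) == 0 || stats::sd(D) == 0)
    stop("degenerate variance in true ratings")
  # collinearity of the estimate with valence, to machine precision
  r_vd <- suppressWarnings(stats::cor(V, Dh))
  if (is.na(r_vd) || 1 - r_vd^2 < 1e-12)
    return(list(pct_residual_explained = 0, p_value = NA_real_,
                collinear_flag = TRUE, n = n))
  m1 <- stats::lm(D ~ V)
  m2 <- stats::lm(D ~ V + Dh)
  ssr1 <- sum(stats::resid(m1)^2)
  ssr2 <- sum(stats::resid(m2)^2)
  # a perfect estimate gives an essentially perfect fit; summary.lm warns then
  pval <- suppressWarnings(summary(m2)$coefficients["Dh", "Pr(>|t|)"])
  list(pct_residual_explained = 100 * (1 - ssr2 / ssr1),
       p_value = pval, collinear_flag = FALSE, n = n)
}
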