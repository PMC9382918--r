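#' Hartigan's dip statistic
#'
#' The dip of a sample is the maximum absolute deviation between its
#' empirical CDF and the closest unimodal CDF: the sup-norm distance from the
#' ecdf to the set of distribution functions that are convex up to some mode
#' and concave after it (an atom at the mode is allowed). It is the standard
#' test statistic for departure from unimodality; large dips indicate
#' multimodal structure.
#'
#' The implementation works on the band formulation of the problem: a
#' unimodal CDF within sup-distance `d` of the ecdf exists if and only if,
#' for some mode position, a convex nondecreasing function fits inside the
#' band `[F - d, F^- + d]` left of the mode and a concave one right of it,
#' with compatible values at the junction. All binding constraints are chords
#' over triples of jump points, linear in `d`, so the minimal `d` is computed
#' directly from chord maxima; junction compatibility is then verified and,
#' in the rare case it binds, the minimal feasible `d` is found by bisection.
#'
#' @param x numeric sample (length >= 1; ties allowed)
#' @return the dip statistic, a number in `[0, 0.25]`
#' @export
dip_statistic <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 1L) stop("empty sample")
  r <- rle(x)
  u <- r$values
  if (length(u) == 1L) return(0)  # a point mass is itself unimodal
  hi <- cumsum(r$lengths)         # ecdf counts at each unique value
  lo <- c(0, hi[-length(u)])      # left-limit counts
  dip_stat_cpp(u, lo, hi, n)
}

#' Null reference distribution for the dip statistic
#'
#' Dip statistics of `n_boot` samples of size `n` drawn from the uniform
#' distribution on (0, 1), the standard calibration null for the dip test.
#' Computing the reference once and passing it to [dip_test()] amortises the
#' bootstrap over many tests at the same sample size.
#'
#' @param n sample size the reference is matched to
#' @param n_boot number of bootstrap draws (>= 2000 recommended)
#' @param seed RNG seed
#' @return sorted numeric vector of null dip statistics, with attribute `n`
#' @export
dip_null_reference <- function(n, n_boot = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- sort(vapply(seq_len(n_boot), function(b) dip_statistic(stats::runif(n)),
                     numeric(1)))
  attr(ref, "n") <- as.integer(n)
  ref
}

#' Dip test for unimodality
#'
#' Computes the dip statistic of a sample and a bootstrap p-value under the
#' uniform null at matched sample size. Small p-values reject unimodality
#' (suggest bimodal or multimodal structure). The p-value uses the add-one
#' rule `(b + 1) / (n_boot + 1)` so that finite simulation never reports
#' exactly zero.
#'
#' @param x numeric sample, length >= 10
#' @param n_boot bootstrap draws used when no reference is supplied
#' @param seed RNG seed for the bootstrap
#' @param reference optional precomputed [dip_null_reference()] for
#'   `length(x)` observations
#' @return list with `dip`, `p_value`, `n`, `n_boot`
#' @export
dip_test <- function(x, n_boot = 2000L, seed = NULL, reference = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10L) stop("dip test requires at least 10 observations")
  d <- dip_statistic(x)
  if (is.null(reference)) {
    reference <- dip_null_reference(n, n_boot, seed)
  } else if (!is.null(attr(reference, "n")) && attr(reference, "n") != n) {
    stop("reference was computed for n = ", attr(reference, "n"),
         ", sample has n = ", n)
  }
  b <- sum(reference >= d - 1e-12)
  list(dip = d, p_value = (b + 1) / (length(reference) + 1),
       n = n, n_boot = length(reference))
}
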