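#' Configuration for the synthetic colexification generator
#'
#' The generator emulates the statistical premise of colexification-based
#' norm interpolation: words fall into meaning clusters whose members tend to
#' colexify (intra-cluster edges), affective ratings are smooth over the
#' clusters (cluster centre plus Gaussian noise), and homographs contribute
#' meaning-free cross-cluster edges. Each word independently becomes a
#' homograph with probability `homograph_edge_prob`, gaining one edge to a
#' uniformly chosen word of another cluster; this per-word rate mirrors
#' homography being a property of individual word forms.
#'
#' Edge attestation counts are drawn with a long-tailed distribution
#' (`1 + Geometric(0.5)`, capped at `n_languages`): most colexifications are
#' attested by one or two languages, a few by many, as in real colexification
#' databases. Languages are assigned to families round-robin.
#'
#' @param n_clusters number of meaning clusters
#' @param words_per_cluster words per cluster
#' @param n_languages number of languages attesting edges
#' @param n_families number of language families (`<= n_languages`)
#' @param intra_cluster_edge_prob probability an intra-cluster pair is linked
#' @param homograph_edge_prob per-word probability of one cross-cluster
#'   (noise) edge
#' @param rating_noise_sd SD of within-cluster rating noise, on the rating
#'   scale
#' @param lexicon_coverage fraction of words whose true ratings are exported
#'   as the "known" lexicon (sampled uniformly within each cluster)
#' @param scale_min,scale_max rating scale bounds
#' @param dominance_alpha optional collinearity plant: dominance becomes
#'   `alpha * valence + (1 - alpha) * independent dominance`
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_clusters = 40L, words_per_cluster = 50L,
                         n_languages = 20L, n_families = 8L,
                         intra_cluster_edge_prob = 0.15,
                         homograph_edge_prob = 0.01,
                         rating_noise_sd = 0.05,
                         lexicon_coverage = 0.5,
                         scale_min = 0, scale_max = 1,
                         dominance_alpha = NULL) {
  stopifnot(n_clusters >= 1L, words_per_cluster >= 1L,
            n_languages >= 1L, n_families >= 1L, n_families <= n_languages,
            intra_cluster_edge_prob >= 0, intra_cluster_edge_prob <= 1,
            homograph_edge_prob >= 0, homograph_edge_prob <= 1,
            rating_noise_sd >= 0,
            lexicon_coverage > 0, lexicon_coverage <= 1,
            scale_min < scale_max)
  structure(list(n_clusters = as.integer(n_clusters),
                 words_per_cluster = as.integer(words_per_cluster),
                 n_languages = as.integer(n_languages),
                 n_families = as.integer(n_families),
                 intra_cluster_edge_prob = intra_cluster_edge_prob,
                 homograph_edge_prob = homograph_edge_prob,
                 rating_noise_sd = rating_noise_sd,
                 lexicon_coverage = lexicon_coverage,
                 scale_min = scale_min, scale_max = scale_max,
                 dominance_alpha = dominance_alpha),
            class = "synth_config")
}

# language identifiers and their round-robin family assignment
synth_language_meta <- function(cfg) {
  langs <- sprintf("L%02d", seq_len(cfg$n_languages))
  fams <- sprintf("F%02d", ((seq_len(cfg$n_languages) - 1L) %% cfg$n_families) + 1L)
  language_meta(langs, fams)
}

#' Generate a synthetic colexification network
#'
#' Words are labelled `c<cluster>_w<index>`. Pairs within a cluster are
#' linked independently with `intra_cluster_edge_prob`; each word gains a
#' cross-cluster homograph edge with `homograph_edge_prob`. Every edge is
#' attested by a random set of 1 to `n_languages` languages (long-tailed
#' count), so language and family weights vary. Deterministic under `seed`.
#'
#' @param cfg a [synth_config()]
#' @param seed integer RNG seed
#' @return list with `network` (a `colex_network`), `meta` (language ->
#'   family), `clusters` (named integer vector: word -> cluster id)
#' @export
generate_network <- function(cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- cfg$n_clusters; W <- cfg$words_per_cluster
  words <- as.vector(vapply(seq_len(K), function(k)
    sprintf("c%02d_w%03d", k, seq_len(W)), character(W)))
  clusters <- stats::setNames(rep(seq_len(K), each = W), words)
  meta <- synth_language_meta(cfg)
  langs <- names(meta)
  a <- character(); b <- character()
  if (W >= 2L) {
    pr <- utils::combn(W, 2L)
    for (k in seq_len(K)) {
      on <- stats::runif(ncol(pr)) < cfg$intra_cluster_edge_prob
      if (any(on)) {
        base <- (k - 1L) * W
        a <- c(a, words[base + pr[1L, on]])
        b <- c(b, words[base + pr[2L, on]])
      }
    }
  }
  if (K >= 2L && cfg$homograph_edge_prob > 0) {
    homo <- which(stats::runif(length(words)) < cfg$homograph_edge_prob)
    for (i in homo) {
      other <- which(clusters != clusters[i])
      j <- other[sample.int(length(other), 1L)]
      a <- c(a, words[i]); b <- c(b, words[j])
    }
  }
  if (!length(a)) {
    net <- colex_network(NULL, nodes = words, provenance = "synthetic")
    return(list(network = net, meta = meta, clusters = clusters))
  }
  cp <- canon_pair(a, b)
  key <- paste(cp$a, cp$b, sep = "\r")
  first <- !duplicated(key)
  a <- cp$a[first]; b <- cp$b[first]
  n_lang <- pmin(1L + stats::rgeom(length(a), 0.5), cfg$n_languages)
  lang_sets <- lapply(n_lang, function(k) sort(sample(langs, k)))
  edges <- data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE)
  edges$languages <- lang_sets
  edges$families <- lapply(lang_sets, function(ls) sort(unique(unname(meta[ls]))))
  edges$language_weight <- lengths(edges$languages)
  edges$family_weight <- lengths(edges$families)
  net <- colex_network(edges, nodes = words, provenance = "synthetic")
  list(network = net, meta = meta, clusters = clusters)
}

#' Generate ground-truth ratings and a partial lexicon over planted clusters
#'
#' Each cluster draws a valence/arousal/dominance centre uniformly within the
#' scale bounds; each word's true rating is its cluster centre plus Gaussian
#' noise with SD `rating_noise_sd`, clipped to the bounds. A
#' `lexicon_coverage` fraction of words, sampled uniformly within each
#' cluster, is exported as the "known" lexicon. With `dominance_alpha` set,
#' dominance is replaced by `alpha * valence + (1 - alpha) * dominance`,
#' planting valence-dominance collinearity with closed-form correlation
#' `alpha / sqrt(alpha^2 + (1 - alpha)^2)` (valence and the independent
#' dominance component share the same marginal distribution).
#'
#' @param clusters named integer vector (word -> cluster), as returned by
#'   [generate_network()]
#' @param cfg a [synth_config()]
#' @param seed integer RNG seed
#' @return list with `truth` (data.frame `word`, `cluster`, `valence`,
#'   `arousal`, `dominance`, `is_known`) and `lexicon` (an
#'   `affective_lexicon` of the known words)
#' @export
generate_lexicon <- function(clusters, cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  words <- names(clusters)
  K <- max(clusters)
  clip <- function(v) pmin(pmax(v, cfg$scale_min), cfg$scale_max)
  centers <- matrix(stats::runif(3 * K, cfg$scale_min, cfg$scale_max), K, 3,
                    dimnames = list(NULL, c("valence", "arousal", "dominance")))
  noise <- function() stats::rnorm(length(words), 0, cfg$rating_noise_sd)
  truth <- data.frame(word = words, cluster = unname(clusters),
                      stringsAsFactors = FALSE)
  for (d in c("valence", "arousal", "dominance"))
    truth[[d]] <- clip(centers[clusters, d] + noise())
  if (!is.null(cfg$dominance_alpha)) {
    al <- cfg$dominance_alpha
    truth$dominance <- clip(al * truth$valence + (1 - al) * truth$dominance)
  }
  known <- logical(length(words))
  for (k in seq_len(K)) {
    idx <- which(truth$cluster == k)
    n_known <- round(cfg$lexicon_coverage * length(idx))
    if (n_known > 0L) known[idx[sample.int(length(idx), n_known)]] <- TRUE
  }
  truth$is_known <- known
  lex_df <- truth[known, c("word", "valence", "arousal", "dominance")]
  rownames(lex_df) <- NULL
  list(truth = truth,
       lexicon = affective_lexicon(lex_df, scale_min = cfg$scale_min,
                                   scale_max = cfg$scale_max))
}

#' Emit dictionary entries whose shared translations reconstruct a network
#'
#' Inverse of [detect_shared_translation()]: for every edge and every
#' language attesting it, a synthetic foreign word (`<lang>:e<edge>`) is
#' translated into both endpoint words of the pivot language. Running
#' [detect_shared_translation()] followed by [assemble_network()] on the
#' output reconstructs the input network exactly, weights included. Foreign
#' labels are unique per (edge, language), so no identical translations
#' beyond the planted ones can arise.
#'
#' @param net a `colex_network` whose edges carry language sets
#' @param pivot_lang pivot language identifier for the entries
#' @return data.frame of translation entries
#' @export
generate_dictionaries <- function(net, pivot_lang = "eng") {
  e <- net$edges
  if (!nrow(e))
    return(data.frame(source_lang = character(), source_word = character(),
                      target_lang = character(), target_word = character(),
                      stringsAsFactors = FALSE))
  if (any(lengths(e$languages) == 0L))
    stop("network edges must carry explicit language sets")
  reps <- lengths(e$languages)
  lang <- unlist(e$languages)
  foreign <- paste0(lang, ":e", rep(seq_len(nrow(e)), reps))
  translation_entries(
    source_lang = rep(lang, each = 2L),
    source_word = rep(foreign, each = 2L),
    target_lang = pivot_lang,
    target_word = as.vector(rbind(rep(e$node_a, reps), rep(e$node_b, reps))))
}

#' Plant a dominance-residual structure with known incremental share
#'
#' Generates triples (true valence, true dominance, estimated dominance) in
#' which the estimated dominance explains exactly `partial_r2` of the
#' residual variance of true dominance given true valence, in expectation:
#' `D = alpha V + E`, `Dhat = alpha V + sqrt(partial_r2) E +
#' sqrt(1 - partial_r2) Z` with independent standard normal `V`, `E`, `Z`.
#' Used to calibrate [dominance_residual_analysis()].
#'
#' @param n sample size
#' @param partial_r2 planted incremental residual-variance share, in `[0, 1]`
#' @param alpha valence-dominance collinearity strength
#' @param seed RNG seed
#' @return data.frame with columns `true_V`, `true_D`, `est_D`
#' @export
plant_dominance_structure <- function(n, partial_r2 = 0.4, alpha = 1,
                                      seed = NULL) {
  stopifnot(partial_r2 >= 0, partial_r2 <= 1, n >= 10)
  if (!is.null(seed)) set.seed(seed)
  V <- stats::rnorm(n); E <- stats::rnorm(n); Z <- stats::rnorm(n)
  data.frame(true_V = V,
             true_D = alpha * V + E,
             est_D = alpha * V + sqrt(partial_r2) * E + sqrt(1 - partial_r2) * Z)
}
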