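# Small hand-built networks used across test files.

# quick network from parallel vectors of endpoints and weights
make_net <- function(a, b, lw, fw = lw, provenance = "synthetic") {
  edges <- data.frame(node_a = a, node_b = b,
                      language_weight = as.integer(lw),
                      family_weight = as.integer(fw),
                      stringsAsFactors = FALSE)
  colex_network(edges, provenance = provenance)
}

# unit-weight path graph over the given node labels
path_net <- function(labels) {
  k <- length(labels)
  make_net(labels[-k], labels[-1], rep(1L, k - 1L))
}

seed_df <- function(nodes, valence) {
  data.frame(node = nodes, valence = valence, stringsAsFactors = FALSE)
}

# small ratings lexicon on [0, 1]
toy_lexicon <- function(words, v, a = v, d = v) {
  affective_lexicon(
    data.frame(word = words, valence = v, arousal = a, dominance = d,
               stringsAsFactors = FALSE),
    scale_min = 0, scale_max = 1)
}

# random connected-ish synthetic fixture for propagation properties
random_fixture <- function(seed, n_clusters = 4L, words_per_cluster = 12L,
                           coverage = 0.4, homograph = 0.05) {
  cfg <- synth_config(n_clusters = n_clusters,
                      words_per_cluster = words_per_cluster,
                      intra_cluster_edge_prob = 0.3,
                      homograph_edge_prob = homograph,
                      rating_noise_sd = 0.05,
                      lexicon_coverage = coverage)
  gen <- generate_network(cfg, seed = seed)
  lx <- generate_lexicon(gen$clusters, cfg, seed = seed + 10000L)
  list(net = gen$network, meta = gen$meta, clusters = gen$clusters,
       truth = lx$truth, lexicon = lx$lexicon, cfg = cfg)
}
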