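#' Run the full interpolation and validation pipeline
#'
#' Wires the stages together: read (or synthesise) a network, match it
#' against an affective lexicon, propagate ratings, run the full-network
#' correlation, cross-validation, and (optionally) the null models, and
#' write versioned CSV/JSON outputs plus a manifest recording inputs,
#' parameters and seeds. Given an identical configuration and seed, two runs
#' produce identical result files (the timestamp lives only in the manifest).
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{network}{path to an edge-list TSV, or `"synthetic"`}
#'     \item{lexicon}{path to a lexicon CSV (ignored for synthetic runs)}
#'     \item{scale_min, scale_max}{lexicon scale bounds}
#'     \item{mode}{`"word"` or `"concept"` matching}
#'     \item{provenance}{network provenance tag for TSV input}
#'     \item{min_languages, min_families}{filter thresholds (default 1, 1)}
#'     \item{weight_mode, convergence_tol, max_iterations}{propagation}
#'     \item{cv_reps, train_frac}{cross-validation settings}
#'     \item{null_reps_permuted, null_reps_random}{null model repetitions
#'       (0 disables)}
#'     \item{seed}{integer seed for every stochastic step}
#'     \item{synth}{list of [synth_config()] overrides for synthetic runs}
#'   }
#' @param outdir output directory, created if missing
#' @return invisibly, a list with the in-memory results (`network`, `match`,
#'   `propagation`, `full`, `cv`, `nulls`, `manifest`)
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg_get <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  seed <- as.integer(cfg_get("seed", 1L))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  net_src <- cfg_get("network", "synthetic")
  mode <- cfg_get("mode", "word")
  if (identical(net_src, "synthetic")) {
    sc <- do.call(synth_config, cfg_get("synth", list()))
    gen <- generate_network(sc, seed = seed)
    lx <- generate_lexicon(gen$clusters, sc, seed = seed + 1L)
    net <- gen$network
    lex <- lx$lexicon
  } else {
    if (!file.exists(net_src)) stop("network file not found: ", net_src)
    net <- read_colex_network(net_src, provenance = cfg_get("provenance",
                                                            "shared_translation"))
    lex_path <- cfg_get("lexicon", NULL)
    if (is.null(lex_path) || !file.exists(lex_path))
      stop("lexicon file not found: ", if (is.null(lex_path)) "(unset)" else lex_path)
    lex <- read_affective_lexicon(lex_path,
                                  scale_min = cfg_get("scale_min", 1),
                                  scale_max = cfg_get("scale_max", 9))
  }
  net <- filter_network(net,
                        min_languages = cfg_get("min_languages", 1L),
                        min_families = cfg_get("min_families", 1L))
  pcfg <- propagation_config(weight_mode = cfg_get("weight_mode", "language"),
                             convergence_tol = cfg_get("convergence_tol", 1e-6),
                             max_iterations = cfg_get("max_iterations", 10000L))
  mt <- match_nodes(net, lex, mode = mode)
  cov <- coverage_report(mt)
  prop <- propagate(net, mt, pcfg)
  full <- full_network_analysis(net, mt, pcfg)
  cv <- cross_validate(net, mt, pcfg,
                       train_frac = cfg_get("train_frac", 0.75),
                       reps = cfg_get("cv_reps", 10L),
                       seed = seed + 2L, keep_last = TRUE)
  nulls <- list()
  np <- cfg_get("null_reps_permuted", 0L)
  if (np > 0L) {
    d1 <- mt$dims[[1]]
    est <- full$estimates
    m <- match(est$node, mt$ratings$node)
    nulls$permuted_values <- null_permuted_values(mt$ratings[[d1]][m], est[[d1]],
                                                  reps = np, seed = seed + 3L)
  }
  nr <- cfg_get("null_reps_random", 0L)
  if (nr > 0L)
    nulls$random_neighbors <- null_random_neighbors(net, mt, pcfg, reps = nr,
                                                    seed = seed + 4L)

  # outputs
  write_colex_network(net, file.path(outdir, "network.tsv"))
  utils::write.csv(prop$estimates, file.path(outdir, "estimates.csv"),
                   row.names = FALSE)
  rep_json <- list(
    coverage = cov,
    propagation = list(coverage = prop$coverage,
                       iterations = as.list(prop$iterations),
                       discarded = length(prop$discarded_nodes)),
    full_network = lapply(full$correlations, function(cr)
      list(rho = cr$rho, ci = cr$ci, p_value = cr$p_value, n = cr$n)),
    cross_validation = list(rho = as.list(cv$rho),
                            pct_computable = cv$pct_computable,
                            per_rep = cv$per_rep),
    null_models = lapply(nulls, function(nm)
      list(mean_rho = nm$mean_rho, interval = nm$interval,
           p_empirical = nm$p_empirical, reps = nm$reps)))
  jsonlite::write_json(rep_json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("colexaffect")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = config[setdiff(names(config), "synth")],
    synth = config$synth,
    n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    n_matching = nrow(mt$ratings))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(network = net, match = mt, propagation = prop, full = full,
                 cv = cv, nulls = nulls, manifest = manifest))
}
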