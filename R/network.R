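#' @import stats utils
#' @importFrom stringi stri_trans_nfc
NULL

# Canonical word normalisation used everywhere two labels are compared:
# NFC unicode normalisation, whitespace trim, case fold. Original casing is
# preserved for display; only comparisons use the normalised form.
norm_word <- function(x) {
  tolower(trimws(stringi::stri_trans_nfc(enc2utf8(as.character(x)))))
}

# Order an unordered node pair canonically (by normalised label).
canon_pair <- function(a, b) {
  swap <- norm_word(a) > norm_word(b)
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Construct a colexification network
#'
#' A colexification network is an undirected graph whose nodes are words (for
#' identical-translation data) or concept labels (for CLICS-style data). Each
#' edge records the set of languages attesting the colexification and the set
#' of language families those languages belong to; the edge's language weight
#' and family weight are the cardinalities of those sets. When a source only
#' provides counts (no language lists), the sets are empty and the weights are
#' carried verbatim.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `language_weight`,
#'   `family_weight` and (optionally) list columns `languages`, `families`
#'   holding character vectors.
#' @param nodes character vector of node labels; defaults to the union of edge
#'   endpoints.
#' @param provenance one of `"clics"`, `"shared_translation"`, `"roundtrip"`,
#'   `"synthetic"`.
#' @return An object of class `colex_network` with elements `nodes`, `edges`,
#'   `provenance`.
#' @export
colex_network <- function(edges, nodes = NULL, provenance = "shared_translation") {
  provenance <- match.arg(provenance,
                          c("clics", "shared_translation", "roundtrip", "synthetic"))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        language_weight = integer(), family_weight = integer())
    edges$languages <- list()
    edges$families <- list()
  }
  stopifnot(all(c("node_a", "node_b", "language_weight", "family_weight")
                %in% names(edges)))
  if (is.null(edges$languages)) edges$languages <- replicate(nrow(edges), character(), simplify = FALSE)
  if (is.null(edges$families)) edges$families <- replicate(nrow(edges), character(), simplify = FALSE)
  if (nrow(edges)) {
    if (any(norm_word(edges$node_a) == norm_word(edges$node_b)))
      stop("self-loops are not allowed in a colexification network")
    if (any(edges$language_weight < 1L) || any(edges$family_weight < 1L))
      stop("edge weights must be >= 1")
    if (any(edges$family_weight > edges$language_weight))
      stop("family_weight may not exceed language_weight")
    cp <- canon_pair(edges$node_a, edges$node_b)
    edges$node_a <- cp$a
    edges$node_b <- cp$b
    key <- paste(norm_word(edges$node_a), norm_word(edges$node_b), sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate unordered node pairs; merge edges before construction")
    edges <- edges[order(key), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "colex_network")
}

#' @export
print.colex_network <- function(x, ...) {
  cat(sprintf("<colex_network> %s: %d nodes, %d edges\n",
              x$provenance, length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  language weight: %d-%d; family weight: %d-%d\n",
                min(x$edges$language_weight), max(x$edges$language_weight),
                min(x$edges$family_weight), max(x$edges$family_weight)))
  }
  invisible(x)
}

#' Number of nodes and edges
#' @param net a `colex_network`
#' @return integer vector `c(nodes, edges)`
#' @export
network_size <- function(net) {
  c(nodes = length(net$nodes), edges = nrow(net$edges))
}

#' Convert a colexification network to an igraph graph
#'
#' Edge attributes `language_weight` and `family_weight` are carried over.
#'
#' @param net a `colex_network`
#' @return an igraph object
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(match(net$edges$node_a, net$nodes),
                                    match(net$edges$node_b, net$nodes)))
    igraph::E(g)$language_weight <- net$edges$language_weight
    igraph::E(g)$family_weight <- net$edges$family_weight
  }
  g
}

#' Read a language-to-family metadata table
#'
#' Two-column tab-separated file (with header) mapping language identifiers to
#' family identifiers, in the style of a Glottolog export. Every language must
#' resolve to exactly one family.
#'
#' @param path path to the TSV file
#' @return named character vector: `meta[language] == family`
#' @export
read_language_meta <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("language metadata needs two columns: language, family")
  language_meta(df[[1]], df[[2]])
}

#' Build language metadata from vectors
#' @param language character vector of language identifiers
#' @param family character vector of family identifiers, parallel to `language`
#' @return named character vector mapping language to family
#' @export
language_meta <- function(language, family) {
  language <- trimws(language); family <- trimws(family)
  dup <- duplicated(language)
  if (any(dup)) {
    conflicting <- unique(language[dup][family[dup] !=
                                          family[match(language[dup], language)]])
    if (length(conflicting))
      stop("language(s) mapped to more than one family: ",
           paste(conflicting, collapse = ", "))
  }
  out <- family[!dup]
  names(out) <- language[!dup]
  out
}

#' Write a colexification network as a canonical edge-list TSV
#'
#' Columns: `node_a, node_b, language_weight, family_weight, languages,
#' families`, with the sets serialised as comma-joined sorted lists (empty
#' string when only counts are known). [read_colex_network()] round-trips the
#' format.
#'
#' @param net a `colex_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_colex_network <- function(net, path) {
  e <- net$edges
  out <- data.frame(
    node_a = e$node_a, node_b = e$node_b,
    language_weight = e$language_weight, family_weight = e$family_weight,
    languages = vapply(e$languages, function(s) paste(sort(s), collapse = ","), ""),
    families = vapply(e$families, function(s) paste(sort(s), collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a canonical edge-list TSV written by [write_colex_network()]
#' @param path path to the TSV
#' @param provenance provenance tag to attach
#' @return a `colex_network`
#' @export
read_colex_network <- function(path, provenance = "shared_translation") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", fileEncoding = "UTF-8")
  need <- c("node_a", "node_b", "language_weight", "family_weight")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  split_set <- function(x) {
    lapply(x, function(s) if (is.na(s) || !nzchar(s)) character()
           else strsplit(s, ",", fixed = TRUE)[[1]])
  }
  edges <- data.frame(node_a = df$node_a, node_b = df$node_b,
                      language_weight = as.integer(df$language_weight),
                      family_weight = as.integer(df$family_weight),
                      stringsAsFactors = FALSE)
  edges$languages <- if ("languages" %in% names(df)) split_set(df$languages)
                     else replicate(nrow(df), character(), simplify = FALSE)
  edges$families <- if ("families" %in% names(df)) split_set(df$families)
                    else replicate(nrow(df), character(), simplify = FALSE)
  colex_network(edges, provenance = provenance)
}
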