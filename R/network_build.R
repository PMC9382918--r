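#' Read a dictionary of translation entries
#'
#' Tab-separated UTF-8 file with a header row and columns `source_lang,
#' source_word, target_lang, target_word`. Each row is one directed dictionary
#' entry (a headword in the source language translated into the target
#' language). Rows whose words are empty after trimming, or whose source and
#' target language coincide, are rejected.
#'
#' @param path path to the TSV file
#' @return data.frame of translation entries
#' @export
read_translation_entries <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", fileEncoding = "UTF-8")
  need <- c("source_lang", "source_word", "target_lang", "target_word")
  if (!all(need %in% names(df)))
    stop("dictionary must have columns: ", paste(need, collapse = ", "))
  translation_entries(df$source_lang, df$source_word, df$target_lang, df$target_word)
}

#' Build a validated table of translation entries
#' @param source_lang,source_word,target_lang,target_word parallel character
#'   vectors, one element per dictionary row
#' @return data.frame with the four columns, trimmed
#' @export
translation_entries <- function(source_lang, source_word, target_lang, target_word) {
  df <- data.frame(source_lang = trimws(source_lang),
                   source_word = trimws(source_word),
                   target_lang = trimws(target_lang),
                   target_word = trimws(target_word),
                   stringsAsFactors = FALSE)
  bad <- !nzchar(df$source_word) | !nzchar(df$target_word)
  if (any(bad))
    stop("empty word(s) after trimming in row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  same <- df$source_lang == df$target_lang
  if (any(same))
    stop("source and target language identical in row(s): ",
         paste(utils::head(which(same), 5L), collapse = ", "))
  df
}

# Merge raw (node_a, node_b, language) triples into unique unordered edges
# with unioned language sets. Word comparison is case-insensitive; the first
# encountered casing is kept for display.
merge_support_triples <- function(a, b, lang) {
  if (!length(a)) {
    e <- data.frame(node_a = character(), node_b = character(),
                    language_weight = integer(), family_weight = integer())
    e$languages <- list()
    return(e)
  }
  cp <- canon_pair(a, b)
  key <- paste(norm_word(cp$a), norm_word(cp$b), sep = "\r")
  first <- !duplicated(key)
  langs <- lapply(split(lang, factor(key, levels = key[first])),
                  function(s) sort(unique(s)))
  e <- data.frame(node_a = cp$a[first], node_b = cp$b[first],
                  stringsAsFactors = FALSE)
  e$languages <- unname(langs)
  e$language_weight <- lengths(e$languages)
  e$family_weight <- NA_integer_
  e
}

#' Detect identical translations by round-trip through a pivot language
#'
#' Implements the bilingual-dictionary rule: a pivot-language word `w` is
#' translated into word `v` of language `l`, and `v` is translated back into
#' the pivot language as `u`. Whenever `u` differs from `w` (case-insensitive
#' comparison), the unordered pair `{w, u}` is recorded as an identical
#' translation supported by language `l`. A language supports a pair at most
#' once, however many word paths induce it. Language pairs for which no
#' reverse dictionary exists contribute nothing and are reported via a
#' message.
#'
#' @param entries translation entries (see [translation_entries()])
#' @param pivot_lang the pivot language identifier (e.g. `"eng"`)
#' @return data.frame of unordered edges with list column `languages`
#' @export
detect_roundtrip <- function(entries, pivot_lang) {
  fwd <- entries[entries$source_lang == pivot_lang, , drop = FALSE]
  bwd <- entries[entries$target_lang == pivot_lang, , drop = FALSE]
  if (!nrow(fwd)) stop("no entries with pivot language '", pivot_lang, "' as source")
  missing_rev <- setdiff(unique(fwd$target_lang), unique(bwd$source_lang))
  if (length(missing_rev))
    message("no reverse dictionary for language(s): ",
            paste(missing_rev, collapse = ", "), "; skipped")
  bkey <- paste(bwd$source_lang, norm_word(bwd$source_word), sep = "\r")
  fkey <- paste(fwd$target_lang, norm_word(fwd$target_word), sep = "\r")
  hit <- match(fkey, bkey, nomatch = 0L)
  # expand: each forward row may match several backward rows
  idx <- which(fkey %in% bkey)
  back_by_key <- split(seq_len(nrow(bwd)), bkey)
  w <- character(); u <- character(); lg <- character()
  for (i in idx) {
    js <- back_by_key[[fkey[i]]]
    us <- bwd$target_word[js]
    keep <- norm_word(us) != norm_word(fwd$source_word[i])
    if (any(keep)) {
      w <- c(w, rep(fwd$source_word[i], sum(keep)))
      u <- c(u, us[keep])
      lg <- c(lg, rep(fwd$target_lang[i], sum(keep)))
    }
  }
  merge_support_triples(w, u, lg)
}

#' Detect identical translations shared through a pivot language
#'
#' Implements the multilingual-dictionary rule: whenever a foreign word of
#' language `l` is translated into two or more distinct pivot-language words,
#' every unordered pair of those pivot words is an identical translation
#' supported by `l`. A foreign word with a single pivot translation
#' contributes nothing.
#'
#' @inheritParams detect_roundtrip
#' @return data.frame of unordered edges with list column `languages`
#' @export
detect_shared_translation <- function(entries, pivot_lang) {
  into <- entries[entries$target_lang == pivot_lang, , drop = FALSE]
  key <- paste(into$source_lang, norm_word(into$source_word), sep = "\r")
  groups <- split(seq_len(nrow(into)), key)
  a <- character(); b <- character(); lg <- character()
  for (g in groups) {
    words <- into$target_word[g]
    words <- words[!duplicated(norm_word(words))]
    k <- length(words)
    if (k >= 2L) {
      pr <- utils::combn(k, 2L)
      a <- c(a, words[pr[1L, ]])
      b <- c(b, words[pr[2L, ]])
      lg <- c(lg, rep(into$source_lang[g[1L]], ncol(pr)))
    }
  }
  merge_support_triples(a, b, lg)
}

#' Load a CLICS-style concept edge list
#'
#' Tab-separated file with header naming the two concept-label columns
#' (`node_a`, `node_b` or `concept_a`, `concept_b`) and either explicit
#' comma-joined `languages`/`families` lists or precomputed
#' `language_weight`/`family_weight` counts (`n_languages`/`n_families` also
#' accepted). When only counts are given they are taken verbatim and the sets
#' stay empty. Duplicate unordered pairs are merged: sets are unioned when
#' present; counts-only duplicates take the elementwise maximum (a lower bound
#' on the unknown union).
#'
#' @param path path to the TSV
#' @return a `colex_network` with provenance `"clics"`
#' @export
load_clics_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", fileEncoding = "UTF-8")
  pick <- function(...) {
    cands <- c(...)
    hit <- cands[cands %in% names(df)]
    if (length(hit)) hit[[1]] else NA_character_
  }
  ca <- pick("node_a", "concept_a"); cb <- pick("node_b", "concept_b")
  if (is.na(ca) || is.na(cb))
    stop("cannot find concept label columns (node_a/node_b or concept_a/concept_b)")
  lcol <- pick("languages"); fcol <- pick("families")
  lw <- pick("language_weight", "n_languages"); fw <- pick("family_weight", "n_families")
  has_sets <- !is.na(lcol) && any(nzchar(df[[lcol]]))
  split_set <- function(x) lapply(x, function(s)
    if (is.na(s) || !nzchar(s)) character() else
      sort(unique(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))))
  if (has_sets) {
    languages <- split_set(df[[lcol]])
    families <- if (!is.na(fcol)) split_set(df[[fcol]])
                else replicate(nrow(df), character(), simplify = FALSE)
    language_weight <- lengths(languages)
    family_weight <- if (!is.na(fcol)) lengths(families) else language_weight
  } else {
    if (is.na(lw) || is.na(fw))
      stop("need either languages/families lists or language/family counts")
    language_weight <- suppressWarnings(as.integer(df[[lw]]))
    family_weight <- suppressWarnings(as.integer(df[[fw]]))
    bad <- which(is.na(language_weight) | is.na(family_weight))
    if (length(bad))
      stop("malformed count in row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
    languages <- replicate(nrow(df), character(), simplify = FALSE)
    families <- replicate(nrow(df), character(), simplify = FALSE)
  }
  bad <- which(family_weight > language_weight)
  if (length(bad))
    stop("family count exceeds language count in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(norm_word(df[[ca]]) == norm_word(df[[cb]]) |
                 !nzchar(trimws(df[[ca]])) | !nzchar(trimws(df[[cb]])))
  if (length(bad))
    stop("malformed edge (self-loop or empty label) in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  cp <- canon_pair(trimws(df[[ca]]), trimws(df[[cb]]))
  key <- paste(norm_word(cp$a), norm_word(cp$b), sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  merge_one <- function(rows) {
    ls <- sort(unique(unlist(languages[rows])))
    fs <- sort(unique(unlist(families[rows])))
    if (length(ls)) {
      list(languages = ls, families = fs,
           language_weight = length(ls),
           family_weight = if (length(fs)) length(fs) else length(ls))
    } else {
      list(languages = character(), families = character(),
           language_weight = max(language_weight[rows]),
           family_weight = max(family_weight[rows]))
    }
  }
  merged <- lapply(split(seq_along(key), grp), merge_one)
  edges <- data.frame(node_a = cp$a[first], node_b = cp$b[first],
                      language_weight = vapply(merged, `[[`, 1L, "language_weight"),
                      family_weight = vapply(merged, `[[`, 1L, "family_weight"),
                      stringsAsFactors = FALSE)
  edges$languages <- lapply(merged, `[[`, "languages")
  edges$families <- lapply(merged, `[[`, "families")
  colex_network(edges, provenance = "clics")
}

#' Assemble a colexification network from detected edges
#'
#' Edges with the same unordered node pair are merged (language sets unioned),
#' family sets are derived from the language-to-family metadata, and both
#' weights are recomputed as set cardinalities.
#'
#' @param edges data.frame of edges with list column `languages` (as returned
#'   by [detect_roundtrip()] or [detect_shared_translation()])
#' @param meta named character vector mapping language to family
#'   (see [language_meta()])
#' @param provenance provenance tag for the resulting network
#' @return a `colex_network`
#' @export
assemble_network <- function(edges, meta,
                             provenance = c("shared_translation", "roundtrip",
                                            "synthetic", "clics")) {
  provenance <- match.arg(provenance)
  if (!nrow(edges)) return(colex_network(NULL, provenance = provenance))
  langs <- unique(unlist(edges$languages))
  unknown <- setdiff(langs, names(meta))
  if (length(unknown))
    stop("language id(s) not in metadata: ", paste(unknown, collapse = ", "))
  tri_a <- rep(edges$node_a, lengths(edges$languages))
  tri_b <- rep(edges$node_b, lengths(edges$languages))
  tri_l <- unlist(edges$languages)
  e <- merge_support_triples(tri_a, tri_b, tri_l)
  e$families <- lapply(e$languages, function(ls) sort(unique(unname(meta[ls]))))
  e$family_weight <- lengths(e$families)
  colex_network(e, provenance = provenance)
}

#' Filter a colexification network by attestation thresholds
#'
#' Keeps only edges attested by at least `min_languages` languages and at
#' least `min_families` families (the CLICS cleaning rule uses 3 and 3; the
#' identical-translation networks use at least 2 languages). Nodes left
#' without any edge are dropped. The input network is not modified.
#'
#' @param net a `colex_network`
#' @param min_languages minimum language weight (>= 1)
#' @param min_families minimum family weight (>= 1)
#' @return a new, filtered `colex_network`
#' @export
filter_network <- function(net, min_languages = 3L, min_families = 3L) {
  stopifnot(min_languages >= 1L, min_families >= 1L)
  keep <- net$edges$language_weight >= min_languages &
    net$edges$family_weight >= min_families
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  colex_network(edges, provenance = net$provenance)
}
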