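#' Construct an affective lexicon
#'
#' Holds per-word ratings of valence, arousal and dominance on a declared
#' scale (1-9 for WKB-style lexica, 0-1 for NRC-VAD-style lexica), plus
#' optional per-word rater standard deviations. Words must be unique after
#' case folding; all ratings must lie within the scale bounds. A lexicon may
#' omit arousal and/or dominance, in which case downstream analyses restrict
#' themselves to the available dimensions.
#'
#' @param ratings data.frame with columns `word`, `valence` and optionally
#'   `arousal`, `dominance`, `sd_valence`, `sd_arousal`, `sd_dominance`
#' @param scale_min,scale_max numeric scale bounds
#' @return object of class `affective_lexicon`
#' @export
affective_lexicon <- function(ratings, scale_min = 1, scale_max = 9) {
  stopifnot(is.data.frame(ratings), "word" %in% names(ratings),
            "valence" %in% names(ratings), scale_min < scale_max)
  ratings$word <- trimws(as.character(ratings$word))
  key <- norm_word(ratings$word)
  if (anyDuplicated(key))
    stop("duplicate word(s) after case folding: ",
         paste(utils::head(unique(ratings$word[duplicated(key)]), 5L), collapse = ", "))
  dims <- intersect(c("valence", "arousal", "dominance"), names(ratings))
  for (d in dims) {
    v <- ratings[[d]]
    if (any(!is.na(v) & (v < scale_min | v > scale_max)))
      stop("'", d, "' ratings outside [", scale_min, ", ", scale_max, "]")
  }
  structure(list(ratings = ratings, key = key, dims = dims,
                 scale_min = scale_min, scale_max = scale_max),
            class = "affective_lexicon")
}

#' @export
print.affective_lexicon <- function(x, ...) {
  cat(sprintf("<affective_lexicon> %d words, dimensions: %s, scale [%g, %g]\n",
              nrow(x$ratings), paste(x$dims, collapse = "/"),
              x$scale_min, x$scale_max))
  invisible(x)
}

#' Read an affective lexicon from CSV
#'
#' Comma-separated file with header `word, valence[, arousal, dominance,
#' sd_valence, sd_arousal, sd_dominance]`.
#'
#' @param path path to the CSV file
#' @inheritParams affective_lexicon
#' @return an `affective_lexicon`
#' @export
read_affective_lexicon <- function(path, scale_min = 1, scale_max = 9) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  affective_lexicon(df, scale_min = scale_min, scale_max = scale_max)
}

#' Write an affective lexicon to CSV
#' @param lex an `affective_lexicon`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_affective_lexicon <- function(lex, path) {
  utils::write.csv(lex$ratings, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Clean a concept label into lookup tokens
#'
#' Applies the concept-label cleaning rules used to match CLICS-style concept
#' nodes against a word lexicon: all text within parentheses (including
#' nested parentheses) is removed, the remainder is lowercased and split on
#' whitespace, and the connector token `"or"` is dropped. The result may be
#' empty.
#'
#' @param label a concept label, e.g. `"wash (clothes)"` or
#'   `"breath or breathe"`
#' @return character vector of tokens (possibly empty)
#' @export
clean_concept_label <- function(label) {
  stopifnot(length(label) == 1L, nzchar(label))
  s <- stringi::stri_trans_nfc(enc2utf8(label))
  repeat {
    s2 <- gsub("\\([^()]*\\)", " ", s)
    if (identical(s2, s)) break
    s <- s2
  }
  s <- gsub("[()]", " ", s)  # unbalanced leftovers
  toks <- strsplit(trimws(tolower(s)), "\\s+")[[1]]
  toks[nzchar(toks) & toks != "or"]
}

#' Match network nodes against an affective lexicon
#'
#' In `"word"` mode (identical-translation networks) a node matches if and
#' only if its case-folded label is a lexicon word. In `"concept"` mode
#' (CLICS-style networks) the node label is first cleaned with
#' [clean_concept_label()]; each token is looked up individually and the
#' node's rating is the arithmetic mean of the ratings of the tokens found.
#' A concept node none of whose tokens are in the lexicon is non-matching.
#'
#' @param net a `colex_network`
#' @param lex an `affective_lexicon`
#' @param mode `"word"` or `"concept"`
#' @return object of class `match_result` with elements `ratings` (data.frame
#'   `node` + one column per available dimension), `non_matching` (character),
#'   `tokens` (named list: node -> contributing lexicon words), `dims`, and
#'   the lexicon size.
#' @export
match_nodes <- function(net, lex, mode = c("word", "concept")) {
  mode <- match.arg(mode)
  nodes <- net$nodes
  dims <- lex$dims
  lx <- lex$ratings
  if (mode == "word") {
    hit <- match(norm_word(nodes), lex$key)
    matched <- which(!is.na(hit))
    ratings <- data.frame(node = nodes[matched], stringsAsFactors = FALSE)
    for (d in dims) ratings[[d]] <- lx[[d]][hit[matched]]
    tokens <- as.list(lx$word[hit[matched]])
    names(tokens) <- nodes[matched]
  } else {
    toks <- lapply(nodes, clean_concept_label)
    found <- lapply(toks, function(tt) match(norm_word(tt), lex$key))
    found <- lapply(found, function(ix) ix[!is.na(ix)])
    matched <- which(lengths(found) > 0L)
    ratings <- data.frame(node = nodes[matched], stringsAsFactors = FALSE)
    for (d in dims)
      ratings[[d]] <- vapply(found[matched],
                             function(ix) mean(lx[[d]][ix]), numeric(1))
    tokens <- lapply(found[matched], function(ix) lx$word[ix])
    names(tokens) <- nodes[matched]
  }
  structure(list(ratings = ratings,
                 non_matching = nodes[setdiff(seq_along(nodes), matched)],
                 tokens = tokens, dims = dims, mode = mode,
                 n_lexicon = nrow(lx)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s mode: %d matching, %d non-matching nodes\n",
              x$mode, nrow(x$ratings), length(x$non_matching)))
  invisible(x)
}

#' Coverage of a node-lexicon match
#'
#' Reports the number of matching nodes, the percentage of network nodes
#' matched, and the percentage of lexicon words used by at least one node
#' (a lexicon word contributing to several concept nodes counts once).
#'
#' @param match a `match_result`
#' @return list with `n_matching`, `pct_network`, `pct_lexicon`
#' @export
coverage_report <- function(match) {
  n_nodes <- nrow(match$ratings) + length(match$non_matching)
  used <- unique(norm_word(unlist(match$tokens, use.names = FALSE)))
  list(n_matching = nrow(match$ratings),
       pct_network = if (n_nodes) 100 * nrow(match$ratings) / n_nodes else 0,
       pct_lexicon = if (match$n_lexicon) 100 * length(used) / match$n_lexicon else 0)
}
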