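test_that("round-trip detection records pairs through the pivot and merges languages", {
  entries <- translation_entries(
    source_lang = c("eng", "fra", "eng", "deu", "eng", "fra"),
    source_word = c("age",  "âge", "age", "Ära", "bear", "ours"),
    target_lang = c("fra",  "eng", "deu", "eng", "fra",  "eng"),
    target_word = c("âge",  "era", "Ära", "era", "ours", "bear"))
  edges <- detect_roundtrip(entries, "eng")
  expect_equal(nrow(edges), 1L)
  expect_setequal(c(edges$node_a, edges$node_b), c("age", "era"))
  # two languages induce the same pair -> one edge, language weight 2
  expect_equal(edges$language_weight, 2L)
  expect_setequal(edges$languages[[1]], c("fra", "deu"))
})

test_that("round-trip back to the same word (case-insensitively) yields no edge", {
  entries <- translation_entries(
    source_lang = c("eng", "fra"), source_word = c("bear", "ours"),
    target_lang = c("fra", "eng"), target_word = c("ours", "Bear"))
  edges <- detect_roundtrip(entries, "eng")
  expect_equal(nrow(edges), 0L)
})

test_that("missing reverse dictionaries are skipped with a message", {
  entries <- translation_entries(
    source_lang = c("eng", "fra"), source_word = c("age", "âge"),
    target_lang = c("spa", "eng"), target_word = c("edad", "era"))
  expect_message(edges <- detect_roundtrip(entries, "eng"), "spa")
  expect_equal(nrow(edges), 0L)
})

test_that("shared translations produce all pairs of pivot words", {
  entries <- translation_entries(
    source_lang = rep("ell", 5), source_word = c(rep("pharmacon", 2), rep("x", 3)),
    target_lang = "eng",
    target_word = c("medicine", "poison", "a", "b", "c"))
  edges <- detect_shared_translation(entries, "eng")
  # the pharmacon-style pair plus C(3,2) pairs for the 3-way word
  expect_equal(nrow(edges), 4L)
  key <- paste(edges$node_a, edges$node_b)
  expect_true("medicine poison" %in% key)
  expect_setequal(setdiff(key, "medicine poison"), c("a b", "a c", "b c"))
  expect_true(all(edges$language_weight == 1L))
})

test_that("a foreign word with a single translation contributes nothing", {
  entries <- translation_entries("deu", "toll", "eng", "great")
  expect_equal(nrow(detect_shared_translation(entries, "eng")), 0L)
})

test_that("pair count from k shared translations is k(k-1)/2", {
  for (k in 2:6) {
    entries <- translation_entries(
      source_lang = rep("deu", k), source_word = rep("w", k),
      target_lang = "eng", target_word = paste0("t", seq_len(k)))
    expect_equal(nrow(detect_shared_translation(entries, "eng")),
                 k * (k - 1) / 2)
  }
})

test_that("assembly merges unordered pairs and recomputes family weights", {
  meta <- language_meta(c("X", "Y", "Z"), c("P", "P", "Q"))
  raw <- data.frame(node_a = c("a", "b"), node_b = c("b", "a"),
                    stringsAsFactors = FALSE)
  raw$languages <- list("X", "Y")
  net <- assemble_network(raw, meta, "shared_translation")
  expect_equal(nrow(net$edges), 1L)
  # languages X and Y share family P
  expect_equal(net$edges$language_weight, 2L)
  expect_equal(net$edges$family_weight, 1L)

  raw$languages <- list("X", "Z")
  net2 <- assemble_network(raw, meta, "shared_translation")
  expect_equal(net2$edges$language_weight, 2L)
  expect_equal(net2$edges$family_weight, 2L)

  raw$languages <- list("X", "unknown_lang")
  expect_error(assemble_network(raw, meta), "unknown_lang")
})

test_that("assembly is invariant to the order of input entries", {
  meta <- language_meta(sprintf("L%d", 1:6), sprintf("F%d", c(1, 1, 2, 2, 3, 3)))
  raw <- data.frame(node_a = c("a", "b", "a", "c", "b"),
                    node_b = c("b", "c", "b", "a", "a"),
                    stringsAsFactors = FALSE)
  raw$languages <- list("L1", c("L2", "L3"), "L4", "L5", "L6")
  net1 <- assemble_network(raw, meta)
  set.seed(5)
  for (r in 1:5) {
    perm <- raw[sample.int(nrow(raw)), , drop = FALSE]
    net2 <- assemble_network(perm, meta)
    expect_identical(net1$edges$node_a, net2$edges$node_a)
    expect_identical(net1$edges$language_weight, net2$edges$language_weight)
    expect_identical(net1$edges$families, net2$edges$families)
  }
  expect_true(all(net1$edges$family_weight <= net1$edges$language_weight))
})

test_that("filtering keeps edges meeting both thresholds and drops isolated nodes", {
  net <- make_net(a = c("a", "b", "c", "d", "e"),
                  b = c("b", "c", "d", "e", "f"),
                  lw = c(3, 3, 2, 5, 1), fw = c(3, 2, 2, 5, 1))
  f33 <- filter_network(net, 3, 3)
  expect_equal(nrow(f33$edges), 2L)
  f21 <- filter_network(net, 2, 1)
  expect_equal(nrow(f21$edges), 4L)
  f11 <- filter_network(net, 1, 1)
  expect_equal(nrow(f11$edges), 5L)
  expect_setequal(f11$nodes, net$nodes)
  # idempotence and monotonicity
  expect_identical(filter_network(f33, 3, 3)$edges, f33$edges)
  for (t in 1:5)
    expect_lte(nrow(filter_network(net, t, 1)$edges),
               nrow(filter_network(net, max(t - 1, 1), 1)$edges))
  # nodes only touched by dropped edges disappear
  expect_false("f" %in% f33$nodes)
})

test_that("CLICS-style loading accepts counts, merges duplicates, rejects bad rows", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("concept_a\tconcept_b\tn_languages\tn_families",
               "MEDICINE\tPOISON\t5\t4",
               "POISON\tMEDICINE\t3\t2",
               "AGE\tERA\t2\t2"), tsv)
  net <- load_clics_edges(tsv)
  expect_equal(net$provenance, "clics")
  expect_equal(nrow(net$edges), 2L)
  e <- net$edges[net$edges$node_a == "MEDICINE" | net$edges$node_b == "MEDICINE", ]
  expect_equal(e$language_weight, 5L)
  expect_equal(e$family_weight, 4L)

  writeLines(c("concept_a\tconcept_b\tn_languages\tn_families",
               "A\tB\t2\t4"), tsv)
  expect_error(load_clics_edges(tsv), "row")
})

test_that("CLICS loading with explicit language lists unions duplicates", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("concept_a\tconcept_b\tlanguages\tfamilies",
               "A\tB\tl1,l2\tf1",
               "B\tA\tl2,l3\tf2"), tsv)
  net <- load_clics_edges(tsv)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(net$edges$languages[[1]], c("l1", "l2", "l3"))
  expect_equal(net$edges$language_weight, 3L)
  expect_equal(net$edges$family_weight, 2L)
})

test_that("edge-list TSV output round-trips through the reader", {
  fx <- random_fixture(21, n_clusters = 3L, words_per_cluster = 6L)
  path <- tempfile(fileext = ".tsv")
  write_colex_network(fx$net, path)
  back <- read_colex_network(path, provenance = "synthetic")
  expect_identical(back$edges$node_a, fx$net$edges$node_a)
  expect_identical(back$edges$node_b, fx$net$edges$node_b)
  expect_identical(back$edges$language_weight, fx$net$edges$language_weight)
  expect_identical(back$edges$family_weight, fx$net$edges$family_weight)
  expect_identical(lapply(back$edges$languages, sort),
                   lapply(fx$net$edges$languages, sort))
})

test_that("network construction enforces its invariants", {
  expect_error(make_net("a", "a", 1), "self-loop")
  expect_error(make_net("a", "b", 2, 3), "family_weight")
  expect_error(make_net("a", "b", 0, 0), ">= 1")
})
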