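test_that("co-occurrence counts every unordered pair once per document", {
  rec <- make_annotations(
    c("d1", "d2", "d3", "d4", "d5"),
    list(c("a", "b", "c"), c("a", "b"), "a", c("b", "c"), c("a", "c")))
  co <- build_cooccurrence(rec)
  expect_equal(cooccurrence_count(co, "a", "b"), 2L)
  expect_equal(cooccurrence_count(co, "a", "c"), 2L)
  expect_equal(cooccurrence_count(co, "b", "c"), 2L)
  expect_equal(cooccurrence_count(co, "a", "a"), 4L)  # |D_a|
  expect_equal(cooccurrence_count(co, "a", "zz"), 0L)
  # single-class records contribute no pairs
  co1 <- build_cooccurrence(make_annotations(c("x", "y"), list("a", "b")))
  expect_equal(nrow(co1$pairs), 0L)
  # pair total equals sum over documents of C(|classes|, 2)
  expect_equal(sum(co$pairs$n),
               sum(choose(lengths(rec$classes), 2)))
})

test_that("Jaccard index behaves as a set similarity", {
  rec <- make_annotations(
    c("d1", "d2", "d3", "d4"),
    list(c("p", "q"), c("p", "q"), c("p", "r"), "q"))
  co <- build_cooccurrence(rec)
  # D_p = {d1,d2,d3}, D_q = {d1,d2,d4}: intersection 2, union 4
  expect_equal(jaccard(co, "p", "q"), 0.5)
  expect_equal(jaccard(co, "p", "p"), 1)
  expect_equal(jaccard(co, "r", "q"), 0)   # disjoint document sets
  expect_equal(jaccard(co, "p", "zz"), 0)  # unknown class
  expect_equal(jaccard(co, "p", "q"), jaccard(co, "q", "p"))
})

test_that("absolute and Jaccard rankings can disagree", {
  # "big" co-occurs often with everything but weakly (huge document set);
  # "n1"/"n2" co-occur rarely but exclusively
  docs <- c(
    lapply(1:10, function(i) c("big", sprintf("x%d", i))),
    lapply(1:4, function(i) c("big", "mid")),
    lapply(1:3, function(i) c("n1", "n2")))
  rec <- make_annotations(sprintf("d%02d", seq_along(docs)), docs)
  co <- build_cooccurrence(rec)
  by_abs <- rank_pairs(co, by = "absolute", top = 1)
  by_jac <- rank_pairs(co, by = "jaccard", top = 1)
  expect_equal(c(by_abs$c1, by_abs$c2), c("big", "mid"))
  expect_equal(c(by_jac$c1, by_jac$c2), c("n1", "n2"))
  expect_equal(by_jac$jaccard, 1)
})

test_that("class suggestions rank partners by Jaccard and are symmetric", {
  rec <- make_annotations(
    sprintf("d%d", 1:6),
    list(c("q", "close"), c("q", "close"), c("q", "far"),
         c("far", "z1"), c("far", "z2"), "lonely"))
  co <- build_cooccurrence(rec)
  sug <- suggest_classes(co, "q", top = 5)
  expect_equal(sug$value[1], "close")
  expect_false("q" %in% sug$value)
  expect_equal(sug$source[1], "cooccurrence_jaccard")
  # symmetric at pair level with equal scores
  back <- suggest_classes(co, "close", top = 5)
  expect_equal(back$score[back$value == "q"], sug$score[sug$value == "close"])
  # a class with no co-assignments gets nothing
  expect_equal(nrow(suggest_classes(co, "lonely")), 0L)
})

test_that("enumeration extraction handles the three declared patterns", {
  e1 <- extract_enumeration(
    "Orthopaedic devices such as splints, casts or braces")
  expect_equal(e1$head, "Orthopaedic devices")
  expect_equal(e1$members, c("splints", "casts", "braces"))

  e2 <- extract_enumeration(
    "Sulfonylureas, e.g. glibenclamide, tolbutamide, chlorpropamide")
  expect_equal(e2$head, "Sulfonylureas")
  expect_equal(e2$members,
               c("glibenclamide", "tolbutamide", "chlorpropamide"))

  e3 <- extract_enumeration("Gastrins; Somatostatins; Melanotropins")
  expect_equal(e3$head, "Gastrins")
  expect_equal(e3$members, c("Somatostatins", "Melanotropins"))

  none <- extract_enumeration("Medicinal preparations containing peptides")
  expect_null(none$head)
  expect_equal(none$members, character(0))
  expect_equal(extract_enumeration("")$members, character(0))

  # members never contain list delimiters
  for (def in c("Devices such as a b, c d or e f",
                "Things, e.g. one, two and three",
                "Head; x; y, z")) {
    mem <- extract_enumeration(def)$members
    expect_false(any(grepl("[,;]|\\bor\\b|\\be\\.g\\.", mem)))
  }
})

test_that("ontology matching is whole-word and longest-match-wins", {
  onto <- toy_drug_ontology()
  hit <- match_ontology_terms(
    paste("medicinal preparations containing genetic material which is",
          "inserted into cells of the living body to treat genetic",
          "diseases; gene therapy"), onto)
  expect_true("GT" %in% hit)
  # "containing" must NOT match the synonym "Containment"
  expect_false("CONT" %in% hit)
  expect_equal(match_ontology_terms("", onto), character(0))
  # synonyms do match as whole words
  expect_equal(match_ontology_terms("requires containment today", onto),
               "CONT")
  # longest match wins on overlaps: "gene therapy" beats any shorter term
  onto2 <- taxonomy_from_table(data.frame(
    code = c("R", "GENE", "GTH"), parent_code = c("", "R", "R"),
    level = c(1L, 2L, 2L),
    definition = c("root", "Gene", "Gene Therapy"), synonyms = "",
    stringsAsFactors = FALSE))
  expect_equal(match_ontology_terms("about gene therapy", onto2), "GTH")
})

test_that("sibling expansion suggests the unenumerated ontology children", {
  onto <- toy_drug_ontology()
  sug <- sibling_expand(
    "Sulfonylureas, e.g. glibenclamide, tolbutamide, chlorpropamide", onto)
  expect_setequal(sug, c("Carbutamide", "Acetohexamide"))
  # all children already enumerated: nothing to add
  all_kids <- paste("Sulfonylureas, e.g. glibenclamide, tolbutamide,",
                    "chlorpropamide, carbutamide, acetohexamide")
  expect_equal(sibling_expand(all_kids, onto), character(0))
  # head absent from the ontology: nothing
  expect_equal(sibling_expand("Widgets such as glibenclamide", onto),
               character(0))
  # members that match no child: nothing
  expect_equal(sibling_expand("Sulfonylureas, e.g. aspirin", onto),
               character(0))
})

test_that("the keyword index inverts class-keyword mappings", {
  onto <- toy_drug_ontology()
  t <- taxonomy_from_table(data.frame(
    code = c("A", "A61K48"), parent_code = c("", "A"), level = 1:2,
    definition = c("root",
                   "preparations for gene therapy involving cells"),
    synonyms = "", stringsAsFactors = FALSE))
  idx <- build_keyword_index(t, ontology = onto, classes = "A61K48")
  hits <- keywords_to_classes("gene therapy", idx, t)
  expect_equal(hits$class, "A61K48")
  expect_equal(hits$source, "reverse_index")
  expect_match(hits$definition, "gene therapy")
  expect_equal(nrow(keywords_to_classes("zeppelin", idx)), 0L)
  # round trip: every indexed (class, keyword) pair maps back
  for (i in seq_len(nrow(idx))) {
    back <- keywords_to_classes(idx$keyword[i], idx)
    expect_true(idx$class[i] %in% back$class)
  }
})

test_that("feature overlap compares top feature sets", {
  docs <- separable_docs(n_per_class = 6L)
  spec <- corpus_spec(docs_per_class = 6, min_text_length = 1, seed = 5)
  corpus <- build_corpus(docs, spec)
  ms <- train_all(docs, corpus, spec)
  # a class against itself overlaps completely
  n_x <- nrow(top_features(ms$models[["X"]], 100)$positive)
  expect_equal(feature_overlap(ms, "X", "X", 100), n_x)
  # disjoint signature vocabularies share nothing positive
  expect_equal(feature_overlap(ms, "X", "Y", 100), 0L)
  expect_error(feature_overlap(ms, "X", "nope"), "no model")
})

test_that("correlated class pairs overlap more than random ones", {
  cfg <- generator_config(
    sections = 4, branching = c(3, 3), classes = 8, docs_per_class = 12,
    words_per_doc = 60, signature_fraction = 0.7,
    signature_words_per_class = 8, background_vocab_size = 150,
    multi_label_rate = 0.4,
    correlated_pairs = data.frame(a = c(1, 3), b = c(2, 4),
                                  prob = c(0.9, 0.9)),
    seed = 17)
  t <- gen_taxonomy(cfg)
  sim <- gen_corpus(cfg, t)
  spec <- corpus_spec(docs_per_class = 12, min_text_length = 10, seed = 2)
  corpus <- build_corpus(sim$documents, spec)
  ms <- train_all(sim$documents, corpus, spec)
  co <- build_cooccurrence(sim$annotations)
  res <- overlap_experiment(ms, co, pairs = 2, random_classes = 8,
                            n = 50, seed = 3)
  expect_gt(res$mean_cooccurring, res$mean_random)
})
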