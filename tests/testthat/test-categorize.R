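# small multi-class corpus built from the generator under a fixed seed
small_corpus <- function(classes = 5L, docs_per_class = 10L, seed = 42L,
                         p = 0.8) {
  cfg <- generator_config(sections = 4, branching = c(3, 3),
                          classes = classes,
                          docs_per_class = docs_per_class,
                          words_per_doc = 40,
                          signature_fraction = p,
                          background_vocab_size = 100,
                          multi_label_rate = 0, seed = seed)
  t <- gen_taxonomy(cfg)
  c(gen_corpus(cfg, t), list(taxonomy = t, cfg = cfg))
}

test_that("corpus construction applies length, primary and count filters", {
  sim <- small_corpus()
  docs <- sim$documents
  spec <- corpus_spec(docs_per_class = 10, min_text_length = 10,
                      primary_only = FALSE, seed = 1)
  corpus <- build_corpus(docs, spec)
  expect_equal(corpus$classes, sim$classes)
  expect_true(all(lengths(corpus$positives) == 10L))
  # total positives follow the classes x docs-per-class arithmetic
  expect_equal(sum(lengths(corpus$positives)),
               length(corpus$classes) * spec$docs_per_class)

  # an unreachable document count leaves no eligible classes
  spec_big <- corpus_spec(docs_per_class = 1000, min_text_length = 10)
  expect_equal(length(suppressMessages(build_corpus(docs, spec_big))$classes),
               0L)

  # a text-length requirement beyond every document excludes everything
  spec_long <- corpus_spec(docs_per_class = 5, min_text_length = 10^6)
  expect_equal(suppressMessages(build_corpus(docs, spec_long))$diagnostics$n_long_enough,
               0L)

  # primary_only counts only primary-classified documents
  docs2 <- docs
  docs2$primary[1:5] <- NA_character_
  spec_prim <- corpus_spec(docs_per_class = 10, min_text_length = 10,
                           primary_only = TRUE)
  c2 <- build_corpus(docs2, spec_prim)
  expect_equal(length(c2$classes), length(sim$classes) - 1L)
})

test_that("positive sampling is reproducible under the seed", {
  sim <- small_corpus()
  spec <- corpus_spec(docs_per_class = 5, min_text_length = 10, seed = 9)
  c1 <- build_corpus(sim$documents, spec)
  c2 <- build_corpus(sim$documents, spec)
  expect_identical(c1$positives, c2$positives)
  c3 <- build_corpus(sim$documents,
                     corpus_spec(docs_per_class = 5, min_text_length = 10,
                                 seed = 10))
  expect_false(identical(c1$positives, c3$positives))
})

test_that("round-robin negative sampling takes one document per class in turn", {
  pool <- list(A = sprintf("a%d", 1:5), B = sprintf("b%d", 1:5),
               C = sprintf("c%d", 1:5), D = sprintf("d%d", 1:5))
  # |pos| = 3 and 3 other classes: one document from each
  neg <- sample_negatives("A", c("p1", "p2", "p3"), pool, seed = 1)
  expect_equal(length(neg), 3L)
  src <- substr(neg, 1, 1)
  expect_equal(sort(src), c("b", "c", "d"))

  # 2 other classes and |pos| = 4: cycling gives exactly 2 from each
  pool2 <- list(A = "x", B = sprintf("b%d", 1:5), C = sprintf("c%d", 1:5))
  neg2 <- sample_negatives("A", sprintf("p%d", 1:4), pool2, seed = 1)
  expect_equal(as.integer(table(substr(neg2, 1, 1))), c(2L, 2L))

  # positives are never sampled as negatives
  pool3 <- list(A = "z", B = c("p1", "n1"), C = "n2")
  neg3 <- sample_negatives("A", c("p1", "p2"), pool3, seed = 3)
  expect_false("p1" %in% neg3)

  # determinism under the seed
  expect_identical(sample_negatives("A", c("p1", "p2", "p3"), pool, 7),
                   sample_negatives("A", c("p1", "p2", "p3"), pool, 7))

  # exhausted pool fails with the shortfall reported
  expect_error(sample_negatives("A", sprintf("p%d", 1:9), pool3, 1),
               "exhausted")
})

test_that("threshold assignment honors theta at both extremes and in between", {
  sim <- small_corpus()
  spec <- corpus_spec(docs_per_class = 10, min_text_length = 10, seed = 1)
  corpus <- build_corpus(sim$documents, spec)
  ms <- train_all(sim$documents, corpus, spec)
  doc <- sim$documents$text[1]
  expect_equal(nrow(assign_by_threshold(ms, doc, theta = 0)),
               length(ms$models))
  expect_equal(nrow(assign_by_threshold(ms, doc, theta = 1 + 1e-9)), 0L)
  # raising theta never adds classes
  a5 <- assign_by_threshold(ms, doc, theta = 0.5)$class
  a6 <- assign_by_threshold(ms, doc, theta = 0.6)$class
  expect_true(all(a6 %in% a5))
})

test_that("top-k assignment ranks deterministically and caps at k", {
  sim <- small_corpus()
  spec <- corpus_spec(docs_per_class = 10, min_text_length = 10, seed = 1)
  corpus <- build_corpus(sim$documents, spec)
  ms <- train_all(sim$documents, corpus, spec)
  doc <- sim$documents$text[1]
  expect_equal(nrow(assign_top_k(ms, doc, k = 3)), 3L)
  # k beyond the class count returns all classes
  expect_equal(sort(assign_top_k(ms, doc, k = 100)$class),
               sort(names(ms$models)))
  # top-k sets are nested, so recall is non-decreasing in k
  for (k in 1:4) {
    expect_true(all(assign_top_k(ms, doc, k)$class %in%
                      assign_top_k(ms, doc, k + 1L)$class))
  }
  # the true class of a training document surfaces at k = 1
  expect_equal(assign_top_k(ms, doc, 1)$class, sim$documents$primary[1])
})

test_that("the co-occurrence filter keeps historically co-assigned classes only", {
  # narrative: a contact-lens-mold patent is office-assigned the optical
  # moldings class; predictions about morphinans and tyres never co-occur
  # with it and are removed, while the lens-systems class co-occurs once
  rec <- make_annotations(
    c("p1", "p2", "p3"),
    list(c("B29D11", "G02C7"), c("A61K31", "A61P25"), c("B29D30", "B60C1")))
  co <- build_cooccurrence(rec)
  predicted <- c("B29D11", "G02C7", "A61K31", "B29D30")
  known <- "B29D11"
  kept <- cooccurrence_filter(predicted, known, co)
  expect_equal(kept, c("B29D11", "G02C7"))
  # known = predicted passes through unchanged
  expect_equal(cooccurrence_filter(known, known, co), known)
  expect_error(cooccurrence_filter(predicted, character(0), co),
               "non-empty")
})

test_that("precision/recall/F1 arithmetic follows the conventions", {
  # constant-positive classifier on balanced folds: recall 1, precision 1/2
  sim <- small_corpus(classes = 3L, docs_per_class = 6L)
  spec <- corpus_spec(docs_per_class = 6, min_text_length = 10, seed = 2)
  corpus <- build_corpus(sim$documents, spec)
  always_yes <- function(pos, neg, config, vocab = NULL) {
    structure(list(bias = 100, weights = numeric(ncol(pos)),
                   l2_variance = 1, vocab = vocab, iterations = 0L,
                   objective = 0, grad_norm = 0, converged = TRUE),
              class = "maxent_model")
  }
  cv <- cross_validate(sim$documents, corpus, spec, folds = 3,
                       trainer = always_yes)
  expect_equal(unname(cv$macro["recall"]), 1)
  expect_equal(unname(cv$macro["precision"]), 0.5)
  expect_equal(unname(cv$macro["f1"]), 2 / 3)

  # constant-negative classifier: zero predicted positives scores F1 = 0
  always_no <- function(pos, neg, config, vocab = NULL) {
    structure(list(bias = -100, weights = numeric(ncol(pos)),
                   l2_variance = 1, vocab = vocab, iterations = 0L,
                   objective = 0, grad_norm = 0, converged = TRUE),
              class = "maxent_model")
  }
  cv0 <- cross_validate(sim$documents, corpus, spec, folds = 3,
                        trainer = always_no)
  expect_equal(unname(cv0$macro["f1"]), 0)
})

test_that("macro scores equal hand-computed means on a two-class fixture", {
  docs <- separable_docs(n_per_class = 6L)
  spec <- corpus_spec(docs_per_class = 6, min_text_length = 1, seed = 5)
  corpus <- build_corpus(docs, spec)
  cv <- cross_validate(docs, corpus, spec, folds = 3)
  # separable signatures: every fold classifies perfectly
  expect_equal(unname(cv$macro), c(1, 1, 1))
  expect_equal(cv$macro[["f1"]],
               mean(2 * cv$per_class$precision * cv$per_class$recall /
                      (cv$per_class$precision + cv$per_class$recall)))
  # fold counts: every positive document is tested exactly once
  expect_equal(cv$per_class$tp + cv$per_class$fn, c(6L, 6L))
})

test_that("cross-validation rejects more folds than documents", {
  docs <- separable_docs(n_per_class = 4L)
  spec <- corpus_spec(docs_per_class = 4, min_text_length = 1, seed = 5)
  corpus <- build_corpus(docs, spec)
  expect_error(cross_validate(docs, corpus, spec, folds = 5), "folds")
})

test_that("identical seeds reproduce the evaluation report bit for bit", {
  sim <- small_corpus(classes = 3L, docs_per_class = 6L)
  spec <- corpus_spec(docs_per_class = 6, min_text_length = 10, seed = 4)
  corpus <- build_corpus(sim$documents, spec)
  cv1 <- cross_validate(sim$documents, corpus, spec, folds = 3)
  cv2 <- cross_validate(sim$documents, corpus, spec, folds = 3)
  expect_identical(cv1, cv2)
})

test_that("model training is independent of class order", {
  sim <- small_corpus(classes = 3L, docs_per_class = 6L)
  spec <- corpus_spec(docs_per_class = 6, min_text_length = 10, seed = 4)
  corpus <- build_corpus(sim$documents, spec)
  ms1 <- train_all(sim$documents, corpus, spec)
  corpus_rev <- corpus
  corpus_rev$classes <- corpus$classes  # class list order is canonical
  ms2 <- train_all(sim$documents, corpus_rev, spec)
  doc <- sim$documents$text[1]
  expect_equal(score_all(ms1, doc), score_all(ms2, doc))
})

test_that("model sets round-trip through JSON", {
  sim <- small_corpus(classes = 3L, docs_per_class = 6L)
  spec <- corpus_spec(docs_per_class = 6, min_text_length = 10, seed = 4)
  corpus <- build_corpus(sim$documents, spec)
  ms <- train_all(sim$documents, corpus, spec)
  path <- tempfile(fileext = ".json")
  write_model_set(ms, path)
  ms2 <- read_model_set(path)
  expect_equal(names(ms2$models), names(ms$models))
  for (doc in sim$documents$text[1:5]) {
    expect_identical(score_all(ms2, doc), score_all(ms, doc))
  }
})

test_that("group-level recall generalizes exact recall", {
  sim <- small_corpus()
  t <- sim$taxonomy
  spec <- corpus_spec(docs_per_class = 10, min_text_length = 10, seed = 1)
  corpus <- build_corpus(sim$documents, spec)
  ms <- train_all(sim$documents, corpus, spec)
  eval_docs <- sim$documents[seq(1, nrow(sim$documents), by = 5), ]
  exact <- group_level_recall(ms, eval_docs, t, k = 2)
  exact_lv <- group_level_recall(ms, eval_docs, t, k = 2,
                                 group_level = max(t$placements$level))
  expect_equal(exact_lv, exact)
  for (gl in c(2L, 1L)) {
    expect_gte(group_level_recall(ms, eval_docs, t, k = 2,
                                  group_level = gl), exact)
  }
})
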