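# One-vs-rest categorization pipeline: corpus construction, round-robin
# negative sampling, training, assignment, ratio-preserving
# cross-validation and hierarchy-aware recall.

#' Corpus construction parameters
#'
#' @param docs_per_class Positives (and negatives) per class.
#' @param min_text_length Minimum text length in characters for a document
#'   to qualify.
#' @param primary_only Count a document toward a class only when the class
#'   is its primary classification.
#' @param seed Seed for the uniform sampling of positives.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(docs_per_class = 100L, min_text_length = 2000L,
                        primary_only = FALSE, seed = 1L) {
  stopifnot(docs_per_class >= 1, min_text_length >= 0, seed >= 0)
  structure(list(docs_per_class = as.integer(docs_per_class),
                 min_text_length = as.integer(min_text_length),
                 primary_only = isTRUE(primary_only),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Load document records from TSV
#'
#' Columns: `doc_id`, `year`, `classes` (pipe-separated), `primary`
#' (may be empty), `text`.
#'
#' @param path Path to a document TSV with a header row.
#' @return Data frame with a list column `classes`.
#' @export
load_documents <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  required <- c("doc_id", "classes", "text")
  if (!all(required %in% names(df))) {
    stop("document TSV must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!"year" %in% names(df)) df$year <- NA_character_
  if (!"primary" %in% names(df)) df$primary <- NA_character_
  df$primary[!nzchar(trimws(ifelse(is.na(df$primary), "", df$primary)))] <-
    NA_character_
  data.frame(doc_id = df$doc_id,
             year = suppressWarnings(as.integer(df$year)),
             classes = I(lapply(strsplit(df$classes, "|", fixed = TRUE),
                                function(v) unique(v[nzchar(v)]))),
             primary = df$primary,
             text = df$text,
             stringsAsFactors = FALSE)
}

#' Write document records to TSV
#' @param docs Document records ([load_documents()] layout).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_documents <- function(docs, path) {
  df <- data.frame(
    doc_id = docs$doc_id,
    year = ifelse(is.na(docs$year), "", as.character(docs$year)),
    classes = vapply(docs$classes, paste, "", collapse = "|"),
    primary = ifelse(is.na(docs$primary), "", docs$primary),
    text = docs$text,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Select eligible classes and per-class positive documents
#'
#' A class is eligible when at least `docs_per_class` documents meet the
#' text-length requirement and (with `primary_only`) carry the class as
#' their primary classification.  Positives are drawn uniformly (seeded)
#' from each qualifying set.
#'
#' @param docs Document records.
#' @param spec A [corpus_spec()].
#' @return List with `classes`, `positives` (named list of doc_id
#'   vectors), `class_docs` (all qualifying doc_ids per class, for
#'   negative pools) and `diagnostics` (per-filter counts).
#' @export
build_corpus <- function(docs, spec) {
  long_enough <- nchar(docs$text) >= spec$min_text_length
  pool <- docs[long_enough, , drop = FALSE]
  memberships <- if (spec$primary_only) {
    lapply(seq_len(nrow(pool)), function(i) {
      pr <- pool$primary[i]
      if (is.na(pr)) character(0) else pr
    })
  } else {
    pool$classes
  }
  cls_to_docs <- split(
    rep(pool$doc_id, lengths(memberships)),
    unlist(memberships))
  cls_to_docs <- lapply(cls_to_docs, unique)
  eligible <- names(cls_to_docs)[lengths(cls_to_docs) >= spec$docs_per_class]
  eligible <- sort(eligible)
  positives <- withr::with_seed(spec$seed, {
    lapply(cls_to_docs[eligible], function(ids) {
      sort(sample(ids, spec$docs_per_class))
    })
  })
  diagnostics <- list(
    n_documents = nrow(docs),
    n_long_enough = sum(long_enough),
    n_classes_seen = length(cls_to_docs),
    n_classes_eligible = length(eligible))
  if (!length(eligible)) {
    message("no eligible classes: ", diagnostics$n_long_enough,
            " documents meet the length requirement across ",
            diagnostics$n_classes_seen, " classes")
  }
  list(classes = eligible,
       positives = positives,
       class_docs = cls_to_docs,
       diagnostics = diagnostics)
}

#' Round-robin negative sampling for one class
#'
#' All other classes are shuffled once (seeded); one unused qualifying
#' document is then taken from each class in turn, cycling through the
#' shuffled order until the negative set matches the positive set in size.
#' Documents already in the positive set are skipped.
#'
#' @param class Target class code.
#' @param positives Doc ids of the positive set.
#' @param pool Named list of qualifying doc ids per class (the
#'   `class_docs` of [build_corpus()]); the target class is excluded
#'   internally.
#' @param seed Seed for the shuffle and the per-class draws.
#' @return Character vector of doc ids, same length as `positives`.
#' @export
sample_negatives <- function(class, positives, pool, seed) {
  pool <- pool[setdiff(names(pool), class)]
  need <- length(positives)
  withr::with_seed(seed, {
    order_cls <- sample(names(pool))
    remaining <- lapply(pool[order_cls], function(ids) {
      setdiff(ids, positives)
    })
    negatives <- character(0)
    while (length(negatives) < need) {
      took <- FALSE
      for (cl in order_cls) {
        if (length(negatives) >= need) break
        avail <- setdiff(remaining[[cl]], negatives)
        if (!length(avail)) next
        pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
        negatives <- c(negatives, pick)
        remaining[[cl]] <- setdiff(remaining[[cl]], pick)
        took <- TRUE
      }
      if (!took) {
        stop(sprintf(
          "negative pool exhausted for class %s: needed %d, found %d",
          class, need, length(negatives)), call. = FALSE)
      }
    }
    negatives
  })
}

# deterministic per-class seed derived from the corpus seed
class_seed <- function(seed, class, classes) {
  (seed * 10007L + match(class, classes) * 97L) %% .Machine$integer.max
}

#' Train one binary classifier per eligible class
#'
#' The shared vocabulary is built from all training texts (the union of
#' every class's positive and negative documents).
#'
#' @param docs Document records.
#' @param corpus Result of [build_corpus()].
#' @param spec The [corpus_spec()] used to build the corpus.
#' @param config Classifier hyperparameters ([maxent_config()]).
#' @param verbose Log per-class progress to stderr.
#' @return A `model_set`: per-class `maxent_model`s plus the shared
#'   vocabulary and the spec provenance.
#' @export
train_all <- function(docs, corpus, spec, config = maxent_config(),
                      verbose = FALSE) {
  classes <- corpus$classes
  negatives <- lapply(classes, function(cl) {
    sample_negatives(cl, corpus$positives[[cl]], corpus$class_docs,
                     seed = class_seed(spec$seed, cl, classes))
  })
  names(negatives) <- classes
  train_ids <- unique(c(unlist(corpus$positives), unlist(negatives)))
  tokens <- lapply(docs$text, tokenize)
  names(tokens) <- docs$doc_id
  vocab <- build_vocabulary(tokens[train_ids])
  models <- vector("list", length(classes))
  names(models) <- classes
  for (cl in classes) {
    if (verbose) message("training ", cl)
    Xp <- vectorize_corpus(tokens[corpus$positives[[cl]]], vocab)
    Xn <- vectorize_corpus(tokens[negatives[[cl]]], vocab)
    models[[cl]] <- maxent_train(Xp, Xn, config, vocab = vocab)
  }
  structure(list(models = models, vocab = vocab, spec = spec,
                 negatives = negatives),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set: %d classes, vocabulary of %d tokens>\n",
              length(x$models), vocabulary_size(x$vocab)))
  invisible(x)
}

#' Score every classifier of a model set on one document
#'
#' @param ms A `model_set`.
#' @param doc Document text or a `feature_vector` over the set's
#'   vocabulary.
#' @return Named numeric vector of positive-class posteriors, one per
#'   class.
#' @export
score_all <- function(ms, doc) {
  fv <- if (inherits(doc, "feature_vector")) doc else vectorize(doc, ms$vocab)
  vapply(ms$models, maxent_score, numeric(1), x = fv)
}

#' Assign classes whose score reaches a confidence threshold
#'
#' @param ms A `model_set`.
#' @param doc Document text (or a `feature_vector` over the set's
#'   vocabulary).
#' @param theta Confidence threshold in \[0, 1\] (default 0.5); classes
#'   scoring at least `theta` are assigned.  The empty set is allowed.
#' @return Data frame (`class`, `score`) sorted by descending score.
#' @export
assign_by_threshold <- function(ms, doc, theta = 0.5) {
  s <- score_all(ms, doc)
  keep <- s >= theta
  out <- data.frame(class = names(s)[keep], score = unname(s[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$class), , drop = FALSE]
}

#' Assign the k highest-scoring classes
#'
#' @param ms A `model_set`.
#' @param doc Document text or `feature_vector`.
#' @param k Number of classes to assign (default 10); ties are broken by
#'   class code ascending, and `k` beyond the class count returns all.
#' @return Data frame (`class`, `score`), `k` rows, ranked.
#' @export
assign_top_k <- function(ms, doc, k = 10L) {
  s <- score_all(ms, doc)
  ord <- order(-s, names(s))
  take <- ord[seq_len(min(k, length(s)))]
  data.frame(class = names(s)[take], score = unname(s[take]),
             stringsAsFactors = FALSE)
}

#' Filter predicted classes by historical co-occurrence
#'
#' Keeps a predicted class only if it ever co-occurred with one of the
#' document's known (office-assigned) classes, or is itself known.
#'
#' @param predicted Character vector of predicted class codes.
#' @param known Non-empty character vector of known class codes.
#' @param co A [build_cooccurrence()] table.
#' @return The filtered subset of `predicted`, original order preserved.
#' @export
cooccurrence_filter <- function(predicted, known, co) {
  if (!length(known)) {
    stop("known classes must be non-empty", call. = FALSE)
  }
  keep <- vapply(predicted, function(cl) {
    cl %in% known ||
      any(vapply(known, function(k) cooccurrence_count(co, cl, k) > 0L,
                 logical(1)))
  }, logical(1))
  predicted[keep]
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Ratio-preserving k-fold cross-validation
#'
#' Positives and negatives of each class are split (seeded shuffle, then
#' striping) into `folds` parts each, and fold i pairs the i-th positive
#' part with the i-th negative part, so every test fold keeps the 1:1
#' class ratio.  The fold vocabulary is built from the training folds
#' only.  Macro scores are unweighted means over classes.
#'
#' @param docs Document records.
#' @param corpus Result of [build_corpus()].
#' @param spec The [corpus_spec()] used.
#' @param folds Number of folds (default 10).
#' @param theta Confidence threshold for a positive prediction.
#' @param config Classifier hyperparameters.
#' @param trainer Training function `(pos, neg, config, vocab)`; the
#'   maximum-entropy trainer by default (injectable for diagnostics).
#' @param verbose Log per-class progress.
#' @return List with `per_class` (data frame class, tp, fp, fn,
#'   precision, recall, f1) and `macro` (named vector).
#' @export
cross_validate <- function(docs, corpus, spec, folds = 10L, theta = 0.5,
                           config = maxent_config(), trainer = maxent_train,
                           verbose = FALSE) {
  classes <- corpus$classes
  tokens <- lapply(docs$text, tokenize)
  names(tokens) <- docs$doc_id
  res <- data.frame(class = classes, tp = 0L, fp = 0L, fn = 0L,
                    precision = 0, recall = 0, f1 = 0,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    pos <- corpus$positives[[cl]]
    neg <- sample_negatives(cl, pos, corpus$class_docs,
                            seed = class_seed(spec$seed, cl, classes))
    if (folds > min(length(pos), length(neg))) {
      stop(sprintf("folds (%d) exceeds the positive/negative set size (%d)",
                   folds, min(length(pos), length(neg))), call. = FALSE)
    }
    seed_cl <- class_seed(spec$seed + 1L, cl, classes)
    # striped fold labels dealt out in a seeded random order
    pos_fold <- withr::with_seed(seed_cl,
      sample(rep_len(seq_len(folds), length(pos))))
    neg_fold <- withr::with_seed(seed_cl + 1L,
      sample(rep_len(seq_len(folds), length(neg))))
    tp <- fp <- fn <- 0L
    if (verbose) message("cross-validating ", cl)
    for (f in seq_len(folds)) {
      train_pos <- pos[pos_fold != f]; test_pos <- pos[pos_fold == f]
      train_neg <- neg[neg_fold != f]; test_neg <- neg[neg_fold == f]
      vocab <- build_vocabulary(tokens[c(train_pos, train_neg)])
      m <- trainer(vectorize_corpus(tokens[train_pos], vocab),
                   vectorize_corpus(tokens[train_neg], vocab),
                   config, vocab = vocab)
      sp <- maxent_score(m, vectorize_corpus(tokens[test_pos], vocab))
      sn <- maxent_score(m, vectorize_corpus(tokens[test_neg], vocab))
      tp <- tp + sum(sp >= theta)
      fn <- fn + sum(sp < theta)
      fp <- fp + sum(sn >= theta)
    }
    scores <- prf(tp, fp, fn)
    res$tp[ci] <- tp; res$fp[ci] <- fp; res$fn[ci] <- fn
    res$precision[ci] <- scores["precision"]
    res$recall[ci] <- scores["recall"]
    res$f1[ci] <- scores["f1"]
  }
  list(per_class = res,
       macro = c(precision = mean(res$precision),
                 recall = mean(res$recall),
                 f1 = mean(res$f1)))
}

#' Top-k recall at a coarser hierarchy level
#'
#' A true class counts as recovered when any of the k predicted classes
#' shares its ancestor at `group_level` (e.g. the main group); classes
#' shallower than `group_level` fall back to exact matching.  With
#' `group_level` at the exact class level this equals plain top-k recall.
#' Only true classes that have a trained model enter the denominator.
#'
#' @param ms A `model_set`.
#' @param docs Evaluation document records (with true `classes`).
#' @param t The taxonomy the classes live in.
#' @param k Predictions per document.
#' @param group_level Hierarchy level at which ancestors are compared;
#'   `Inf` (default) keeps every class exact.
#' @return Recall in \[0, 1\].
#' @export
group_level_recall <- function(ms, docs, t, k = 10L, group_level = Inf) {
  model_classes <- names(ms$models)
  key <- function(cl) {
    lv <- t$entry_level[match(cl, t$codes)]
    if (is.infinite(group_level) || group_level >= lv) return(cl)
    paste(sort(ancestor_at_level(t, cl, group_level)), collapse = "|")
  }
  n_true <- 0L; n_hit <- 0L
  for (i in seq_len(nrow(docs))) {
    true <- intersect(docs$classes[[i]], model_classes)
    if (!length(true)) next
    preds <- assign_top_k(ms, docs$text[i], k)$class
    pred_keys <- vapply(preds, key, "")
    for (cl in true) {
      n_true <- n_true + 1L
      if (key(cl) %in% pred_keys) n_hit <- n_hit + 1L
    }
  }
  if (n_true == 0L) return(NaN)
  n_hit / n_true
}

# Model-set serialization ------------------------------------------------

#' Write a model set to versioned JSON
#' @param ms A `model_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_model_set <- function(ms, path) {
  l <- list(
    format_version = 1L,
    vocab = ms$vocab$tokens,
    spec = unclass(ms$spec),
    models = lapply(ms$models, function(m) {
      x <- maxent_model_to_list(m)
      x$vocab <- NULL  # shared vocabulary stored once
      x
    }))
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a model set from JSON
#' @param path Path written by [write_model_set()].
#' @return A `model_set`.
#' @export
read_model_set <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  vocab <- structure(list(tokens = l$vocab, frozen = TRUE),
                     class = "vocabulary")
  models <- lapply(l$models, function(x) {
    x$vocab <- NULL
    m <- maxent_model_from_list(x)
    m$vocab <- vocab
    m
  })
  spec <- l$spec
  spec$primary_only <- isTRUE(spec$primary_only)
  structure(list(models = models, vocab = vocab,
                 spec = structure(spec, class = "corpus_spec")),
            class = "model_set")
}
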