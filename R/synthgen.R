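# Synthetic taxonomies, corpora and annotation tables with the statistical
# structure the pipeline assumes, so every stage is testable without
# proprietary bulk corpora.
#
# Text model: each token is a signature word of one of the document's
# classes with probability `signature_fraction`, otherwise a background
# word drawn from a Zipf(1.0) distribution over a shared vocabulary.

#' Generator configuration
#'
#' Defaults encode the study conditions used throughout the package's
#' evaluation experiments: 20 classes with 100 documents each, 120-word
#' documents whose tokens are class signature words half of the time.
#'
#' @param sections Number of main trees.
#' @param branching Children per entry at each level (vector; depth is
#'   `length(branching) + 1`).
#' @param classes Number of leaf classes that receive documents.
#' @param docs_per_class Documents generated per class.
#' @param words_per_doc Tokens per document text.
#' @param signature_fraction Probability `p` that a token is a signature
#'   word of one of the document's classes (`p = 0` gives
#'   class-independent text).
#' @param signature_words_per_class Signature vocabulary size per class.
#' @param background_vocab_size Shared background vocabulary size.
#' @param multi_label_rate Probability that a document receives a
#'   secondary class in addition to its primary.
#' @param correlated_pairs Data frame (`a`, `b`, `prob`) of class indices
#'   (into the generated class list) whose co-assignment is boosted to
#'   `prob` and which share half their signature words.
#' @param enumeration_fraction Fraction of generated class definitions
#'   carrying a "such as x, y or z" enumeration.
#' @param seed Master seed; identical configurations are bit-identical.
#' @return A `generator_config` list.
#' @export
generator_config <- function(sections = 8L, branching = c(4L, 4L),
                             classes = 20L, docs_per_class = 100L,
                             words_per_doc = 120L,
                             signature_fraction = 0.5,
                             signature_words_per_class = 10L,
                             background_vocab_size = 1000L,
                             multi_label_rate = 0.5,
                             correlated_pairs = NULL,
                             enumeration_fraction = 0,
                             seed = 1L) {
  stopifnot(sections >= 1, all(branching >= 1), classes >= 1,
            docs_per_class >= 1, words_per_doc >= 1,
            signature_fraction >= 0, signature_fraction <= 1,
            signature_words_per_class >= 1, background_vocab_size >= 1,
            multi_label_rate >= 0, multi_label_rate <= 1,
            enumeration_fraction >= 0, enumeration_fraction <= 1)
  if (!is.null(correlated_pairs)) {
    stopifnot(is.data.frame(correlated_pairs),
              all(c("a", "b", "prob") %in% names(correlated_pairs)))
  }
  structure(list(
    sections = as.integer(sections), branching = as.integer(branching),
    classes = as.integer(classes),
    docs_per_class = as.integer(docs_per_class),
    words_per_doc = as.integer(words_per_doc),
    signature_fraction = signature_fraction,
    signature_words_per_class = as.integer(signature_words_per_class),
    background_vocab_size = as.integer(background_vocab_size),
    multi_label_rate = multi_label_rate,
    correlated_pairs = correlated_pairs,
    enumeration_fraction = enumeration_fraction,
    seed = as.integer(seed)), class = "generator_config")
}

gen_word_pool <- c(
  "apparatus", "device", "method", "process", "compound", "preparation",
  "treatment", "measurement", "assembly", "container", "membrane",
  "circuit", "signal", "polymer", "catalyst", "reagent", "vector",
  "culture", "sensor", "filter", "coating", "valve", "engine", "fabric",
  "enzyme", "tissue", "implant", "antenna", "pigment", "solvent")

#' Generate a synthetic taxonomy forest
#'
#' `sections` main trees, each expanding by the per-level branching
#' factors; definitions are drawn from a fixed word pool and optionally
#' carry enumeration patterns for expansion experiments.
#'
#' @param cfg A [generator_config()].
#' @return A single-placement taxonomy of depth `length(branching) + 1`.
#' @export
gen_taxonomy <- function(cfg) {
  withr::with_seed(cfg$seed, {
    rows <- list()
    make_def <- function() {
      base <- paste(sample(gen_word_pool, 3L), collapse = " ")
      if (runif(1) < cfg$enumeration_fraction) {
        members <- sample(gen_word_pool, 3L)
        base <- paste0(base, " such as ", members[1L], ", ", members[2L],
                       " or ", members[3L])
      }
      base
    }
    sections <- LETTERS[seq_len(cfg$sections)]
    for (s in sections) {
      rows[[length(rows) + 1L]] <- data.frame(
        code = s, parent_code = "", level = 1L, definition = make_def(),
        synonyms = "", stringsAsFactors = FALSE)
    }
    frontier <- sections
    level <- 1L
    for (b in cfg$branching) {
      level <- level + 1L
      nxt <- character(0)
      for (parent in frontier) {
        for (i in seq_len(b)) {
          code <- paste0(parent, ".", i)
          rows[[length(rows) + 1L]] <- data.frame(
            code = code, parent_code = parent, level = level,
            definition = make_def(), synonyms = "",
            stringsAsFactors = FALSE)
          nxt <- c(nxt, code)
        }
      }
      frontier <- nxt
    }
    taxonomy_from_table(do.call(rbind, rows))
  })
}

#' Generate a synthetic document corpus with annotations
#'
#' Each document draws a primary class; with probability
#' `multi_label_rate` a secondary class is added, preferring correlated
#' partners.  Tokens follow the signature/background mixture described in
#' the module header.
#'
#' @param cfg A [generator_config()].
#' @param t A taxonomy from [gen_taxonomy()] (or compatible) whose deepest
#'   level supplies the document classes.
#' @return List with `documents` (document records), `annotations`
#'   (annotation records), `classes` and `signatures` (named list of
#'   signature words per class).
#' @export
gen_corpus <- function(cfg, t) {
  depth <- max(t$placements$level)
  leaves <- t$codes[t$entry_level == depth]
  if (length(leaves) < cfg$classes) {
    stop(sprintf("taxonomy has %d leaves but %d classes requested",
                 length(leaves), cfg$classes), call. = FALSE)
  }
  withr::with_seed(cfg$seed + 1L, {
    classes <- sort(sample(leaves, cfg$classes))
    K <- cfg$classes
    S <- cfg$signature_words_per_class
    signatures <- lapply(seq_len(K), function(k) {
      sprintf("sig%dw%d", k, seq_len(S))
    })
    names(signatures) <- classes
    cp <- cfg$correlated_pairs
    if (!is.null(cp) && nrow(cp)) {
      n_share <- max(1L, S %/% 2L)
      for (r in seq_len(nrow(cp))) {
        shared <- sprintf("shared%dw%d", r, seq_len(n_share))
        a <- cp$a[r]; b <- cp$b[r]
        signatures[[a]][seq_len(n_share)] <- shared
        signatures[[b]][seq_len(n_share)] <- shared
      }
    }
    bg <- sprintf("bg%d", seq_len(cfg$background_vocab_size))
    zipf <- (1 / seq_len(cfg$background_vocab_size))
    zipf <- zipf / sum(zipf)
    partner_of <- rep(NA_integer_, K)
    partner_prob <- rep(0, K)
    if (!is.null(cp) && nrow(cp)) {
      partner_of[cp$a] <- cp$b; partner_prob[cp$a] <- cp$prob
      partner_of[cp$b] <- cp$a; partner_prob[cp$b] <- cp$prob
    }
    n_docs <- K * cfg$docs_per_class
    doc_id <- character(n_docs)
    text <- character(n_docs)
    labels <- vector("list", n_docs)
    primary <- character(n_docs)
    d <- 0L
    for (k in seq_len(K)) {
      for (r in seq_len(cfg$docs_per_class)) {
        d <- d + 1L
        doc_id[d] <- sprintf("D%s_%03d", k, r)
        lab <- k
        if (runif(1) < cfg$multi_label_rate && K > 1L) {
          sec <- if (!is.na(partner_of[k]) && runif(1) < partner_prob[k]) {
            partner_of[k]
          } else {
            sample(setdiff(seq_len(K), k), 1L)
          }
          lab <- c(lab, sec)
        }
        labels[[d]] <- classes[lab]
        primary[d] <- classes[k]
        n <- cfg$words_per_doc
        sig_mask <- runif(n) < cfg$signature_fraction
        toks <- character(n)
        n_sig <- sum(sig_mask)
        if (n_sig) {
          which_class <- lab[sample.int(length(lab), n_sig, replace = TRUE)]
          toks[sig_mask] <- vapply(which_class, function(kk) {
            sig <- signatures[[kk]]
            sig[sample.int(length(sig), 1L)]
          }, "")
        }
        n_bg <- n - n_sig
        if (n_bg) {
          toks[!sig_mask] <- sample(bg, n_bg, replace = TRUE, prob = zipf)
        }
        text[d] <- paste(toks, collapse = " ")
      }
    }
    documents <- data.frame(doc_id = doc_id, year = 2000L,
                            classes = I(labels), primary = primary,
                            text = text, stringsAsFactors = FALSE)
    annotations <- new_annotation_records(doc_id, labels, primary)
    list(documents = documents, annotations = annotations,
         classes = classes, signatures = signatures)
  })
}

#' Generate an annotation study with a target annotation count
#'
#' Emulates annotation-count and relatedness regimes: per-document counts
#' are `1 + Poisson(mean_annotations - 1)`, and with probability
#' `relatedness` a multi-annotated document draws all its classes as
#' children of one parent (guaranteed sibling pairs); otherwise classes
#' are uniform over the taxonomy.
#'
#' @param t A taxonomy.
#' @param n_docs Number of documents.
#' @param mean_annotations Target mean annotations per document (>= 1).
#' @param relatedness Probability that a multi-annotated document is
#'   all-sibling.
#' @param seed Seed.
#' @return Annotation records.
#' @export
gen_annotation_study <- function(t, n_docs = 1000L, mean_annotations = 2,
                                 relatedness = 0.5, seed = 1L) {
  stopifnot(mean_annotations >= 1, relatedness >= 0, relatedness <= 1)
  p <- t$placements
  kids_of <- split(seq_len(nrow(p)), p$parent_pid)
  withr::with_seed(seed, {
    counts <- 1L + rpois(n_docs, mean_annotations - 1)
    classes <- vector("list", n_docs)
    for (i in seq_len(n_docs)) {
      k <- counts[i]
      related <- k >= 2L && runif(1) < relatedness
      if (related) {
        # draw all classes from one sibling family; counts beyond the
        # largest family are capped so relatedness is guaranteed
        big <- kids_of[lengths(kids_of) >= min(k, max(lengths(kids_of)))]
        big <- big[lengths(big) >= 2L]
        if (length(big)) {
          fam <- big[[sample.int(length(big), 1L)]]
          classes[[i]] <- p$code[fam[sample.int(length(fam),
                                                min(k, length(fam)))]]
          next
        }
      }
      classes[[i]] <- sample(t$codes, min(k, length(t$codes)))
    }
    new_annotation_records(sprintf("A%05d", seq_len(n_docs)), classes,
                           rep(NA_character_, n_docs))
  })
}
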