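# Guided-search support: class co-occurrence statistics with Jaccard
# ranking, classifier feature-overlap analysis, and keyword-side expansion
# from class definitions and a domain ontology.

#' Build a class co-occurrence table from annotation records
#'
#' Every unordered pair of classes assigned to the same document counts
#' once per document; per-class document sets are retained for the Jaccard
#' index.  Built from existing (office-assigned) annotations only.
#'
#' @param records Annotation records.
#' @return A `cooccurrence_table` with `sets` (doc ids per class) and
#'   `pairs` (data frame `c1`, `c2`, `n` with `c1 < c2`).
#' @export
build_cooccurrence <- function(records) {
  sets <- list()
  for (i in seq_len(nrow(records))) {
    for (cl in records$classes[[i]]) {
      sets[[cl]] <- c(sets[[cl]], records$doc_id[i])
    }
  }
  sets <- lapply(sets, unique)
  pair_keys <- unlist(lapply(records$classes, function(cl) {
    cl <- sort(unique(cl))
    if (length(cl) < 2L) return(character(0))
    pairs <- utils::combn(cl, 2L)
    paste(pairs[1L, ], pairs[2L, ], sep = "\r")
  }))
  pairs <- if (length(pair_keys)) {
    tab <- table(pair_keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    data.frame(c1 = vapply(parts, `[`, "", 1L),
               c2 = vapply(parts, `[`, "", 2L),
               n = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(c1 = character(0), c2 = character(0), n = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(list(sets = sets, pairs = pairs), class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf("<cooccurrence_table: %d classes, %d co-occurring pairs>\n",
              length(x$sets), nrow(x$pairs)))
  invisible(x)
}

#' Co-assignment count of a class pair
#'
#' `cooccurrence_count(co, c, c)` is the size of the class's document set.
#'
#' @param co A `cooccurrence_table`.
#' @param c1,c2 Class codes.
#' @return Integer count (0 for unseen classes or pairs).
#' @export
cooccurrence_count <- function(co, c1, c2) {
  if (c1 == c2) {
    s <- co$sets[[c1]]
    return(if (is.null(s)) 0L else length(s))
  }
  key <- sort(c(c1, c2))
  hit <- co$pairs$c1 == key[1L] & co$pairs$c2 == key[2L]
  if (any(hit)) co$pairs$n[hit][1L] else 0L
}

#' Jaccard index of two classes' document sets
#'
#' @param co A `cooccurrence_table`.
#' @param c1,c2 Class codes.
#' @return |D1 n D2| / |D1 u D2| in \[0, 1\]; 0 when either set is
#'   empty/unknown.
#' @export
jaccard <- function(co, c1, c2) {
  d1 <- co$sets[[c1]]; d2 <- co$sets[[c2]]
  if (is.null(d1) || is.null(d2)) return(0)
  u <- length(union(d1, d2))
  if (u == 0L) return(0)
  length(intersect(d1, d2)) / u
}

#' Rank co-occurring class pairs
#'
#' Pairs are ranked on the absolute co-assignment count or on the Jaccard
#' index; ties are broken by the other criterion (descending) and then by
#' the code pair ascending.
#'
#' @param co A `cooccurrence_table`.
#' @param by `"absolute"` or `"jaccard"`.
#' @param top How many pairs to return.
#' @return Data frame `c1`, `c2`, `n`, `jaccard`, ranked.
#' @export
rank_pairs <- function(co, by = c("jaccard", "absolute"), top = 10L) {
  by <- match.arg(by)
  p <- co$pairs
  if (!nrow(p)) return(cbind(p, jaccard = numeric(0)))
  p$jaccard <- vapply(seq_len(nrow(p)),
                      function(i) jaccard(co, p$c1[i], p$c2[i]), numeric(1))
  ord <- if (by == "absolute") {
    order(-p$n, -p$jaccard, p$c1, p$c2)
  } else {
    order(-p$jaccard, -p$n, p$c1, p$c2)
  }
  utils::head(p[ord, , drop = FALSE], top)
}

new_suggestions <- function(kind, value, source, score) {
  data.frame(kind = kind, value = value, source = source, score = score,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Suggest co-occurring classes for query expansion
#'
#' Partners of the query class ranked by Jaccard index (default) or
#' absolute co-assignment count; the query class itself is excluded.
#'
#' @param co A `cooccurrence_table`.
#' @param query_class Class code the user is confident about.
#' @param top How many suggestions.
#' @param by Ranking criterion, `"jaccard"` or `"absolute"`.
#' @return Expansion suggestions: data frame `kind`, `value`, `source`,
#'   `score`.
#' @export
suggest_classes <- function(co, query_class, top = 10L,
                            by = c("jaccard", "absolute")) {
  by <- match.arg(by)
  p <- co$pairs
  hit <- p$c1 == query_class | p$c2 == query_class
  p <- p[hit, , drop = FALSE]
  if (!nrow(p)) {
    return(new_suggestions(character(0), character(0), character(0),
                           numeric(0)))
  }
  partner <- ifelse(p$c1 == query_class, p$c2, p$c1)
  jac <- vapply(partner, function(cc) jaccard(co, query_class, cc),
                numeric(1))
  ord <- if (by == "absolute") {
    order(-p$n, -jac, partner)
  } else {
    order(-jac, -p$n, partner)
  }
  take <- utils::head(ord, top)
  new_suggestions("class", partner[take],
                  if (by == "absolute") "cooccurrence_abs"
                  else "cooccurrence_jaccard",
                  if (by == "absolute") as.numeric(p$n[take]) else jac[take])
}

#' Overlap of two classifiers' top feature lists
#'
#' The number of common tokens among the top `n` report-filtered positive
#' features of each classifier.
#'
#' @param ms A `model_set`.
#' @param c1,c2 Class codes with trained models.
#' @param n Feature list length (default 100).
#' @return Integer overlap in \[0, n\].
#' @export
feature_overlap <- function(ms, c1, c2, n = 100L) {
  tf <- function(cl) {
    m <- ms$models[[cl]]
    if (is.null(m)) stop("no model for class ", cl, call. = FALSE)
    top_features(m, n, report_filter = TRUE)$positive$token
  }
  length(intersect(tf(c1), tf(c2)))
}

#' Feature overlap of co-occurring versus random class pairs
#'
#' Compares the mean top-`n` feature overlap of the most frequently
#' co-occurring class pairs against the mean pairwise overlap of a seeded
#' random class sample.
#'
#' @param ms A `model_set`.
#' @param co A `cooccurrence_table` over the same classes.
#' @param pairs How many top co-occurring pairs to use.
#' @param random_classes Size of the random class sample.
#' @param n Feature list length.
#' @param seed Seed for the random sample.
#' @return List with `cooccurring` (data frame per pair), `mean_cooccurring`,
#'   `mean_random`, and `random_classes` used.
#' @export
overlap_experiment <- function(ms, co, pairs = 100L, random_classes = 100L,
                               n = 100L, seed = 1L) {
  model_classes <- names(ms$models)
  top_pairs <- rank_pairs(co, by = "absolute", top = nrow(co$pairs))
  top_pairs <- top_pairs[top_pairs$c1 %in% model_classes &
                         top_pairs$c2 %in% model_classes, , drop = FALSE]
  top_pairs <- utils::head(top_pairs, pairs)
  ov <- vapply(seq_len(nrow(top_pairs)), function(i) {
    feature_overlap(ms, top_pairs$c1[i], top_pairs$c2[i], n)
  }, numeric(1))
  rnd <- withr::with_seed(seed, {
    sample(model_classes, min(random_classes, length(model_classes)))
  })
  rnd_ov <- numeric(0)
  if (length(rnd) >= 2L) {
    cmb <- utils::combn(rnd, 2L)
    rnd_ov <- vapply(seq_len(ncol(cmb)), function(i) {
      feature_overlap(ms, cmb[1L, i], cmb[2L, i], n)
    }, numeric(1))
  }
  list(cooccurring = cbind(top_pairs, overlap = ov),
       mean_cooccurring = if (length(ov)) mean(ov) else NaN,
       mean_random = if (length(rnd_ov)) mean(rnd_ov) else NaN,
       random_classes = rnd)
}

#' Extract an enumeration from a class definition
#'
#' Detects the patterns `<head> such as x, y or z`, `<head>, e.g. x, y, z`
#' and `<head>; x; y`, returning the trimmed head and member terms.
#'
#' @param definition Definition string.
#' @return List with `head` (string or `NULL`) and `members` (character
#'   vector, empty when no pattern is found).
#' @export
extract_enumeration <- function(definition) {
  none <- list(head = NULL, members = character(0))
  if (is.null(definition) || is.na(definition) || !nzchar(definition)) {
    return(none)
  }
  split_members <- function(s) {
    parts <- strsplit(s, ",|\\bor\\b|\\band\\b")[[1]]
    parts <- trimws(gsub("\\s+", " ", parts))
    parts[nzchar(parts)]
  }
  clean_head <- function(h) trimws(sub("[,;:]\\s*$", "", trimws(h)))
  m <- regexec("^(.*?)[,;]?\\s+such as\\s+(.*)$", definition,
               ignore.case = TRUE)
  g <- regmatches(definition, m)[[1]]
  if (length(g) == 3L) {
    return(list(head = clean_head(g[2L]), members = split_members(g[3L])))
  }
  m <- regexec("^(.*?)[,;]?\\s*\\be\\.?\\s?g\\.?\\s+(.*)$", definition,
               ignore.case = TRUE)
  g <- regmatches(definition, m)[[1]]
  if (length(g) == 3L) {
    return(list(head = clean_head(g[2L]), members = split_members(g[3L])))
  }
  if (grepl(";", definition, fixed = TRUE)) {
    parts <- trimws(strsplit(definition, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) >= 2L) {
      members <- unlist(lapply(parts[-1L], split_members))
      return(list(head = clean_head(parts[1L]), members = members))
    }
  }
  none
}

# locate whole-word, case-insensitive occurrences of a term; returns a
# two-column matrix of (start, end) character positions
term_spans <- function(term, text) {
  pattern <- paste0("(?<![[:alnum:]])",
                    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
                    "(?![[:alnum:]])")
  m <- gregexpr(pattern, text, ignore.case = TRUE, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  cbind(start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Match ontology terms against a class definition
#'
#' Whole-word, case-insensitive exact matching of ontology labels and
#' synonyms inside the definition; overlapping matches are resolved
#' longest-match-wins.  Partial-word hits (the "containing" vs
#' "Containment" trap) are rejected by construction.
#'
#' @param definition Definition string.
#' @param ontology A taxonomy serving as the term source.
#' @return Character vector of matched entry codes (unique, in match
#'   order).
#' @export
match_ontology_terms <- function(definition, ontology) {
  if (is.null(definition) || is.na(definition) || !nzchar(definition)) {
    return(character(0))
  }
  terms <- data.frame(
    code = rep(ontology$codes, lengths(ontology$synonyms) + 1L),
    term = unlist(Map(c, ontology$definitions, ontology$synonyms)),
    stringsAsFactors = FALSE)
  terms <- terms[nzchar(terms$term), , drop = FALSE]
  terms <- terms[order(-nchar(terms$term)), , drop = FALSE]
  taken <- NULL
  hits <- character(0)
  for (i in seq_len(nrow(terms))) {
    spans <- term_spans(terms$term[i], definition)
    if (is.null(spans)) next
    for (r in seq_len(nrow(spans))) {
      s <- spans[r, "start"]; e <- spans[r, "end"]
      overlaps <- !is.null(taken) &&
        any(taken[, "start"] <= e & taken[, "end"] >= s)
      if (!overlaps) {
        taken <- rbind(taken, spans[r, , drop = FALSE])
        hits <- c(hits, terms$code[i])
      }
    }
  }
  unique(hits)
}

# children (entry codes) of an ontology entry across all its placements
ontology_children <- function(ontology, code) {
  pids <- tax_placement_ids(ontology, code)
  unique(ontology$placements$code[
    !is.na(ontology$placements$parent_pid) &
      ontology$placements$parent_pid %in% pids])
}

#' Expand an enumerated definition with ontology siblings
#'
#' When a definition names an ontology term as its enumeration head and at
#' least one member matches a child of that term, the remaining children
#' are suggested as high-precision related terms.
#'
#' @param definition Definition string containing an enumeration.
#' @param ontology A taxonomy serving as the domain ontology.
#' @return Character vector of suggested term labels (children not already
#'   enumerated); empty when the pattern or ontology support is missing.
#' @export
sibling_expand <- function(definition, ontology) {
  enum <- extract_enumeration(definition)
  if (is.null(enum$head) || !length(enum$members)) return(character(0))
  head_codes <- match_ontology_terms(enum$head, ontology)
  if (!length(head_codes)) return(character(0))
  members <- tolower(enum$members)
  out <- character(0)
  for (hc in head_codes) {
    kids <- ontology_children(ontology, hc)
    if (!length(kids)) next
    kid_labels <- ontology$definitions[match(kids, ontology$codes)]
    kid_names <- lapply(seq_along(kids), function(i) {
      tolower(c(kid_labels[i],
                ontology$synonyms[[match(kids[i], ontology$codes)]]))
    })
    member_hits <- vapply(kid_names, function(nm) any(nm %in% members),
                          logical(1))
    if (!any(member_hits)) next
    out <- c(out, kid_labels[!member_hits])
  }
  unique(out)
}

#' Build a keyword-to-class reverse index
#'
#' Indexes (i) ontology terms matched in each class definition and (ii)
#' the top-`n` positive classifier features per class, so keywords can be
#' mapped back to classes.
#'
#' @param t Taxonomy whose class definitions are indexed.
#' @param ontology Optional domain ontology for definition matching.
#' @param ms Optional `model_set` contributing classifier features.
#' @param classes Classes to index (default: all with models, else all
#'   taxonomy entries).
#' @param n Features per class.
#' @return Data frame `keyword`, `class`, `source` of class
#'   `keyword_index`.
#' @export
build_keyword_index <- function(t, ontology = NULL, ms = NULL,
                                classes = NULL, n = 10L) {
  if (is.null(classes)) {
    classes <- if (!is.null(ms)) names(ms$models) else t$codes
  }
  rows <- list()
  for (cl in classes) {
    if (!is.null(ontology) && cl %in% t$codes) {
      def <- t$definitions[match(cl, t$codes)]
      codes <- match_ontology_terms(def, ontology)
      labels <- ontology$definitions[match(codes, ontology$codes)]
      if (length(labels)) {
        rows[[length(rows) + 1L]] <- data.frame(
          keyword = tolower(labels), class = cl, source = "reverse_index",
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(ms) && cl %in% names(ms$models)) {
      feats <- top_features(ms$models[[cl]], n,
                            report_filter = TRUE)$positive$token
      if (length(feats)) {
        rows[[length(rows) + 1L]] <- data.frame(
          keyword = feats, class = cl, source = "classifier_feature",
          stringsAsFactors = FALSE)
      }
    }
  }
  idx <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(keyword = character(0), class = character(0),
               source = character(0), stringsAsFactors = FALSE)
  }
  idx <- unique(idx)
  structure(idx, class = c("keyword_index", "data.frame"))
}

#' Suggest classes for a keyword
#'
#' Looks the keyword up in a reverse index built by
#' [build_keyword_index()] and attaches class definitions where a
#' taxonomy is supplied.
#'
#' @param keyword A single token or term (case-insensitive).
#' @param index A `keyword_index`.
#' @param t Optional taxonomy for definitions.
#' @return Data frame `class`, `source`, `definition` (possibly empty).
#' @export
keywords_to_classes <- function(keyword, index, t = NULL) {
  hit <- index[tolower(index$keyword) == tolower(keyword), , drop = FALSE]
  out <- data.frame(class = hit$class, source = hit$source,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out$definition <- if (!is.null(t) && nrow(out)) {
    ifelse(out$class %in% t$codes,
           t$definitions[match(out$class, t$codes)], NA_character_)
  } else character(nrow(out))
  row.names(out) <- NULL
  out
}
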