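# Bag-of-words features: tokenizer, vocabulary, sparse count vectors.

.taxocat_env <- new.env(parent = emptyenv())

#' Default English stopword list
#'
#' Shipped with the package as a plain-text file (one token per line) and
#' overridable wherever a stopword argument is accepted.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  if (is.null(.taxocat_env$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "taxocat")
    .taxocat_env$stopwords <- readLines(path, encoding = "UTF-8")
  }
  .taxocat_env$stopwords
}

#' Tokenize text for classification
#'
#' Lowercases, splits on any non-alphanumeric character, drops tokens
#' shorter than two characters and tokens on the stopword list.
#'
#' @param text A character string (empty text gives an empty token list).
#' @param stopwords Stopword list; defaults to the shipped English list.
#' @return Character vector of tokens.
#' @export
tokenize <- function(text, stopwords = default_stopwords()) {
  if (!length(text) || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nchar(toks) >= 2L]
  toks[!toks %in% stopwords]
}

#' Build a vocabulary from training documents
#'
#' The vocabulary fixes the feature space of the classifiers and must be
#' built from training documents only; it is frozen on construction unless
#' `freeze = FALSE`, and vectorizing against an unfrozen vocabulary is an
#' error (a train/test leak guard).  Tokens are sorted, so the result does
#' not depend on document order.
#'
#' @param docs Either a character vector of texts or a list of token
#'   vectors (already tokenized).
#' @param stopwords Stopword list used when `docs` are raw texts.
#' @param freeze Freeze the vocabulary (default).
#' @return A `vocabulary` object.
#' @export
build_vocabulary <- function(docs, stopwords = default_stopwords(),
                             freeze = TRUE) {
  toks <- if (is.character(docs)) {
    lapply(docs, tokenize, stopwords = stopwords)
  } else docs
  tokens <- sort(unique(unlist(toks)))
  structure(list(tokens = tokens, frozen = freeze), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d tokens%s>\n", length(x$tokens),
              if (x$frozen) ", frozen" else ""))
  invisible(x)
}

#' Freeze a vocabulary
#' @param v A vocabulary.
#' @return The vocabulary with insertion disabled (required for
#'   vectorization).
#' @export
freeze_vocabulary <- function(v) {
  v$frozen <- TRUE
  v
}

#' Vocabulary size
#' @param v A vocabulary.
#' @return Integer number of tokens.
#' @export
vocabulary_size <- function(v) length(v$tokens)

#' Turn a document into a sparse count vector
#'
#' Tokens outside the vocabulary map to nothing; counts equal token
#' multiplicities.
#'
#' @param doc Text string or a token vector.
#' @param v A frozen vocabulary.
#' @param stopwords Stopword list used when `doc` is raw text.
#' @return A `feature_vector`: sparse map from token index to count.
#' @export
vectorize <- function(doc, v, stopwords = default_stopwords()) {
  if (!isTRUE(v$frozen)) {
    stop("vocabulary is not frozen; freeze it before vectorizing ",
         "(vocabularies must be built on training documents only)",
         call. = FALSE)
  }
  # a single string is raw text; a longer character vector is tokens
  toks <- if (is.character(doc) && length(doc) == 1L) {
    tokenize(doc, stopwords = stopwords)
  } else {
    as.character(doc)
  }
  idx <- match(toks, v$tokens)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) {
    return(structure(list(idx = integer(0), cnt = integer(0),
                          size = length(v$tokens)),
                     class = "feature_vector"))
  }
  tab <- table(idx)
  structure(list(idx = as.integer(names(tab)),
                 cnt = as.integer(tab),
                 size = length(v$tokens)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector: %d/%d nonzero, total count %d>\n",
              length(x$idx), x$size, sum(x$cnt)))
  invisible(x)
}

#' Vectorize a corpus into a sparse document-term matrix
#'
#' @param docs Character vector of texts or list of token vectors.
#' @param v A frozen vocabulary.
#' @param stopwords Stopword list used for raw texts.
#' @return A `dgCMatrix` with one row per document and one column per
#'   vocabulary token.
#' @export
vectorize_corpus <- function(docs, v, stopwords = default_stopwords()) {
  if (!isTRUE(v$frozen)) {
    stop("vocabulary is not frozen; freeze it before vectorizing",
         call. = FALSE)
  }
  tok_lists <- if (is.character(docs)) {
    lapply(docs, tokenize, stopwords = stopwords)
  } else docs
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_along(tok_lists)) {
    idx <- match(tok_lists[[d]], v$tokens)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    tab <- table(idx)
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.integer(tab))
    ii <- c(ii, rep.int(d, length(tab)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(tok_lists), length(v$tokens)))
}

# feature_vector -> 1-row sparse matrix
fv_as_matrix <- function(x) {
  Matrix::sparseMatrix(i = rep.int(1L, length(x$idx)), j = x$idx, x = x$cnt,
                       dims = c(1L, x$size))
}
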