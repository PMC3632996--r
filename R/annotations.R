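# Document -> class assignment records and their statistics.
#
# Records are kept as a data frame with a list column `classes`; `primary`
# is NA for MeSH-style records, which designate no primary heading.

new_annotation_records <- function(doc_id, classes, primary) {
  data.frame(doc_id = doc_id,
             classes = I(classes),
             primary = primary,
             stringsAsFactors = FALSE)
}

#' Load document annotations from TSV
#'
#' Columns: `doc_id`, `classes` (pipe-separated class codes), and optional
#' `primary`.  Rows sharing a `doc_id` are merged by set union, so repeated
#' versions of the same document are counted once.  Codes that do not
#' resolve in the companion taxonomy are kept but tallied in the
#' `unresolved` attribute; rows with an empty classes field are dropped
#' with a warning listing their doc_ids (also in attribute `rejected`).
#' A primary code missing from its classes set is added with a warning.
#'
#' @param path Path to an annotation TSV with a header row.
#' @param t Companion taxonomy used to resolve codes.
#' @return Annotation records: a data frame with columns `doc_id`,
#'   `classes` (list), `primary`.
#' @export
load_annotations <- function(path, t) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("doc_id", "classes") %in% names(df))) {
    stop("annotation TSV must have columns doc_id, classes", call. = FALSE)
  }
  if (!"primary" %in% names(df)) df$primary <- NA_character_
  df$primary[!nzchar(trimws(ifelse(is.na(df$primary), "", df$primary)))] <-
    NA_character_
  cls <- lapply(strsplit(df$classes, "|", fixed = TRUE),
                function(v) unique(trimws(v[nzchar(trimws(v))])))
  empty <- lengths(cls) == 0L
  rejected <- df$doc_id[empty]
  if (length(rejected)) {
    warning("rejected record(s) with empty classes field: ",
            paste(rejected, collapse = ", "), call. = FALSE)
  }
  df <- df[!empty, , drop = FALSE]
  cls <- cls[!empty]
  repaired <- character(0)
  for (i in seq_along(cls)) {
    pr <- df$primary[i]
    if (!is.na(pr) && !(pr %in% cls[[i]])) {
      cls[[i]] <- c(cls[[i]], pr)
      repaired <- c(repaired, df$doc_id[i])
    }
  }
  if (length(repaired)) {
    warning("primary code not in classes; added for: ",
            paste(repaired, collapse = ", "), call. = FALSE)
  }
  # merge duplicate doc_ids by union; first non-missing primary wins
  ids <- unique(df$doc_id)
  idx <- split(seq_len(nrow(df)), factor(df$doc_id, levels = ids))
  classes <- lapply(idx, function(ii) unique(unlist(cls[ii])))
  primary <- vapply(idx, function(ii) {
    pr <- df$primary[ii]
    pr <- pr[!is.na(pr)]
    if (length(pr)) pr[[1]] else NA_character_
  }, character(1))
  rec <- new_annotation_records(ids, unname(classes), unname(primary))
  all_codes <- unlist(rec$classes)
  n_unres <- sum(!all_codes %in% t$codes)
  attr(rec, "unresolved") <- n_unres
  attr(rec, "rejected") <- rejected
  if (n_unres > 0L) {
    warning(sprintf("%d annotation code(s) do not resolve in the taxonomy",
                    n_unres), call. = FALSE)
  }
  rec
}

#' Write annotation records to TSV
#' @param records Annotation records.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_annotations <- function(records, path) {
  df <- data.frame(
    doc_id = records$doc_id,
    classes = vapply(records$classes, paste, "", collapse = "|"),
    primary = ifelse(is.na(records$primary), "", records$primary),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Distribution of annotations per document
#'
#' @param records Annotation records.
#' @return List with `histogram` (table over set sizes), `mean`, and
#'   `multi_fraction` (share of documents with >= 2 classes).
#' @export
annotation_count_distribution <- function(records) {
  n <- lengths(records$classes)
  list(histogram = table(n),
       mean = mean(n),
       multi_fraction = mean(n >= 2L))
}

# codes of a record that resolve in the taxonomy
resolvable <- function(classes, t) classes[classes %in% t$codes]

#' Per-document minimum and maximum pairwise annotation distance
#'
#' For each document with at least two (resolvable) annotations, the
#' minimum and maximum over the pairwise shortest-path distances of its
#' class codes, plus aggregate histograms of both.
#'
#' @param records Annotation records.
#' @param t A taxonomy.
#' @return List with `per_doc` (data frame doc_id, min, max),
#'   `min_hist`, `max_hist`.
#' @export
distance_profile <- function(records, t) {
  keep <- vapply(records$classes,
                 function(cl) length(resolvable(cl, t)) >= 2L, logical(1))
  docs <- records[keep, , drop = FALSE]
  codes <- unique(unlist(lapply(docs$classes, resolvable, t = t)))
  if (!length(codes)) {
    return(list(per_doc = data.frame(doc_id = character(0), min = integer(0),
                                     max = integer(0)),
                min_hist = table(integer(0)), max_hist = table(integer(0))))
  }
  dm <- distance_matrix(t, codes)
  mins <- integer(nrow(docs)); maxs <- integer(nrow(docs))
  for (i in seq_len(nrow(docs))) {
    cl <- resolvable(docs$classes[[i]], t)
    sub <- dm[cl, cl, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    mins[i] <- min(vals)
    maxs[i] <- max(vals)
  }
  list(per_doc = data.frame(doc_id = docs$doc_id, min = mins, max = maxs,
                            stringsAsFactors = FALSE),
       min_hist = table(mins), max_hist = table(maxs))
}

#' How often co-assigned classes are closely related
#'
#' For each relation tag, the fraction of multi-annotated documents having
#' at least one annotation pair bearing that tag (pairs are classified by
#' [relationship()]; tags are exclusive per pair, so one document can count
#' toward several tags through different pairs).
#'
#' @param records Annotation records.
#' @param t A taxonomy.
#' @return Named numeric vector over `sibling`, `parent_child`,
#'   `ancestor`, `same_main_tree`.
#' @export
relationship_profile <- function(records, t) {
  tags <- c("sibling", "parent_child", "ancestor", "same_main_tree")
  keep <- vapply(records$classes,
                 function(cl) length(resolvable(cl, t)) >= 2L, logical(1))
  docs <- records[keep, , drop = FALSE]
  counts <- setNames(numeric(length(tags)), tags)
  if (!nrow(docs)) return(counts)
  for (i in seq_len(nrow(docs))) {
    cl <- resolvable(docs$classes[[i]], t)
    seen <- character(0)
    for (a in seq_along(cl)) {
      for (b in seq_len(a - 1L)) {
        seen <- c(seen, relationship(t, cl[a], cl[b]))
      }
    }
    hit <- tags %in% seen
    counts[hit] <- counts[hit] + 1
  }
  counts / nrow(docs)
}

#' Fraction of documents confined to one main tree
#'
#' Includes single-annotated documents (which are trivially confined).  A
#' document counts as single-section when one main-tree root covers at
#' least one placement of every assigned class.
#'
#' @param records Annotation records.
#' @param t A taxonomy.
#' @return A fraction in \[0, 1\].
#' @export
single_section_fraction <- function(records, t) {
  if (!nrow(records)) return(NaN)
  tree_sets <- function(cl) {
    lapply(cl, function(cc) unique(t$placements$tree[tax_placement_ids(t, cc)]))
  }
  single <- vapply(records$classes, function(cl) {
    cl <- resolvable(cl, t)
    if (!length(cl)) return(FALSE)
    ts <- tree_sets(cl)
    length(Reduce(intersect, ts)) > 0L
  }, logical(1))
  mean(single)
}

#' How often documents literally contain an assigned class definition
#'
#' Case-insensitive, whitespace-normalized substring search of each
#' assigned class's definition in the document text.  Empty definitions
#' never match.
#'
#' @param docs Document records (data frame with `doc_id`, `text`).
#' @param records Annotation records.
#' @param t A taxonomy.
#' @return Fraction of documents containing at least one of their class
#'   definitions.
#' @export
definition_occurrence_rate <- function(docs, records, t) {
  norm <- function(s) trimws(gsub("\\s+", " ", tolower(s)))
  txt <- setNames(vapply(docs$text, norm, ""), docs$doc_id)
  hits <- vapply(seq_len(nrow(records)), function(i) {
    id <- records$doc_id[i]
    if (!id %in% names(txt)) return(FALSE)
    cl <- resolvable(records$classes[[i]], t)
    defs <- norm(t$definitions[match(cl, t$codes)])
    defs <- defs[nzchar(defs)]
    any(vapply(defs, function(d) grepl(d, txt[[id]], fixed = TRUE),
               logical(1)))
  }, logical(1))
  mean(hits)
}
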