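# Internal representation ------------------------------------------------
#
# A taxonomy is a forest of class entries.  Entries are unique codes; each
# entry occupies one or more *placements* (tree positions).  Multi-placement
# entries arise in MeSH, where a descriptor can carry several tree numbers;
# IPC-like taxonomies loaded from TSV are single-placement.  An implicit
# artificial root joins the main trees so that shortest paths exist between
# any two entries.  For MeSH the main-tree roots are the category letters
# (A, B, C, ...), which are structural nodes, not entries; for TSV
# taxonomies the roots are the level-1 entries themselves.

new_taxonomy <- function(codes, definitions, synonyms, placements, trees,
                         virtual_roots) {
  stopifnot(length(codes) == length(definitions),
            length(codes) == length(synonyms))
  entry_level <- rep(NA_integer_, length(codes))
  if (nrow(placements)) {
    lv <- tapply(placements$level, placements$code, min)
    entry_level <- as.integer(lv[codes])
  }
  t <- structure(list(
    codes = codes,
    definitions = definitions,
    synonyms = synonyms,
    entry_level = entry_level,
    placements = placements,
    trees = trees,
    virtual_roots = virtual_roots
  ), class = "taxonomy")
  t$adj <- tax_build_adjacency(t)
  t
}

empty_placements <- function() {
  data.frame(pid = integer(), code = character(), parent_pid = integer(),
             level = integer(), tree = character(), stringsAsFactors = FALSE)
}

# Node ids for the search graph: 1..P placements, then (if roots are
# virtual) one node per main tree, then the artificial root last.
tax_node_count <- function(t) {
  nrow(t$placements) + if (t$virtual_roots) length(t$trees) + 1L else 1L
}

tax_root_node <- function(t) tax_node_count(t)

tax_tree_node <- function(t, tree) {
  stopifnot(t$virtual_roots)
  nrow(t$placements) + match(tree, t$trees)
}

tax_build_adjacency <- function(t) {
  n <- tax_node_count(t)
  adj <- vector("list", n)
  p <- t$placements
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  root <- n
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      if (!is.na(p$parent_pid[i])) {
        add_edge(i, p$parent_pid[i])
      } else if (t$virtual_roots) {
        add_edge(i, nrow(p) + match(p$tree[i], t$trees))
      } else {
        add_edge(i, root)
      }
    }
  }
  if (t$virtual_roots) {
    for (k in seq_along(t$trees)) add_edge(nrow(p) + k, root)
  }
  lapply(adj, function(v) unique(as.integer(v)))
}

tax_check_code <- function(t, code) {
  missing <- setdiff(code, t$codes)
  if (length(missing)) {
    stop("unknown class code(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

tax_placement_ids <- function(t, code) {
  which(t$placements$code == code)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy: %d entries, %d placements, %d main trees, depth %d>\n",
              length(x$codes), nrow(x$placements), length(x$trees),
              if (nrow(x$placements)) max(x$placements$level) else 0L))
  invisible(x)
}

#' Number of unique entries in a taxonomy
#' @param t A taxonomy.
#' @return Integer count of unique class entries.
#' @export
n_entries <- function(t) length(t$codes)

#' Number of placements (tree positions) in a taxonomy
#' @param t A taxonomy.
#' @return Integer count of placements; at least [n_entries()].
#' @export
n_placements <- function(t) nrow(t$placements)

#' Look up entry codes by their definition label
#'
#' Convenience for MeSH-style taxonomies, where the human-readable heading
#' rather than the descriptor identifier is usually known.
#'
#' @param t A taxonomy.
#' @param label Definition string (exact, case-insensitive).
#' @return Character vector of matching codes (possibly empty).
#' @export
find_code <- function(t, label) {
  t$codes[tolower(t$definitions) == tolower(label)]
}

#' Definition string of an entry
#' @param t A taxonomy.
#' @param code Entry code.
#' @return The definition (main label) string.
#' @export
definition_of <- function(t, code) {
  tax_check_code(t, code)
  t$definitions[match(code, t$codes)]
}

# Loaders ----------------------------------------------------------------

#' Load a MeSH descriptor XML file
#'
#' Reads NLM's descriptor XML (the `desc<year>.xml` distribution).  Each
#' `DescriptorRecord` becomes one entry; each of its tree numbers becomes a
#' placement.  Hierarchy edges follow the tree-number prefix rule: the
#' parent of `C01.234.567` is the descriptor holding tree number `C01.234`.
#' Tree numbers without a dot are children of their category letter, which
#' is modeled as a main-tree root node (not an entry).  All entry terms
#' except the preferred heading are kept as synonyms.
#'
#' @param path Path to a descriptor XML file.
#' @return A taxonomy.  Descriptors without tree numbers are skipped with a
#'   warning carrying the skipped count.
#' @export
load_mesh_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed MeSH XML in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  codes <- character(0); defs <- character(0); syns <- list()
  tn_code <- character(0); tn_num <- character(0)
  skipped <- 0L
  for (rec in recs) {
    ui <- xml2::xml_text(xml2::xml_find_first(rec, "./DescriptorUI"))
    name <- xml2::xml_text(
      xml2::xml_find_first(rec, "./DescriptorName/String"))
    if (is.na(ui) || !nzchar(ui)) {
      stop("DescriptorRecord without DescriptorUI (name: ",
           if (is.na(name)) "<none>" else name, ")", call. = FALSE)
    }
    tns <- xml2::xml_text(
      xml2::xml_find_all(rec, "./TreeNumberList/TreeNumber"))
    if (!length(tns)) {
      skipped <- skipped + 1L
      next
    }
    terms <- xml2::xml_text(xml2::xml_find_all(
      rec, "./ConceptList/Concept/TermList/Term/String"))
    codes <- c(codes, ui)
    defs <- c(defs, name)
    syns <- c(syns, list(setdiff(unique(terms), name)))
    tn_code <- c(tn_code, rep(ui, length(tns)))
    tn_num <- c(tn_num, tns)
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d descriptor(s) without tree numbers", skipped),
            call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    stop("duplicate DescriptorUI: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  # placements from tree numbers
  level <- lengths(gregexpr("\\.", tn_num)) + 1L
  level[!grepl("\\.", tn_num)] <- 1L
  parent_num <- sub("\\.[^.]*$", "", tn_num)
  parent_num[level == 1L] <- NA_character_
  tree <- substr(tn_num, 1L, 1L)
  parent_pid <- match(parent_num, tn_num)
  orphan <- !is.na(parent_num) & is.na(parent_pid)
  if (any(orphan)) {
    stop("tree number(s) without parent in file: ",
         paste(tn_num[orphan], collapse = ", "), call. = FALSE)
  }
  placements <- data.frame(
    pid = seq_along(tn_num), code = tn_code, parent_pid = parent_pid,
    level = level, tree = tree, stringsAsFactors = FALSE)
  new_taxonomy(codes, defs, syns, placements,
               trees = sort(unique(tree)), virtual_roots = TRUE)
}

#' Load a taxonomy from the tab-separated dialect
#'
#' The TSV carries explicit parent codes because IPC subgroup codes do not
#' encode their own parentage.  Columns: `code`, `parent_code` (empty for
#' main-tree roots), `level`, `definition`, `synonyms` (pipe-separated, may
#' be empty).  Row order is irrelevant.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A taxonomy with a single placement per entry.
#' @export
load_taxonomy_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          comment.char = "", check.names = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("code", "parent_code", "level", "definition", "synonyms")
  if (!all(required %in% names(df))) {
    stop("taxonomy TSV must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  taxonomy_from_table(df)
}

#' Build a taxonomy from an in-memory table
#'
#' @param df Data frame with the taxonomy TSV columns (see
#'   [load_taxonomy_table()]).
#' @return A taxonomy.
#' @export
taxonomy_from_table <- function(df) {
  if (!nrow(df)) {
    return(new_taxonomy(character(0), character(0), list(),
                        empty_placements(), character(0),
                        virtual_roots = FALSE))
  }
  code <- as.character(df$code)
  parent <- as.character(df$parent_code)
  parent[is.na(parent) | !nzchar(parent)] <- NA_character_
  level <- as.integer(df$level)
  if (anyDuplicated(code)) {
    stop("duplicate code(s): ",
         paste(unique(code[duplicated(code)]), collapse = ", "),
         call. = FALSE)
  }
  parent_idx <- match(parent, code)
  orphan <- !is.na(parent) & is.na(parent_idx)
  if (any(orphan)) {
    stop("unknown parent_code ",
         paste(unique(parent[orphan]), collapse = ", "),
         " (orphan entries: ", paste(code[orphan], collapse = ", "), ")",
         call. = FALSE)
  }
  expected <- ifelse(is.na(parent), 1L, level[parent_idx] + 1L)
  bad <- which(level != expected)
  if (length(bad)) {
    stop("declared level does not equal parent level + 1 for: ",
         paste(code[bad], collapse = ", "), call. = FALSE)
  }
  # main tree (root ancestor) per entry
  tree <- character(length(code))
  find_tree <- function(i) {
    while (!is.na(parent_idx[i])) i <- parent_idx[i]
    code[i]
  }
  for (i in seq_along(code)) tree[i] <- find_tree(i)
  syn_raw <- as.character(df$synonyms)
  syn_raw[is.na(syn_raw)] <- ""
  synonyms <- lapply(strsplit(syn_raw, "|", fixed = TRUE),
                     function(v) v[nzchar(v)])
  placements <- data.frame(
    pid = seq_along(code), code = code, parent_pid = parent_idx,
    level = level, tree = tree, stringsAsFactors = FALSE)
  new_taxonomy(code, as.character(df$definition), synonyms, placements,
               trees = sort(unique(tree[is.na(parent_idx)])),
               virtual_roots = FALSE)
}

#' Write a taxonomy to the TSV dialect
#'
#' Only single-placement taxonomies round-trip exactly; multi-placement
#' entries are written once per placement with a `#k` suffix disambiguating
#' codes, so this is mainly useful for generated fixtures.
#'
#' @param t A taxonomy (single placement per entry).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_taxonomy_table <- function(t, path) {
  p <- t$placements
  if (any(duplicated(p$code))) {
    stop("write_taxonomy_table() supports single-placement taxonomies only",
         call. = FALSE)
  }
  idx <- match(p$code, t$codes)
  df <- data.frame(
    code = p$code,
    parent_code = ifelse(is.na(p$parent_pid), "", p$code[p$parent_pid]),
    level = p$level,
    definition = t$definitions[idx],
    synonyms = vapply(t$synonyms[idx], paste, "", collapse = "|"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Structural analysis ----------------------------------------------------

#' Structural statistics of a taxonomy
#'
#' Reports the entries-per-level histogram (counted over placements, so the
#' histogram sums to the placement count), the depth, entry and placement
#' counts, definition string-length statistics and the mean synonym count.
#'
#' @param t A taxonomy.
#' @return A list of class `structure_report`.
#' @export
structure_stats <- function(t) {
  p <- t$placements
  depth <- if (nrow(p)) max(p$level) else 0L
  per_level <- integer(depth)
  if (depth > 0L) {
    tab <- table(factor(p$level, levels = seq_len(depth)))
    per_level <- as.integer(tab)
    names(per_level) <- seq_len(depth)
  }
  len <- nchar(t$definitions)
  structure(list(
    per_level = per_level,
    depth = depth,
    n_entries = length(t$codes),
    n_placements = nrow(p),
    label_length = if (length(len)) {
      c(mean = mean(len), min = min(len), max = max(len))
    } else c(mean = 0, min = 0, max = 0),
    mean_synonyms = if (length(t$synonyms)) {
      mean(lengths(t$synonyms))
    } else 0
  ), class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("entries %d  placements %d  depth %d\n",
              x$n_entries, x$n_placements, x$depth))
  cat("per level:", paste(x$per_level, collapse = " "), "\n")
  cat(sprintf("label length mean %.1f [%d, %d]; mean synonyms %.1f\n",
              x$label_length["mean"], x$label_length["min"],
              x$label_length["max"], x$mean_synonyms))
  invisible(x)
}

# BFS over the placement graph.  Returns integer distances from the node
# set `from` to every node (NA when unreachable, which cannot happen in a
# well-formed taxonomy).
tax_bfs <- function(adj, from) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    nxt <- integer(0)
    for (u in queue) {
      for (v in adj[[u]]) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          nxt <- c(nxt, v)
        }
      }
    }
    queue <- nxt
  }
  dist
}

#' Shortest-path distance between two entries
#'
#' The length of the shortest undirected path between the entries over
#' placement edges, including edges through the artificial root that joins
#' the main trees.  For multi-placement entries the minimum over all
#' placement pairs is taken; `distance(a, a)` is 0.
#'
#' @param t A taxonomy.
#' @param a,b Entry codes.
#' @return Integer path length.
#' @export
distance <- function(t, a, b) {
  tax_check_code(t, c(a, b))
  if (a == b) return(0L)
  d <- tax_bfs(t$adj, tax_placement_ids(t, a))
  min(d[tax_placement_ids(t, b)])
}

#' Pairwise distance matrix for a set of entries
#'
#' One breadth-first search per code, so profiling a corpus costs
#' O(U * graph size) for U distinct codes.
#'
#' @param t A taxonomy.
#' @param codes Character vector of entry codes.
#' @return Symmetric integer matrix with dimnames `codes`.
#' @export
distance_matrix <- function(t, codes) {
  codes <- unique(codes)
  tax_check_code(t, codes)
  m <- matrix(0L, length(codes), length(codes),
              dimnames = list(codes, codes))
  pid_sets <- lapply(codes, function(cc) tax_placement_ids(t, cc))
  for (i in seq_along(codes)) {
    d <- tax_bfs(t$adj, pid_sets[[i]])
    for (j in seq_along(codes)) {
      m[i, j] <- if (i == j) 0L else min(d[pid_sets[[j]]])
    }
  }
  m
}

# rootward chain of placement ids starting at pid (inclusive)
tax_chain <- function(t, pid) {
  chain <- pid
  while (!is.na(t$placements$parent_pid[pid])) {
    pid <- t$placements$parent_pid[pid]
    chain <- c(chain, pid)
  }
  chain
}

#' Hierarchical relationship between two entries
#'
#' Classifies the pair as one of `identical`, `parent_child`, `ancestor`
#' (root-ward path of length >= 2, never through the artificial root),
#' `sibling` (shared parent placement), `same_main_tree`, or
#' `different_tree`.  All placement pairs are examined and the closest
#' relation in that priority order is reported.
#'
#' @param t A taxonomy.
#' @param a,b Entry codes.
#' @return A single character tag.
#' @export
relationship <- function(t, a, b) {
  tax_check_code(t, c(a, b))
  if (a == b) return("identical")
  pa <- tax_placement_ids(t, a)
  pb <- tax_placement_ids(t, b)
  p <- t$placements
  tags <- character(0)
  for (i in pa) {
    chain_i <- tax_chain(t, i)
    for (j in pb) {
      chain_j <- tax_chain(t, j)
      if (!is.na(p$parent_pid[i]) && p$parent_pid[i] == j ||
          !is.na(p$parent_pid[j]) && p$parent_pid[j] == i) {
        tags <- c(tags, "parent_child")
      } else if (j %in% chain_i || i %in% chain_j) {
        tags <- c(tags, "ancestor")
      } else if (!is.na(p$parent_pid[i]) && !is.na(p$parent_pid[j]) &&
                 p$parent_pid[i] == p$parent_pid[j]) {
        tags <- c(tags, "sibling")
      } else if (p$tree[i] == p$tree[j]) {
        tags <- c(tags, "same_main_tree")
      } else {
        tags <- c(tags, "different_tree")
      }
    }
  }
  order <- c("parent_child", "ancestor", "sibling", "same_main_tree",
             "different_tree")
  order[min(match(tags, order))]
}

#' Ancestor of an entry at a given level
#'
#' Walks placement parent chains root-ward to the requested level.  For
#' multi-placement entries the set of distinct ancestor codes is returned
#' (placements shallower than `level` contribute nothing).
#'
#' @param t A taxonomy.
#' @param a Entry code.
#' @param level Target level (>= 1, <= the entry's deepest placement level).
#' @return Character vector of ancestor codes (length 1 for tree-shaped
#'   taxonomies); `ancestor_at_level(t, a, level(a))` is `a` itself.
#' @export
ancestor_at_level <- function(t, a, level) {
  tax_check_code(t, a)
  p <- t$placements
  pa <- tax_placement_ids(t, a)
  if (level < 1L || level > max(p$level[pa])) {
    stop("level ", level, " out of range for ", a,
         " (placement levels: ", paste(sort(p$level[pa]), collapse = ", "),
         ")", call. = FALSE)
  }
  out <- character(0)
  for (pid in pa) {
    if (p$level[pid] < level) next
    while (p$level[pid] > level) pid <- p$parent_pid[pid]
    out <- c(out, p$code[pid])
  }
  unique(out)
}
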