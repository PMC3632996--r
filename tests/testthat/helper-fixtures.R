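# Fixtures are built in code; nothing binary ships with the tests.

# The IPC definition chain down to A61K 38/17 (section to subgroup).
chain_table <- function() {
  data.frame(
    code = c("A", "A61", "A61K", "A61K 38/00", "A61K 38/16", "A61K 38/17"),
    parent_code = c("", "A", "A61", "A61K", "A61K 38/00", "A61K 38/16"),
    level = 1:6,
    definition = c(
      "Human necessities",
      "Medical or veterinary science; Hygiene",
      "Preparations for medical, dental or toilet purposes",
      "Medicinal preparations containing peptides",
      paste("Peptides having more than 20 amino acids; Gastrins;",
            "Somatostatins; Melanotropins; Derivatives thereof"),
      "from animals; from humans"),
    synonyms = "",
    stringsAsFactors = FALSE)
}

chain_taxonomy <- function() taxonomy_from_table(chain_table())

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

# Random single-placement forest with n entries over up to k main trees.
random_taxonomy_table <- function(n, k = 2L) {
  code <- sprintf("N%02d", seq_len(n))
  parent <- character(n)
  level <- integer(n)
  roots <- sort(sample.int(n, min(k, n)))
  roots[1] <- 1L
  for (i in seq_len(n)) {
    if (i %in% roots) {
      parent[i] <- ""
      level[i] <- 1L
    } else {
      p <- sample.int(i - 1L, 1L)
      parent[i] <- code[p]
      level[i] <- level[p] + 1L
    }
  }
  data.frame(code = code, parent_code = parent, level = level,
             definition = paste("node", code), synonyms = "",
             stringsAsFactors = FALSE)
}

# Independent shortest-path oracle over the same artificial-root graph.
igraph_distance_oracle <- function(tab) {
  edges <- c()
  for (i in seq_len(nrow(tab))) {
    other <- if (nzchar(tab$parent_code[i])) tab$parent_code[i] else "..root.."
    edges <- c(edges, tab$code[i], other)
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  d <- igraph::distances(g)
  d[tab$code, tab$code, drop = FALSE]
}

# Minimal MeSH descriptor XML built from a per-descriptor spec list:
# list(ui=, name=, trees=c(...), terms=c(...)).
write_mesh_xml <- function(descriptors, path = tempfile(fileext = ".xml")) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    gsub("<", "&lt;", s, fixed = TRUE)
  }
  rec <- vapply(descriptors, function(d) {
    trees <- paste0(
      "<TreeNumberList>",
      paste0("<TreeNumber>", d$trees, "</TreeNumber>", collapse = ""),
      "</TreeNumberList>")
    if (!length(d$trees)) trees <- ""
    terms <- paste0(
      "<ConceptList><Concept><TermList>",
      paste0("<Term><String>", esc(c(d$name, d$terms)), "</String></Term>",
             collapse = ""),
      "</TermList></Concept></ConceptList>")
    paste0("<DescriptorRecord><DescriptorUI>", d$ui, "</DescriptorUI>",
           "<DescriptorName><String>", esc(d$name), "</String></DescriptorName>",
           trees, terms, "</DescriptorRecord>")
  }, "")
  writeLines(c("<?xml version=\"1.0\"?>", "<DescriptorRecordSet>", rec,
               "</DescriptorRecordSet>"), path)
  path
}

# Toy drug ontology: sulfonylureas with five child compounds, plus a
# gene-therapy branch and a "Containment of Biohazards" trap term.
toy_drug_ontology <- function() {
  taxonomy_from_table(data.frame(
    code = c("DRUG", "SULF", "GLIB", "TOLB", "CHLO", "CARB", "ACET",
             "GT", "CONT"),
    parent_code = c("", "DRUG", "SULF", "SULF", "SULF", "SULF", "SULF",
                    "DRUG", "DRUG"),
    level = c(1L, 2L, 3L, 3L, 3L, 3L, 3L, 2L, 2L),
    definition = c("Pharmacologic Substances", "Sulfonylureas",
                   "Glibenclamide", "Tolbutamide", "Chlorpropamide",
                   "Carbutamide", "Acetohexamide", "Gene Therapy",
                   "Containment of Biohazards"),
    synonyms = c("", "", "", "", "", "", "", "", "Containment"),
    stringsAsFactors = FALSE))
}

make_annotations <- function(doc_id, classes, primary = NA_character_) {
  data.frame(doc_id = doc_id, classes = I(classes),
             primary = rep_len(primary, length(doc_id)),
             stringsAsFactors = FALSE)
}

# Small two-signature corpus that is linearly separable.
separable_docs <- function(n_per_class = 10L, classes = c("X", "Y")) {
  sig <- list(X = c("alpha", "beta", "gamma"),
              Y = c("delta", "epsilon", "zeta"))
  rows <- lapply(classes, function(cl) {
    data.frame(
      doc_id = sprintf("%s%02d", cl, seq_len(n_per_class)),
      year = 2000L,
      classes = I(as.list(rep(cl, n_per_class))),
      primary = cl,
      text = vapply(seq_len(n_per_class), function(i) {
        paste(rep(sig[[cl]], 4L), collapse = " ")
      }, ""),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
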