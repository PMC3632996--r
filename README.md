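# taxocat

Patent search relies heavily on classification codes: every patent carries
at least one code from the International Patent Classification (IPC), a
forest of roughly 70,000 alphanumeric entries (section → class → subclass →
main group → subgroup).  Compared with the way PubMed documents are indexed
with Medical Subject Headings (MeSH), patent class assignments are sparse —
fewer than two codes per document on average, almost all from a single
section — and the class definitions are long, abstract strings that almost
never occur in the patent text itself, so they cannot be recovered by
simple term extraction.  `taxocat` is a toolkit for quantifying these
properties of annotation hierarchies and for mitigating them: it assigns
additional classes to documents with per-class binary maximum-entropy
classifiers, and generates guided-search query expansions from class
co-occurrence statistics and from the class definitions themselves.

The package is aimed at text-mining researchers and patent-search tool
builders working with MeSH-like or IPC-like hierarchies; because the bulk
corpora in this domain are proprietary, it ships a seeded synthetic-data
generator that reproduces the statistical structure the pipeline assumes,
so every stage is testable end to end.

## What it computes

**Hierarchy analysis.**  A taxonomy is a forest of entries; MeSH
descriptors may occupy several tree positions (placements), IPC entries
exactly one.  An implicit artificial root joins the main trees.  For two
entries *a*, *b* the annotation distance is the length of the shortest
undirected path between them over placement edges (minimum over placement
pairs), and each co-assigned pair is classified as identical /
parent–child / ancestor / sibling / same main tree / different tree.
Per-document minimum and maximum pairwise distances and relation profiles
summarize how diverse a corpus's annotations are.

**Categorization.**  One binary maximum-entropy model per class: the
exponential-form conditional model *p(y|x) ∝ exp(Σᵢ λᵢ fᵢ(x, y))* over
bag-of-words counts, which for two labels is logistic regression on a
signed weight vector.  Weights start at 0 and are fitted by convex
maximization of the L2-penalized conditional log-likelihood (Gaussian
prior, variance 1 by default).  Negatives are drawn by round-robin
sampling — shuffle the other classes once, then take one unused document
from each in turn — so that positives and negatives stay balanced, and
evaluation uses a ratio-preserving k-fold cross-validation that splits
positives and negatives separately.  Documents are assigned classes either
by confidence threshold (θ = 0.5 default) or top-k ranking (k = 10
default), optionally filtered by historical class co-occurrence.

**Guided search.**  Class pairs are ranked by absolute co-assignment count
and by the Jaccard index of their document sets; frequently co-occurring
partners become query-expansion suggestions.  Keyword-side expansion
extracts enumerations ("… such as splints, casts or braces") from class
definitions, matches domain-ontology terms against definitions
(whole-word, longest-match-wins), and suggests unenumerated ontology
siblings; the resulting class→keyword mappings are invertible into a
keyword→class suggestion index.

## Worked example

```r
library(taxocat)

chain <- load_taxonomy_table(
  system.file("extdata", "ipc_a61k_chain.tsv", package = "taxocat"))
structure_stats(chain)
#> entries 6  placements 6  depth 6
#> per level: 1 1 1 1 1 1
#> label length mean 45.7 [17, 101]; mean synonyms 0.0
distance(chain, "A61K 38/17", "A61K 38/00")
#> [1] 2
relationship(chain, "A61K 38/16", "A61K 38/17")
#> [1] "parent_child"
ancestor_at_level(chain, "A61K 38/17", 4)
#> [1] "A61K 38/00"
```

The chain fixture is the published IPC definition path for subgroup
A61K 38/17 ("from animals; from humans"): the subgroup sits two edges
below its main group A61K 38/00 ("Medicinal preparations containing
peptides") because its true parent is A61K 38/16 — subgroup codes alone do
not encode parentage, which is why the loader requires explicit parents.

```r
cfg  <- generator_config(classes = 6, docs_per_class = 20,
                         words_per_doc = 60, background_vocab_size = 200,
                         seed = 7)
taxo <- gen_taxonomy(cfg)
sim  <- gen_corpus(cfg, taxo)
spec <- corpus_spec(docs_per_class = 20, min_text_length = 10, seed = 7)
corpus <- build_corpus(sim$documents, spec)
round(cross_validate(sim$documents, corpus, spec, folds = 5)$macro, 3)
#> precision    recall        f1
#>     0.942     0.942     0.942

ms <- train_all(sim$documents, corpus, spec)
assign_top_k(ms, sim$documents$text[1], k = 3)
#>   class      score
#> 1 A.3.4 0.98280199
#> 2 D.2.3 0.96504805
#> 3 F.4.4 0.05165883

co <- build_cooccurrence(sim$annotations)
suggest_classes(co, sim$classes[1], top = 3)
#>    kind value               source      score
#> 1 class D.2.3 cooccurrence_jaccard 0.12068966
#> 2 class F.4.4 cooccurrence_jaccard 0.08474576
#> 3 class G.1.2 cooccurrence_jaccard 0.05263158
```

The macro scores are unweighted means of per-class precision/recall/F1
from the ratio-preserving 5-fold cross-validation.  The top-k listing
shows the document's true class and its frequently co-assigned partner
scoring near 1, with all other classifiers near 0; the suggestion table
ranks co-occurrence partners of the first class by Jaccard index.

A command-line wrapper covering the same pipeline (simulate, analyze,
build-corpus, train, evaluate, assign, cooccur, expand) is installed at
`inst/cli/taxocat`; every subcommand writes TSV outputs plus a JSON echo
of its effective configuration, and identical seeds reproduce outputs
byte for byte.

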