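---
title: "Methods: hierarchy analysis, maximum-entropy categorization and guided-search expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchy analysis, maximum-entropy categorization and guided-search expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and the design
decisions behind them.  It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. Taxonomies as placement forests

Classification systems like the IPC and MeSH differ in one structural
respect that drives the whole representation: an IPC entry occupies exactly
one position in its tree, while a MeSH descriptor can carry several tree
numbers and therefore appear in several places.  `taxocat` separates
*entries* (unique codes with a definition and synonyms) from *placements*
(tree positions).  Every structural computation — levels, histograms,
distances, relationships — runs over placements; entry-level answers are
obtained by minimizing or uniting over an entry's placements.

Because the hierarchies are forests, an implicit **artificial root** joins
the main trees so that a shortest path exists between any two entries.
The root is never an entry: it cannot be queried, annotated or matched.
Each edge to a main-tree root counts 1, so the two top-level entries of
different trees are at distance 2.  For MeSH files, the main-tree roots
are the category letters (A, B, C, …), which are not descriptor records;
they are modeled as structural nodes between the artificial root and the
level-1 descriptors.  For TSV taxonomies the level-1 entries are the roots
themselves.  This keeps entry and placement counts aligned with how such
hierarchies are conventionally tabulated (unique descriptors vs tree
numbers).

Distances are computed by breadth-first search over the placement graph;
for multi-placement entries the minimum over placement pairs is taken,
which is the standard shortest-path reading (the alternative — some
aggregate over placements — has no natural metric interpretation).
`distance(a, a)` is 0 by definition even when an entry's placements are
far apart.  An independent check against a general graph library's
shortest-path routine is part of the test suite.

Pairs of co-assigned entries are classified into exactly one of six
relations, evaluated over all placement pairs and resolved in a fixed
priority order: `identical` > `parent_child` > `ancestor` (a root-ward
path of length ≥ 2 that never crosses the artificial root) > `sibling`
(shared parent placement) > `same_main_tree` > `different_tree`.  The
fixed priority makes the relation profile of a corpus a partition, so
profile bars are disjoint.  Two top-level MeSH descriptors of the same
category are *not* siblings — their shared parent is a structural node,
not a placement — but they are `same_main_tree`.

The TSV dialect (`code`, `parent_code`, `level`, `definition`,
`synonyms`) carries explicit parents deliberately: IPC subgroup codes do
not encode their own parentage (A61K 38/17 is a child of A61K 38/16, not
of A61K 38/15), so inferring hierarchy from code strings is unsound.  The
declared `level` is validated against `parent level + 1` at load time.
Definition string-length statistics are measured on the stored definition
exactly as loaded; no cross-reference stripping or reformatting is
attempted, since any such normalization would be a second, undocumented
definition of the quantity.

## 2. Annotation statistics

Annotation records map a document to a non-empty set of class codes with
an optional primary code.  Loading merges duplicate document ids by set
union (so multiple versions of a document count once), and a primary code
missing from its class set is *added* rather than rejected — downstream
analyses merge primary and secondary codes into one set anyway, so repair
preserves more information than rejection.  Codes that do not resolve in
the companion taxonomy are kept and tallied, never silently dropped;
empty class sets are rejected with their document ids reported.

Per-document minimum and maximum pairwise distances are computed for
documents with at least two resolvable annotations, via one BFS per
distinct code (so profiling costs O(U · graph) rather than O(pairs ·
graph)).  The "single-section" fraction counts every document, including
single-annotated ones; a document qualifies when one main tree contains at
least one placement of each of its classes.  Definition-occurrence is
exact substring matching after lowercasing and whitespace collapsing — no
stemming, because the quantity of interest is literal occurrence of the
definition in text, and empty definitions are guarded against matching
everything.

## 3. Features and the maximum-entropy classifier

Tokenization lowercases, splits on any non-alphanumeric character, drops
tokens shorter than two characters and tokens on a configurable stopword
list (a compact English list ships with the package).  Feature values are
raw token counts — not tf-idf, not binary — and the vocabulary is built
from training documents only and frozen; vectorizing against an unfrozen
vocabulary is an error, which acts as a train/test leak guard.  Unseen
tokens map to nothing.  A separate *reporting* filter (stopwords plus
tokens of three or fewer characters) is applied only when ranking
influential features for presentation; training keeps all length-≥2
tokens, since the shorter tokens can still carry signal.

The per-class classifier is the binary maximum-entropy model: the
exponential-form conditional distribution p(y|x) ∝ exp(Σᵢ λᵢ fᵢ(x, y)),
which with two labels reduces to logistic regression on a signed weight
vector plus bias.  Training maximizes the L2-regularized conditional
log-likelihood — a strictly convex problem with a unique optimum — with
all parameters initialized to 0 and an L-BFGS optimizer.  Numerical
choices:

* **Gaussian prior variance σ² = 1.0** on weights (bias unpenalized).
  The reference toolkits in this field default to a unit Gaussian prior;
  the value is exposed in `maxent_config()`.
* **Convergence**: gradient norm below 1e-6 or 250 iterations, both
  recorded on the model (`grad_norm`, `iterations`, `converged`).
* **Stability**: log(1 + e^η) is evaluated as max(η, 0) + log1p(e^{−|η|}),
  and a non-finite objective aborts training with an error rather than
  silently diverging.
* **Serialization**: versioned JSON with 17 significant digits, so
  reloaded models score bit-identically.

The trainer is validated against an independent ridge-regularized
logistic solver (`glmnet` with the penalty mapped as λ = 1/(nσ²),
unstandardized): scores agree to well under 1e-4 on 50-document fixtures.
The oracle is used in tests only; the shipped trainer is the package's
own.

## 4. The categorization pipeline

Corpus construction takes three filters — documents per class, minimum
text length in characters of the raw text field, and an optional
restriction to primary classification — and keeps every class for which
enough documents qualify, sampling the positives uniformly under a seed.
Negatives per class are drawn round-robin: shuffle all other classes once
(seeded), then take one unused qualifying document from each in turn,
cycling until the negative set matches the positive set size.  This keeps
any single large class from dominating the negative set.  Positive and
negative sets are always balanced (1:1).

Cross-validation is ratio-preserving: generic k-fold splitters do not
conserve the positive:negative ratio per fold, so positives and negatives
are split separately (seeded shuffle, then striping) and fold *i* pairs
the *i*-th parts of each.  The fold vocabulary is rebuilt from the
training folds only.  Macro scores are unweighted means over classes; a
class with zero predicted positives has undefined precision and its F1 is
defined as 0, the conservative standard convention.  Evaluation counts a
prediction correct only for originally assigned classes.

Two assignment modes are provided: threshold (classes with posterior
≥ θ; default θ = 0.5, the value at which F1 peaks in this family of
classifiers) and top-k (default k = 10, balancing recall against list
length; ties broken by class code so results are deterministic).  The
co-occurrence filter removes predicted classes that never historically
co-occurred with any of the document's known classes — classes never
co-assigned in a large corpus are very unlikely to describe the same
invention.  Recall can also be evaluated at a coarser hierarchy level:
a true class counts as recovered when a prediction shares its ancestor at
the chosen level (classes shallower than that level fall back to exact
matching), and only true classes with a trained model enter the
denominator — in the synthetic studies every class has a model, so this
equals plain recall there.

## 5. Guided-search expansion

Class-side: the co-occurrence table stores per-class document sets and
per-pair co-assignment counts, built from existing assignments only
(machine-added classes would contaminate the statistic that is supposed to
validate them).  Pairs are ranked by absolute count and by Jaccard index;
the *default* suggestion ranking is Jaccard, because absolute counts are
dominated by giant classes that co-occur with everything weakly.  Both
rankings are exposed, with ties broken by the other criterion and then by
code order.

Keyword-side: three extractors turn class definitions into keywords.
(1) Enumeration extraction recognizes a fixed pattern set — "*head* such
as x, y or z", "*head*, e.g. x, y, z", "*head*; x; y" — and returns the
head and trimmed members; the grammar is deliberately closed and
declared, not learned.  (2) Ontology matching finds whole-word,
case-insensitive occurrences of ontology labels and synonyms in a
definition, resolving overlaps longest-match-wins.  The whole-word rule
is intentionally stricter than fuzzy annotation pipelines: it rejects
partial-word mappings such as the word "containing" matching a shortened
synonym "Containment", a known failure mode of looser matchers.
(3) Sibling expansion: when a definition's enumeration head matches an
ontology entry and at least one member matches a child of that entry, the
remaining children are suggested — a high-precision expansion because the
definition itself establishes the correspondence.  All class→keyword
mappings are invertible into a keyword→class index, so a keyword entered
by a user can suggest classes (with definitions attached).

The feature-overlap experiment quantifies whether co-occurrence tracks
semantic relatedness: for the most frequently co-occurring class pairs,
the number of shared tokens among each classifier's top-100
report-filtered positive features is compared with the mean pairwise
overlap of a random class sample.  Correlated pairs sharing signature
vocabulary are the positive control in the synthetic setting.

## 6. The synthetic-data generator

Real corpora in this domain (bulk patent-office XML, full bibliographic
databases) are proprietary or impractically large, so the generator
emulates the statistical structure the pipeline assumes:

* a taxonomy forest with configurable sections and per-level branching;
* per-class signature vocabularies (10 words per class by default), with
  designated correlated pairs sharing half their signature words;
* documents of `words_per_doc` tokens, each token a signature word of one
  of the document's classes with probability *p* (`signature_fraction`)
  and otherwise a background word from a Zipf(1.0) distribution over a
  shared vocabulary — the Zipf tail creates the realistic shared-noise
  vocabulary that makes classification non-trivial;
* multi-labeling: a secondary class with probability `multi_label_rate`
  (default 0.5, giving roughly the low per-document class counts and
  ~50% multi-assignment share typical of patent corpora), preferring
  correlated partners;
* annotation studies with a target mean annotation count
  (1 + Poisson(mean − 1)) and a relatedness parameter giving the
  probability that a multi-annotated document draws all classes from one
  sibling family (counts are capped at the largest family so full
  relatedness is guaranteed).

Everything is bit-reproducible under a fixed configuration and seed.

**What passing tests do and do not show.**  The generator produces
exchangeable bag-of-words documents with known class-conditional
structure; it does not emulate patent prose, claim/abstract field
structure, vocabulary drift over time, or the heavy-tailed class-size
imbalance of real offices.  Recovery results on synthetic corpora
therefore validate the *machinery* — balanced training, fold hygiene,
threshold/top-k behavior, overlap statistics — not the absolute
performance to expect on real patent text.

**Study conditions.**  The default configuration (20 classes, 100
documents per class, 120-word documents, p = 0.5, background vocabulary
1000) is the package's standing evaluation condition: large enough that
cross-validation is stable, small enough that the full 10-fold study runs
in well under a minute per corpus on one CPU.  The directional
experiments (threshold sweep, top-k recall, feature overlap) use a
12-class corpus with 40 documents per class, three correlated pairs and a
weaker signal (p = 0.4) so that the threshold actually trades precision
against recall instead of saturating.  These sizes are fixed choices, not
tuned quantities; the no-signal control (p = 0) is run at the same size
as the signal condition.

## 7. Command-line interface

The `taxocat` script (installed under `inst/cli/`) is a thin wrapper over
the exported functions: subcommands for hierarchy and annotation
analysis, simulation, corpus construction, training, evaluation,
assignment, co-occurrence ranking and expansion.  Conventions: TSV with
header rows everywhere, floats printed with 6 significant digits for
stable diffs, a JSON echo of the effective configuration next to every
output, and exit codes 0 (success), 1 (data error), 2 (usage error).
Model files are versioned JSON.

## 8. Known limitations

* Multi-parent placement is supported for MeSH-style inputs only; the TSV
  dialect is single-placement by construction.
* The relation profile enumerates all annotation pairs per document, so
  documents with very many annotations cost quadratically; the distance
  profile avoids this via per-code BFS.
* The enumeration grammar is a closed pattern set; definitions that
  enumerate with other constructions ("including", dashes) are not
  recognized.
* The ontology matcher is exact at the word level — no lemmatization —
  so morphological variants of an ontology term do not match.  This is a
  deliberate precision/recall trade documented above.
* `sample_negatives` excludes only the target class's own documents from
  the negative pool; a document carrying the target class as a
  *secondary* label in a non-primary-only corpus can appear as a
  negative, mirroring the label noise inherent in one-vs-rest training on
  multi-label data.
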