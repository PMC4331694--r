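---
title: "Mixed character- and word-level CRFs for chemical name recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed character- and word-level CRFs for chemical name recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemner)
```

## The problem

Chemical compound and drug names are hard targets for named-entity
recognition because their internal structure is unlike ordinary language:
they mix Latin stems with digits, locants, Greek letters, hyphens and
brackets (`(22E,24R)-6β-methoxyergosta-7,22-diene-3β,5α-diol`), and a single
mention can span a coordinated phrase (`C35-fluoro, C35-difluoro, and
C35-trifluorosolamins`). Many names occur only once in a corpus, so a tagger
that memorizes surface forms generalizes poorly.

`chemner` addresses this with two complementary linear-chain conditional
random fields whose predictions are merged:

* a **character-level CRF** models the *internal* structure of names: each
  non-whitespace character is one sequence unit, and character n-gram
  features (orders 1-5 in a ±4 window) capture morphology such as bracketed
  stereo-prefixes and locant lists. The character model can also be trained
  on *inverted* sequences (right to left), which tends to sharpen the
  detection of name endings;
* a **word-level CRF** models the *context* of names: tokens are maximal
  Latin-letter runs plus single-character symbol tokens, with word n-gram
  features in a ±2/±3 window. Its generalization over unseen name stems
  comes from distributional word-class features (below).

## Labels

Both models tag with an 8-label scheme that segments entity and non-entity
stretches alike: `B/M/E/S` for a "normal" (non-entity) run and
`B_NER/M_NER/E_NER/S_NER` for entity segments (`S*` marks single-unit
segments). The non-entity segmentation unit is the maximal run of units
between two entities (or a sequence end and an entity); this is the only
reading under which four normal labels are meaningful. Decoded label
sequences are parsed into well-formed segments where possible; a malformed
run of entity labels (e.g. `M_NER` without `B_NER`) is repaired by treating
the maximal run as one entity, which favors recall.

## Word-class features

Two families of distributional features are supported, both trained on an
unlabeled stream of titles/abstracts:

* **Brown clusters**: agglomerative hard clustering over adjacent-bigram
  statistics. The `num_clusters` most frequent words are seeded as singleton
  clusters; each further word is inserted and the pair of clusters whose
  merge loses the least average mutual information (AMI) is merged; finally
  the surviving clusters are merged to a single root. A word's feature is
  the binary path from the root of the merge tree to its *cluster* — all
  members of a cluster share one code, so the feature generalizes across
  words with similar context distributions. (Path codes of this kind are
  sometimes loosely called Huffman codes; they are merge-tree paths, not
  frequency-optimal prefix codes.)
* **Multi-scale k-means clusters of skip-gram embeddings**: a skip-gram
  model with negative sampling (single-threaded, seeded, dynamic window)
  produces word vectors, which are clustered by k-means (k-means++ seeding,
  Lloyd iterations) independently at several scales; each scale contributes
  its own categorical feature stream, giving the tagger coarse and fine
  word classes at once.

Words seen fewer than `min_count` times are pooled into a dedicated unknown
token that is trained like any other word type, so out-of-vocabulary lookups
at prediction time return the code/ids of the cluster holding the rare
words; when no word falls below the threshold, the unknown token falls back
to the least frequent word's cluster.

## The CRF engine

The engine is a standard first-order linear-chain CRF: state features tie a
feature string to a label, transitions tie label pairs. Training maximizes
the L2-regularized conditional log-likelihood with L-BFGS from a zero start,
which makes it deterministic given the data order. Decoding returns the
Viterbi path and per-position label marginals from a scaled forward-backward
pass (per-position emission shifts keep the scaled recursions in range; the
marginal rows sum to 1 to 1e-9 or better, and both the path and the
marginals match exhaustive path enumeration on small instances — this
oracle test binds the implementation).

An entity's **confidence** is the product over its positions of the marginal
probability of the assigned label. The merge heuristic needs a per-entity
confidence; the marginal product is monotone in per-position certainty,
lies in [0, 1], and matches the per-tag marginal granularity that CRF
toolkits expose.

## Merging, filtering and bracket repair

Character- and word-model spans for one section are combined as a union with
conflict resolution:

1. identical spans collapse to one, keeping the maximum confidence;
2. a cross-model pair sharing exactly one boundary offset keeps the
   higher-confidence span if the confidence difference exceeds **0.7**
   (strict), otherwise the longer span;
3. an overlapping pair sharing no boundary keeps the higher-confidence span;
4. unopposed spans pass through.

Conflicts are resolved in descending confidence order and an eliminated span
takes no further part; ties break toward the longer, then earlier span, then
the character model, for determinism. Merged spans with confidence strictly
below **0.0001** are dropped. Finally each span is checked per bracket pair
`()`, `[]`, `{}` in that order: if it contains one unmatched opener and the
character just after the span is the matching closer, the span is extended
one character right, otherwise it is deleted (symmetrically for an unmatched
closer and the character before the span). An extended span is re-checked
against the remaining pairs; imbalances of two or more fall outside the rule
table and pass unchanged.

## Synthetic corpora

Real BioCreative-scale corpora (thousands of annotated PubMed abstracts plus
hundreds of thousands of unlabeled articles) are not shipped; the package
instead generates seeded synthetic corpora with the structural traits the
method targets, and the whole test suite runs against them.

The generator's inventories and grammar are fixed, so corpora drawn with
different seeds come from one population. Entity names are built from an
inventory of 600 chemical-like stems (onset x infix x class-suffix
enumeration) under productions that mirror the challenge cases: plain stems,
parenthesized stereo-prefixes (`(22E,24R)-...`), Greek-letter locant lists
(`...-3β,5α-diol`), bracket fusion names (`...-[5,6-e]-...`), hyphen/Cn
chains, brace variants, and coordinated multi-part names written as one
contiguous mention. Carrier sentences place entities in frames that also
admit plain nouns, so token identity (or its cluster) carries real
information; with probability `noise` (default 0.05) a sentence carries a
near-miss identifier string (`AB1234`, `(12)`) that is never annotated,
which bounds the precision a memorizing tagger can reach. The unlabeled
cluster stream samples the full stem inventory, while a small labeled corpus
exhausts only part of it — so a held-out split always contains stems unseen
in training, which is exactly the situation the cluster features address.

What the generator does *not* emulate: IUPAC validity, real PubMed topic and
length distributions, nested or discontinuous annotations, inter-annotator
noise. Passing tests therefore demonstrate that the machinery (tokenization,
labeling, inference, merging, scoring) is correct and that cluster features
deliver their generalization benefit under controlled conditions — not that
the headline scores would transfer to real corpora.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `l2` | 1.0 | L2 coefficient of the CRF penalty `l2/2 * \|\|theta\|\|^2` |
| `max_iter` | 120 | L-BFGS iterations (training F plateaus well before) |
| `brown_clusters` | 16 | Brown k for the synthetic profile (the method's original scale, 1000, suits corpora orders of magnitude larger) |
| `scales` | 5, 20, 50 | multi-scale k-means ks for toy vocabularies (scaled down from 50/1000/10000) |
| `embed_dim`, `window`, `negative`, `epochs` | 50/100, 5, 5, 5 | skip-gram defaults |
| `min_count` | 2 | rare-word pooling threshold |
| `confidence_diff_threshold` | 0.7 | merge rule 2, strict comparison |
| `min_confidence` | 0.0001 | confidence floor, strict comparison |

## Numerical and design choices

* **Tokenizer**: "alphabetic" means Latin-script letters; Greek letters,
  digits and all punctuation are single-character symbol tokens. Offsets are
  0-based, half-open, in Unicode code points; title and abstract offset
  spaces are independent. Whitespace produces no unit at either granularity,
  so a character model never labels a space; span offsets still address the
  original text exactly. Sections are not sentence-split by default (a naive
  splitter is available via `sentence_starts()`): a splitter can never cut
  through a multi-phrase entity that way.
* **Direction inversion** reverses unit order and unit surfaces but keeps
  each unit's original offsets, so decoded spans map back by construction;
  label sequences mirror by reversing and swapping `B`/`E` within each
  family.
* **Feature tables**: the character 4-gram row is implemented as the
  symmetric completion (`W_{i-3}^{i}, W_{i-2}^{i+1}, W_{i-1}^{i+2},
  W_i^{i+3}`); the word "3-gram" row is implemented exactly as its spans
  read, i.e. 4-token windows. Boundary positions substitute distinct
  sentinels `_B-k`/`_E+k`, so template arity is constant.
* **Brown determinism and optimality**: merges tie-break on the smallest
  cluster-id pair (cluster id = smallest member word id), and word frequency
  ties break lexicographically. The greedy insert-and-merge procedure is not
  globally optimal in general: on block corpora with unbalanced class sizes
  it can commit to an early merge it cannot undo (an independent
  re-implementation of the same procedure reproduces the identical
  partition, so this is a property of the algorithm, not of the code). On
  class-balanced block corpora it recovers the exhaustive-search maximum-AMI
  partition, which is what the oracle tests pin down.
* **k-means** at `k = 1` and `k = vocabulary size` short-circuits to the
  exact optimum; otherwise k-means++ seeding avoids empty clusters and a
  fixed seed makes assignments reproducible.
* **Degenerate scoring**: precision is 0 when nothing was predicted against
  non-empty gold; the empty-vs-empty corpus scores 1 everywhere, making it a
  fixed point. CDI string matching is case-sensitive by default (a
  `casefold` flag exists).

## Problem sizes used by the checks

The end-to-end study trains on 500 generated documents, evaluates on a
held-out 100 (noise 0.05), with 6,000 unlabeled sentences for cluster
training and Brown k = 16; the cluster-feature recall comparison runs ten
seeds at 100 training / 60 test documents with the word model only. These
sizes are the package's test profile for the synthetic population; all of
them are ordinary function arguments, so larger studies are a matter of
changing numbers.

## Known limitations

* Nested and discontinuous entities are out of scope; a coordinated mention
  is handled only as the contiguous span the gold provides.
* The merge heuristic is pairwise and greedy; a global assignment could in
  principle differ.
* Entity confidence as a marginal product penalizes long entities; ranking
  across lengths inherits that bias.
* The skip-gram trainer is deliberately minimal (no subsampling, no
  hierarchical softmax); it is a feature generator, not a general-purpose
  embedding library.
* Brown clustering is O(V·k^3) per the windowed procedure here and is meant
  for vocabularies of a few thousand words at the package's scales.
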