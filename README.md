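# chemner

Chemical compound and drug name recognition in titles and abstracts, with
**mixed character- and word-level conditional random fields** and
**distributional word-class features**.

Chemical names defeat ordinary taggers: they mix Latin stems with digits,
Greek letters, hyphens and brackets
(`(22E,24R)-6β-methoxyergosta-7,22-diene-3β,5α-diol`), and many occur only
once in a corpus. `chemner` is for text-mining practitioners who need
mention-level chemical NER (and per-document chemical indexing) from
BioCreative-style corpora, and for anyone studying the mixed-CRF +
word-clustering recipe itself.

## The method

Two linear-chain CRFs are trained over an 8-label scheme
(`B/M/E/S` for non-entity runs, `B_NER/M_NER/E_NER/S_NER` for entities):

* a **character-level CRF** (units = non-whitespace characters; features =
  character n-grams of orders 1–5 in a ±4 window) models the internal
  morphology of names, optionally trained right-to-left on inverted
  sequences;
* a **word-level CRF** (units = Latin-letter runs plus single symbol
  tokens; features = word n-grams in a ±2/±3 window) models context, plus
  word-class feature streams: **Brown clusters** (binary merge-tree path
  codes; all words of a cluster share one code) and/or **multi-scale
  k-means clusters of skip-gram embeddings**.

For a label path *y* over units *x*, each CRF models
`p(y|x) ∝ exp( Σᵢ Σ_f∈F(x,i) w_{f,yᵢ} + Σᵢ t_{yᵢ,yᵢ₊₁} )`,
trained by L2-regularized maximum likelihood (L-BFGS) and decoded by
Viterbi with forward–backward marginals. An entity's confidence is the
product of its positions' marginal probabilities.

The two models' spans are then **merged**: identical spans collapse (max
confidence); a pair sharing exactly one boundary keeps the more confident
span if the confidence gap exceeds 0.7, else the longer one; other overlaps
keep the more confident span; everything unopposed passes through. Spans
below confidence 0.0001 are dropped, and bracket-imbalanced spans are
repaired by one-character extension toward a matching neighbor bracket or
deleted.

Because the original BioCreative corpora and PubMed-scale cluster text are
not redistributable here, the package ships a seeded **synthetic corpus
generator** that reproduces the structural challenges (stereo-prefixes,
locant lists, bracket fusions, coordinated mentions, near-miss identifier
noise); the whole test suite and the acceptance script run on it.

## Worked example

```r
library(chemner)

# 1. a seeded synthetic corpus: 200 training and 50 held-out documents
train <- generate_corpus(synth_config(seed = 1, n_docs = 200))
test  <- generate_corpus(synth_config(seed = 2, n_docs = 50))
ctext <- generate_cluster_text(synth_config(seed = 1), 4000)

head(train$gold[, c("doc_id", "section", "start", "end", "text")], 3)
#>     doc_id section start end                          text
#> 1 SYN00001       T     0  28  chlorazone-{24,15}-propazate
#> 2 SYN00002       T    11  35      chlorinone-35β,26β-dione
#> 3 SYN00002       A    40  69 chlorazine-[24,7-e]-methinene

# 2. train the mixed system: inverted char CRF + word CRF with Brown clusters
model <- train_chemner(train$docs, train$gold,
                       char_direction = "INVERTED",
                       cluster_mode = "BROWN", cluster_text = ctext,
                       seed = 1)
model
#> <chemner_model: char(INVERTED) + word(BROWN) >

# 3. predict and score
pred <- predict_chemner(model, test$docs)
head(pred[, c("doc_id", "section", "start", "end", "text", "confidence")], 3)
#>     doc_id section start end             text confidence
#> 1 SYN00001       T     0  16 (7Z,9E)-hexylone  0.9617262
#> 2 SYN00001       A    14  26     chlorolamine  0.9964938
#> 3 SYN00001       A    63  76    C9-butinoxide  0.9835832

evaluate_cem(test$gold, pred)   # exact-offset mention matching
#> CEM: TP=135 FP=1 FN=0
#>   precision 0.99265  recall 1.00000  F-score 0.99631
evaluate_cdi(test$gold, pred)   # unique mention strings per document
#> CDI: TP=135 FP=1 FN=0
#>   precision 0.99265  recall 1.00000  F-score 0.99631
```

The predicted spans carry exact character offsets into each section
(0-based, half-open), a confidence in [0, 1], and survive merge, filter and
bracket repair. `write_predictions()` emits the CEM (`doc  T|A:start:end
rank  conf`) and CDI (`doc  mention  rank  conf`) submission formats;
`read_abstracts()` / `read_annotations()` read the tab-separated corpus
dialects.

A command-line front end with `synth`, `tokenize`, `cluster`, `train`,
`tag`, `evaluate` and `run-all` subcommands is installed at
`system.file("cli", "chemner.R", package = "chemner")`.

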