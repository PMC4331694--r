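Package: chemner
Title: Chemical Named Entity Recognition with Mixed Character- and
    Word-Level Conditional Random Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes chemical compound and drug names in titles and
    abstracts of scientific articles. Trains linear-chain conditional
    random fields at two granularities - a character-level tagger that
    models the internal structure of chemical names (digits, brackets,
    Greek letters, locants) and a word-level tagger that models their
    context - and merges the two predictions with a confidence heuristic
    followed by bracket-balance repair. Word-level generalization comes
    from distributional word-class features: Brown clustering with binary
    merge-tree path codes and multi-scale k-means clustering of skip-gram
    embeddings. Includes readers and writers for BioCreative-style
    stand-off corpora, mention-level (CEM) and document-indexing (CDI)
    scoring, and a seedable generator of synthetic annotated corpora for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
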