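# Seedable generator of synthetic annotated corpora and unlabeled cluster
# text with the structural traits of chemical-name recognition: generated
# names mix Latin stems with digits, Greek letters, hyphens and all three
# bracket pairs; gold offsets are exact by construction; near-miss identifier
# strings (never annotated) bound the precision a memorizing tagger can
# reach; and the stem inventory is larger than a small corpus exhausts, so a
# held-out split always contains stems unseen in training - the situation
# word-cluster features are meant to help with.
#
# The word inventories and the grammar are fixed (not drawn from the seed),
# so corpora generated with different seeds share one population.

.syn_onsets <- c("meth", "eth", "prop", "but", "pent", "hex", "benz", "chlor",
                 "fluor", "brom", "amin", "oxy", "hydro", "cycl", "phen",
                 "acet", "sulf", "nitr", "carb", "thi")
.syn_mids <- c("an", "en", "ox", "yl", "in", "ur", "ol", "az")
.syn_suffixes <- c("ol", "ine", "ate", "ide", "one", "amine", "oxide", "ene")

# deterministic enumeration: suffix varies fastest, then mid, then onset
.syn_stems <- function(pool_size = 600L) {
  stems <- as.vector(t(outer(.syn_onsets,
                             as.vector(t(outer(.syn_mids, .syn_suffixes, paste0))),
                             paste0)))
  stems[seq_len(min(pool_size, length(stems)))]
}

.syn_nouns <- c("cells", "patients", "tissue", "plasma", "mice", "rats",
                "tumor", "liver", "serum", "brain", "protein", "enzyme",
                "receptor", "membrane", "pathway", "gene", "expression",
                "activity", "growth", "response", "levels", "samples",
                "cultures", "assays", "dose", "treatment", "therapy",
                "infection", "kinase", "channel")
.syn_verbs <- c("induced", "inhibited", "reduced", "increased", "modulated",
                "suppressed", "enhanced", "blocked", "activated", "attenuated")

# sentence templates; <E> entity slot, <N> noun, <V> verb, <X> near-miss.
# Several frames admit both <E> and <N> in the same slot, so token identity
# (or its cluster) carries real information there.
.syn_ent_templates <- list(
  c("treatment", "with", "<E>", "<V>", "<N>", "<N>", "in", "<N>"),
  c("the", "effect", "of", "<E>", "on", "<N>", "was", "studied"),
  c("we", "examined", "<E>", "in", "<N>", "and", "<N>"),
  c("<E>", "<V>", "the", "<N>", "of", "<N>"),
  c("exposure", "to", "<E>", "<V>", "<N>", "levels"),
  c("binding", "of", "<E>", "to", "the", "<N>", "<N>"),
  c("synthesis", "of", "<E>", "was", "performed"),
  c("<E>", "is", "a", "potent", "<N>", "inhibitor"))
.syn_noun_templates <- list(
  c("the", "effect", "of", "<N>", "on", "<N>", "was", "studied"),
  c("we", "examined", "<N>", "in", "<N>", "and", "<N>"),
  c("the", "<N>", "of", "<N>", "was", "<V>", "by", "<N>"),
  c("<N>", "<V>", "the", "<N>", "of", "<N>"),
  c("treatment", "with", "<N>", "was", "compared", "across", "<N>"),
  c("results", "showed", "significant", "<N>", "<N>", "changes"))
.syn_noise_templates <- list(
  c("as", "listed", "in", "sample", "<X>", "and", "<N>", "records"),
  c("see", "<X>", "for", "<N>", "details"),
  c("data", "for", "batch", "<X>", "were", "excluded"))
.syn_title_ent_templates <- list(
  c("effects", "of", "<E>", "on", "<N>", "<N>"),
  c("<E>", "and", "<N>", "<N>", "in", "<N>"),
  c("<E>", "modulates", "<N>", "<N>"))
.syn_title_noun_templates <- list(
  c("the", "role", "of", "<N>", "<N>", "in", "<N>"),
  c("<N>", "<N>", "in", "<N>", "and", "<N>"))

#' Configuration for the synthetic corpus generator
#'
#' @param seed integer seed; the same config yields a byte-identical corpus.
#' @param n_docs number of documents.
#' @param noise probability that an abstract sentence carries a near-miss
#'   identifier string (entity-like, never annotated).
#' @param stem_pool_size number of distinct chemical stems in the inventory.
#' @param p_title_entity probability the title contains an entity.
#' @param abstract_sentences integer range (min, max) of abstract sentences.
#' @param p_entity_sentence probability an abstract sentence carries an
#'   entity.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_docs = 100L, noise = 0.05,
                         stem_pool_size = 600L, p_title_entity = 0.6,
                         abstract_sentences = c(2L, 4L),
                         p_entity_sentence = 0.65) {
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 noise = noise, stem_pool_size = as.integer(stem_pool_size),
                 p_title_entity = p_title_entity,
                 abstract_sentences = as.integer(abstract_sentences),
                 p_entity_sentence = p_entity_sentence),
            class = "synth_config")
}

# one generated chemical-like name (string); stems drawn from `stems`
.gen_entity <- function(stems) {
  stem <- function() sample(stems, 1L)
  d <- function() as.character(sample(2:35, 1L))
  sl <- function() sample(c("E", "R", "S", "Z"), 1L)
  gk <- function() sample(c("α", "β"), 1L)  # alpha, beta
  kind <- sample(c("plain", "stereo", "locant", "fusion", "chain", "brace",
                   "greek", "coordinate"),
                 1L, prob = c(0.35, 0.15, 0.15, 0.10, 0.12, 0.05, 0.03, 0.05))
  switch(kind,
    plain = stem(),
    stereo = paste0("(", d(), sl(), ",", d(), sl(), ")-", stem()),
    locant = paste0(stem(), "-", d(), gk(), ",", d(), gk(), "-",
                    sample(c("diol", "diene", "dione", "triol"), 1L)),
    fusion = paste0(stem(), "-[", d(), ",", d(), "-",
                    sample(c("e", "f", "g"), 1L), "]-", stem()),
    chain = if (stats::runif(1) < 0.5) paste0("C", d(), "-", stem())
            else paste0(stem(), "-", d(), "-", stem()),
    brace = paste0(stem(), "-{", d(), ",", d(), "}-", stem()),
    greek = paste0(gk(), "-(", d(), ",", d(), "-", stem(), ")", stem()),
    coordinate = {
      base <- d()
      paste0("C", base, "-fluoro, C", base, "-difluoro, and C", base,
             "-trifluoro", stem())
    })
}

.gen_near_miss <- function() {
  kind <- sample(c("code", "ref"), 1L)
  if (kind == "code") {
    paste0(paste(sample(LETTERS, 2L, replace = TRUE), collapse = ""),
           sample(100:9999, 1L))
  } else paste0("(", sample(10:99, 1L), ")")
}

# realize a template into (text, entity start/end offsets relative to the
# sentence); offsets are 0-based half-open character positions
.realize <- function(template, stems) {
  words <- character(length(template))
  ent_idx <- integer()
  for (i in seq_along(template)) {
    words[i] <- switch(template[i],
      "<E>" = { ent_idx <- c(ent_idx, i); .gen_entity(stems) },
      "<N>" = sample(.syn_nouns, 1L),
      "<V>" = sample(.syn_verbs, 1L),
      "<X>" = .gen_near_miss(),
      template[i])
  }
  starts <- cumsum(c(0L, nchar(words[-length(words)]) + 1L))
  list(text = paste(words, collapse = " "),
       ent_start = starts[ent_idx],
       ent_end = starts[ent_idx] + nchar(words[ent_idx]))
}

#' Generate a synthetic annotated corpus
#'
#' Documents (title + abstract) with embedded generated chemical-like names
#' and exact gold offsets. Deterministic per config. With `noise = 0`, every
#' generated name is annotated, so a recall of 1 is attainable; with
#' `noise > 0`, near-miss identifier strings appear that are never annotated.
#'
#' @param cfg a [synth_config()].
#' @return list with `docs` (document table) and `gold` (entity spans,
#'   `source = "GOLD"`).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  stems <- .syn_stems(cfg$stem_pool_size)
  with_seed(cfg$seed, {
    docs <- vector("list", cfg$n_docs)
    gold <- vector("list", cfg$n_docs)
    for (di in seq_len(cfg$n_docs)) {
      doc_id <- sprintf("SYN%05d", di)
      spans <- list()
      # title
      t_templates <- if (stats::runif(1) < cfg$p_title_entity)
        .syn_title_ent_templates else .syn_title_noun_templates
      tt <- .realize(t_templates[[sample(length(t_templates), 1L)]], stems)
      title <- tt$text
      for (k in seq_along(tt$ent_start)) {
        spans[[length(spans) + 1L]] <- data.frame(
          section = "T", start = tt$ent_start[k], end = tt$ent_end[k],
          stringsAsFactors = FALSE)
      }
      # abstract
      n_sent <- sample(cfg$abstract_sentences[1L]:cfg$abstract_sentences[2L], 1L)
      sents <- character(n_sent)
      cursor <- 0L
      for (si in seq_len(n_sent)) {
        u <- stats::runif(1)
        tset <- if (u < cfg$noise) .syn_noise_templates
        else if (u < cfg$noise + cfg$p_entity_sentence) .syn_ent_templates
        else .syn_noun_templates
        st <- .realize(tset[[sample(length(tset), 1L)]], stems)
        sent <- paste0(st$text, " .")
        for (k in seq_along(st$ent_start)) {
          spans[[length(spans) + 1L]] <- data.frame(
            section = "A", start = cursor + st$ent_start[k],
            end = cursor + st$ent_end[k], stringsAsFactors = FALSE)
        }
        sents[si] <- sent
        cursor <- cursor + nchar(sent) + 1L  # sentences joined by one space
      }
      abstract <- paste(sents, collapse = " ")
      docs[[di]] <- data.frame(doc_id = doc_id, title = title,
                               abstract = abstract, stringsAsFactors = FALSE)
      if (length(spans)) {
        sp <- do.call(rbind, spans)
        sp$doc_id <- doc_id
        gold[[di]] <- sp
      }
    }
    docs <- do.call(rbind, docs)
    gold <- do.call(rbind, gold[!vapply(gold, is.null, logical(1L))])
    text <- vapply(seq_len(nrow(gold)), function(i) {
      .substr0(section_text(docs, gold$doc_id[i], gold$section[i]),
               gold$start[i], gold$end[i])
    }, character(1L))
    gold <- entity_spans(doc_id = gold$doc_id, section = gold$section,
                         start = gold$start, end = gold$end, text = text,
                         confidence = 1, source = "GOLD")
    list(docs = docs, gold = gold)
  })
}

#' Generate unlabeled text for cluster training
#'
#' Carrier sentences over the same inventories as [generate_corpus()], with
#' a high share of entity-context sentences using plain stems so that stems
#' of the same family share contexts and cluster together; the full stem
#' inventory is sampled, so words unseen in a small labeled corpus still
#' receive cluster features.
#'
#' @param cfg a [synth_config()] (its `seed` is offset internally so cluster
#'   text differs from the labeled corpus drawn with the same seed).
#' @param n_sentences number of sentences to emit.
#' @return character vector of `n_sentences` sentence strings.
#' @export
generate_cluster_text <- function(cfg, n_sentences) {
  stopifnot(inherits(cfg, "synth_config"))
  stems <- .syn_stems(cfg$stem_pool_size)
  with_seed(cfg$seed + 1000003L, {
    vapply(seq_len(n_sentences), function(i) {
      if (stats::runif(1) < 0.7) {
        tpl <- .syn_ent_templates[[sample(length(.syn_ent_templates), 1L)]]
        # plain stems dominate here: the point is stem/context co-occurrence
        tpl[tpl == "<E>"] <- sample(stems, sum(tpl == "<E>"), replace = TRUE)
      } else {
        tpl <- .syn_noun_templates[[sample(length(.syn_noun_templates), 1L)]]
      }
      tpl[tpl == "<N>"] <- sample(.syn_nouns, sum(tpl == "<N>"), replace = TRUE)
      tpl[tpl == "<V>"] <- sample(.syn_verbs, sum(tpl == "<V>"), replace = TRUE)
      paste(tpl, collapse = " ")
    }, character(1L))
  })
}
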