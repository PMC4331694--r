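# End-to-end orchestration: train the character-level and/or word-level CRF
# (optionally on inverted character sequences, optionally with Brown or
# multi-scale cluster features), decode both, merge, filter, repair brackets,
# and write CDI/CEM outputs.

#' Mirror a label sequence for direction inversion
#'
#' Reversing a sequence turns segment beginnings into ends, so the label
#' vector of the reversed sequence is the reversed vector with B and E (and
#' B_NER / E_NER) swapped. Applying it twice is the identity.
#'
#' @param labels character vector over [crf_labels()].
#' @return mirrored label vector.
#' @export
invert_labels <- function(labels) {
  swap <- c(B = "E", E = "B", M = "M", S = "S",
            B_NER = "E_NER", E_NER = "B_NER", M_NER = "M_NER", S_NER = "S_NER")
  unname(rev(swap[labels]))
}

# the two sequences (title, abstract) of one document
.doc_sequences <- function(docs, i, granularity) {
  f <- if (granularity == "CHAR") tokenize_chars else tokenize_words
  list(f(docs$title[i], docs$doc_id[i], "T"),
       f(docs$abstract[i], docs$doc_id[i], "A"))
}

# training data (features + labels) for one model configuration
.build_training <- function(docs, gold, granularity, direction = "FORWARD",
                            clusters = NULL, cluster_mode = "NONE") {
  data <- list()
  for (i in seq_len(nrow(docs))) {
    for (seq in .doc_sequences(docs, i, granularity)) {
      if (!length(seq$surface)) next
      labels <- spans_to_labels(seq, gold)
      if (granularity == "CHAR") {
        if (direction == "INVERTED") {
          seq <- invert(seq)
          labels <- invert_labels(labels)
        }
        fm <- char_features(seq)
      } else {
        fm <- word_features(seq, clusters, cluster_mode)
      }
      data[[length(data) + 1L]] <- list(features = fm, labels = labels)
    }
  }
  data
}

#' Train the mixed chemical-name recognizer
#'
#' Trains the enabled models on an annotated corpus: a character-level CRF
#' (forward or on inverted sequences) and/or a word-level CRF with optional
#' cluster features. Cluster models are trained from `cluster_text` when not
#' supplied ready-made.
#'
#' @param docs document table.
#' @param gold gold entity spans.
#' @param char_enabled,word_enabled which models to train (at least one).
#' @param char_direction `"FORWARD"` or `"INVERTED"`.
#' @param cluster_mode `"NONE"`, `"BROWN"` or `"MULTISCALE"` (word model).
#' @param cluster_model optional pre-trained [cluster_model]; otherwise
#'   trained here from `cluster_text`.
#' @param cluster_text character vector of unlabeled sentences for cluster
#'   training (required if `cluster_mode != "NONE"` and no `cluster_model`).
#' @param brown_clusters number of Brown clusters.
#' @param scales k-means scales for `"MULTISCALE"`.
#' @param embed_dim,embed_window,embed_epochs skip-gram parameters.
#' @param min_count rare-word pooling threshold for cluster training.
#' @param l2,max_iter CRF training parameters.
#' @param seed integer seed for every stochastic step.
#' @return a `chemner_model`.
#' @export
train_chemner <- function(docs, gold,
                          char_enabled = TRUE,
                          char_direction = c("FORWARD", "INVERTED"),
                          word_enabled = TRUE,
                          cluster_mode = c("BROWN", "NONE", "MULTISCALE"),
                          cluster_model = NULL, cluster_text = NULL,
                          brown_clusters = 16L, scales = c(5L, 20L, 50L),
                          embed_dim = 50L, embed_window = 5L,
                          embed_epochs = 5L, min_count = 2L,
                          l2 = 1.0, max_iter = 120L, seed = 1L) {
  char_direction <- match.arg(char_direction)
  cluster_mode <- match.arg(cluster_mode)
  if (!char_enabled && !word_enabled) stop("at least one model must be enabled")
  if (word_enabled && cluster_mode != "NONE" && is.null(cluster_model)) {
    if (is.null(cluster_text)) {
      stop("cluster_mode ", cluster_mode,
           " needs cluster_text or a pre-trained cluster_model")
    }
    cluster_model <- if (cluster_mode == "BROWN") {
      train_brown(cluster_text, brown_clusters, min_count = min_count)
    } else {
      emb <- train_embeddings(cluster_text, dimension = embed_dim,
                              window = embed_window, epochs = embed_epochs,
                              min_count = min_count, seed = seed)
      kmeans_multiscale(emb, scales, seed = seed)
    }
  }
  char_model <- NULL
  word_model <- NULL
  if (char_enabled) {
    data <- .build_training(docs, gold, "CHAR", direction = char_direction)
    char_model <- train_crf(data, l2 = l2, max_iter = max_iter, seed = seed,
                            meta = list(granularity = "CHAR",
                                        direction = char_direction))
  }
  if (word_enabled) {
    data <- .build_training(docs, gold, "WORD", clusters = cluster_model,
                            cluster_mode = cluster_mode)
    word_model <- train_crf(data, l2 = l2, max_iter = max_iter, seed = seed,
                            meta = list(granularity = "WORD",
                                        direction = "FORWARD",
                                        cluster_mode = cluster_mode))
  }
  structure(list(char_model = char_model, word_model = word_model,
                 cluster_model = cluster_model,
                 char_direction = char_direction, cluster_mode = cluster_mode,
                 seed = seed),
            class = "chemner_model")
}

#' @export
print.chemner_model <- function(x, ...) {
  cat("<chemner_model:",
      paste(c(if (!is.null(x$char_model)) paste0("char(", x$char_direction, ")"),
              if (!is.null(x$word_model)) paste0("word(", x$cluster_mode, ")")),
            collapse = " + "),
      ">\n")
  invisible(x)
}

# reorder a decoding of an inverted sequence back to forward orientation
.uninvert_decoding <- function(labels, marginals) {
  labels <- invert_labels(labels)
  m <- marginals[rev(seq_len(nrow(marginals))), , drop = FALSE]
  swapped <- m
  swapped[, "B"] <- m[, "E"]; swapped[, "E"] <- m[, "B"]
  swapped[, "B_NER"] <- m[, "E_NER"]; swapped[, "E_NER"] <- m[, "B_NER"]
  list(labels = labels, marginals = swapped)
}

# decode one model over one document section; returns entity spans
.decode_section <- function(model, seq, clusters, cluster_mode, source) {
  if (!length(seq$surface)) return(entity_spans())
  if (model$meta$granularity == "CHAR") {
    if (identical(model$meta$direction, "INVERTED")) {
      dec <- decode_crf(model, char_features(invert(seq)))
      fwd <- .uninvert_decoding(dec$labels, dec$marginals)
      return(labels_to_spans(seq, fwd$labels, fwd$marginals, source = source))
    }
    dec <- decode_crf(model, char_features(seq))
    return(labels_to_spans(seq, dec$labels, dec$marginals, source = source))
  }
  dec <- decode_crf(model, word_features(seq, clusters, cluster_mode))
  labels_to_spans(seq, dec$labels, dec$marginals, source = source)
}

#' Predict chemical-name mentions
#'
#' Tokenizes each document section, decodes every enabled model, maps
#' inverted-direction output back to forward orientation, merges the two
#' models' spans, drops low-confidence spans, and repairs bracket imbalance.
#' With a single enabled model the merge step is the identity on that
#' model's spans.
#'
#' @param model a `chemner_model`.
#' @param docs document table.
#' @param policy a [merge_policy()].
#' @return entity-span data.frame with `source = "MERGED"`.
#' @export
predict_chemner <- function(model, docs, policy = merge_policy()) {
  stopifnot(inherits(model, "chemner_model"))
  char_all <- list()
  word_all <- list()
  for (i in seq_len(nrow(docs))) {
    if (!is.null(model$char_model)) {
      for (seq in .doc_sequences(docs, i, "CHAR")) {
        char_all[[length(char_all) + 1L]] <-
          .decode_section(model$char_model, seq, NULL, NULL, "CHAR_MODEL")
      }
    }
    if (!is.null(model$word_model)) {
      for (seq in .doc_sequences(docs, i, "WORD")) {
        word_all[[length(word_all) + 1L]] <-
          .decode_section(model$word_model, seq, model$cluster_model,
                          model$cluster_mode, "WORD_MODEL")
      }
    }
  }
  char_spans <- if (length(char_all)) do.call(rbind, char_all) else entity_spans()
  word_spans <- if (length(word_all)) do.call(rbind, word_all) else entity_spans()
  merged <- if (!is.null(model$char_model) && !is.null(model$word_model)) {
    merge_spans(char_spans, word_spans, policy)
  } else {
    single <- if (nrow(char_spans)) char_spans else word_spans
    if (nrow(single)) single$source <- "MERGED"
    single
  }
  merged <- filter_confidence(merged, policy)
  adjust_all_brackets(merged, docs, policy)
}

#' Save a trained recognizer to a directory
#'
#' Writes each trained model as plain text plus a manifest of configuration
#' and file checksums.
#'
#' @param model a `chemner_model`.
#' @param model_dir output directory (created if absent).
#' @export
save_chemner <- function(model, model_dir) {
  dir.create(model_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (!is.null(model$char_model)) {
    write_crf_model(model$char_model, file.path(model_dir, "char.crf"))
    files <- c(files, "char.crf")
  }
  if (!is.null(model$word_model)) {
    write_crf_model(model$word_model, file.path(model_dir, "word.crf"))
    files <- c(files, "word.crf")
  }
  if (!is.null(model$cluster_model)) {
    write_cluster_model(model$cluster_model, file.path(model_dir, "clusters.txt"))
    files <- c(files, "clusters.txt")
  }
  sums <- tools::md5sum(file.path(model_dir, files))
  manifest <- c(paste("char_direction", model$char_direction),
                paste("cluster_mode", model$cluster_mode),
                paste("seed", model$seed),
                paste("checksum", files, unname(sums)))
  writeLines(manifest, file.path(model_dir, "manifest.txt"))
  invisible(model_dir)
}

#' Load a recognizer saved by [save_chemner()]
#' @param model_dir directory written by [save_chemner()].
#' @return a `chemner_model`.
#' @export
load_chemner <- function(model_dir) {
  manifest <- readLines(file.path(model_dir, "manifest.txt"))
  get_field <- function(key) {
    sub(paste0("^", key, " "), "", grep(paste0("^", key, " "), manifest, value = TRUE))
  }
  checks <- strsplit(grep("^checksum ", manifest, value = TRUE), " ", fixed = TRUE)
  for (ck in checks) {
    f <- file.path(model_dir, ck[2L])
    if (!file.exists(f)) stop("missing model file: ", ck[2L])
    if (!identical(unname(tools::md5sum(f)), ck[3L])) {
      stop("checksum mismatch for ", ck[2L], ": model directory was modified")
    }
  }
  has <- function(f) file.exists(file.path(model_dir, f))
  structure(list(
    char_model = if (has("char.crf")) read_crf_model(file.path(model_dir, "char.crf")),
    word_model = if (has("word.crf")) read_crf_model(file.path(model_dir, "word.crf")),
    cluster_model = if (has("clusters.txt"))
      read_cluster_model(file.path(model_dir, "clusters.txt")),
    char_direction = get_field("char_direction"),
    cluster_mode = get_field("cluster_mode"),
    seed = as.integer(get_field("seed"))),
    class = "chemner_model")
}

#' Train from corpus files and save the models
#'
#' File-level wrapper over [train_chemner()] and [save_chemner()].
#'
#' @param corpus_path abstracts file (see [read_abstracts()]).
#' @param annotations_path stand-off annotation file.
#' @param model_dir output directory.
#' @param cluster_text_path optional file of unlabeled sentences.
#' @param ... passed to [train_chemner()].
#' @return the trained `chemner_model`, invisibly.
#' @export
run_train <- function(corpus_path, annotations_path, model_dir,
                      cluster_text_path = NULL, ...) {
  for (p in c(corpus_path, annotations_path, cluster_text_path)) {
    if (!file.exists(p)) stop("missing input: ", p)
  }
  docs <- read_abstracts(corpus_path)
  gold <- read_annotations(annotations_path, docs)
  cluster_text <- if (!is.null(cluster_text_path)) {
    readLines(cluster_text_path, encoding = "UTF-8", warn = FALSE)
  }
  model <- train_chemner(docs, gold, cluster_text = cluster_text, ...)
  save_chemner(model, model_dir)
  invisible(model)
}

#' Predict from corpus files and write CDI/CEM outputs
#'
#' @param model_dir directory written by [save_chemner()].
#' @param corpus_path abstracts file to tag.
#' @param out_dir output directory for `predictions.cdi` / `predictions.cem`.
#' @param policy a [merge_policy()].
#' @return the predicted spans, invisibly.
#' @export
run_predict <- function(model_dir, corpus_path, out_dir,
                        policy = merge_policy()) {
  model <- load_chemner(model_dir)
  docs <- read_abstracts(corpus_path)
  spans <- predict_chemner(model, docs, policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_predictions(spans, "CDI", file.path(out_dir, "predictions.cdi"))
  write_predictions(spans, "CEM", file.path(out_dir, "predictions.cem"))
  invisible(spans)
}
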