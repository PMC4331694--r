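# Distributional word-class features: Brown clustering with merge-tree path
# codes, and k-means clustering of skip-gram embeddings at several scales.
#
# Both models share the `cluster_model` container. Words below the count
# threshold are pooled into a dedicated unknown token that is trained like any
# other word type, so out-of-vocabulary lookups at feature-extraction time
# return the code/ids of the cluster that holds the rare words.

#' @useDynLib chemner, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

# normalize a corpus argument: character vector of raw lines (tokenized here
# with tokenize_words) or a list of already-tokenized character vectors
.as_token_stream <- function(corpus) {
  if (is.character(corpus)) {
    lapply(corpus, function(x) tokenize_words(x)$surface)
  } else if (is.list(corpus)) {
    lapply(corpus, as.character)
  } else stop("corpus must be a character vector of lines or a list of token vectors")
}

# frequency-ranked vocabulary with rare words pooled into unknown_token;
# returns list(vocab, counts, ids = corpus as 0-based rank ids with -1 breaks)
.index_corpus <- function(stream, min_count, unknown_token) {
  tokens <- unlist(stream, use.names = FALSE)
  if (!length(tokens)) stop("empty corpus")
  tab <- table(tokens)
  rare <- names(tab)[tab < min_count]
  if (length(rare)) {
    stream <- lapply(stream, function(x) ifelse(x %in% rare, unknown_token, x))
    tokens <- unlist(stream, use.names = FALSE)
    tab <- table(tokens)
  }
  counts <- as.integer(tab)
  # rank by descending count, ties lexicographic, for determinism
  ord <- order(-counts, names(tab), method = "radix")
  vocab <- names(tab)[ord]
  counts <- counts[ord]
  ids <- unlist(lapply(stream, function(x) c(match(x, vocab) - 1L, -1L)),
                use.names = FALSE)
  list(vocab = vocab, counts = counts, ids = ids)
}

#' Construct a cluster model
#' @keywords internal
new_cluster_model <- function(vocab, brown_code = NULL, brown_cluster = NULL,
                              kmeans_ids = list(), unknown_token = "<UNK>") {
  structure(list(vocab = vocab, brown_code = brown_code,
                 brown_cluster = brown_cluster, kmeans_ids = kmeans_ids,
                 unknown_token = unknown_token),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: %d words%s%s>\n", length(x$vocab),
              if (!is.null(x$brown_code)) ", Brown codes" else "",
              if (length(x$kmeans_ids))
                paste0(", k-means scales {",
                       paste(names(x$kmeans_ids), collapse = ", "), "}") else ""))
  invisible(x)
}

#' Train Brown word clusters
#'
#' Agglomerative hard clustering over adjacent-bigram statistics: the
#' `num_clusters` most frequent words start as singleton clusters, each
#' remaining word is inserted and the pair of clusters whose merge loses the
#' least average mutual information is merged, and finally the surviving
#' clusters are merged up to a single root. Each word's binary code is the
#' 0/1 branch path from the root of the merge tree to its leaf cluster, used
#' directly as a categorical feature. (These path codes are sometimes loosely
#' called Huffman codes; they are merge-tree paths, not frequency-optimal
#' prefix codes.)
#'
#' @param corpus character vector of text lines (tokenized internally) or a
#'   list of token vectors; sequence boundaries break bigrams.
#' @param num_clusters number of clusters (must not exceed the vocabulary
#'   size after `min_count` pooling).
#' @param min_count words seen fewer times are pooled into `unknown_token`.
#' @param unknown_token reserved surface used for rare words and for
#'   out-of-vocabulary lookups.
#' @return a `cluster_model` with `brown_code` and `brown_cluster` set.
#' @export
train_brown <- function(corpus, num_clusters, min_count = 2L,
                        unknown_token = "<UNK>") {
  stopifnot(num_clusters >= 1L)
  idx <- .index_corpus(.as_token_stream(corpus), min_count, unknown_token)
  V <- length(idx$vocab)
  if (V < num_clusters) {
    stop(sprintf("vocabulary (%d words after min_count pooling) is smaller than num_clusters (%d); use a smaller k",
                 V, num_clusters))
  }
  res <- brown_cluster_cpp(idx$ids, V, as.integer(num_clusters))
  code <- as.character(res$code)
  names(code) <- idx$vocab
  clu <- as.integer(res$cluster)
  names(clu) <- idx$vocab
  if (!unknown_token %in% idx$vocab) {
    # every observed word met min_count; give OOV lookups the code of the
    # least frequent word's cluster (the closest thing to a rare-word cluster)
    w <- idx$vocab[V]
    code[unknown_token] <- code[[w]]
    clu[unknown_token] <- clu[[w]]
  }
  new_cluster_model(idx$vocab, brown_code = code, brown_cluster = clu,
                    unknown_token = unknown_token)
}

#' Brown code feature of a word
#'
#' Returns the word's full binary path code, or its prefixes at the requested
#' lengths (codes shorter than a requested length are returned whole).
#' Unknown words get the unknown token's feature.
#'
#' @param model a `cluster_model` with Brown codes.
#' @param word a word surface.
#' @param prefix_lengths `"FULL"` (default) or a vector of positive prefix
#'   lengths.
#' @return character vector of feature strings.
#' @export
brown_feature <- function(model, word, prefix_lengths = "FULL") {
  stopifnot(inherits(model, "cluster_model"), !is.null(model$brown_code))
  code <- model$brown_code[[.lookup_word(model, word)]]
  if (identical(prefix_lengths, "FULL")) return(code)
  vapply(as.integer(prefix_lengths), function(p) {
    substr(code, 1L, min(p, nchar(code)))
  }, character(1L))
}

.lookup_word <- function(model, word) {
  if (word %in% model$vocab) word else model$unknown_token
}

#' Train skip-gram word embeddings
#'
#' Skip-gram with negative sampling, single-threaded and deterministic for a
#' fixed seed. The embedding is a means to an end here: its k-means clusters
#' provide the multi-scale word-class features.
#'
#' @inheritParams train_brown
#' @param dimension embedding dimension.
#' @param window maximum context radius (the effective radius per center is
#'   drawn uniformly from 1..window).
#' @param negative negative samples per context pair.
#' @param epochs passes over the corpus.
#' @param seed integer seed.
#' @param alpha initial learning rate (decays linearly).
#' @return an `embedding_set`: list with `dimension` and `vectors` (matrix
#'   with one named row per word).
#' @export
train_embeddings <- function(corpus, dimension = 100L, window = 5L,
                             negative = 5L, epochs = 5L, seed = 1L,
                             min_count = 2L, alpha = 0.025,
                             unknown_token = "<UNK>") {
  idx <- .index_corpus(.as_token_stream(corpus), min_count, unknown_token)
  V <- length(idx$vocab)
  vec <- sgns_train_cpp(idx$ids, V, as.numeric(idx$counts),
                        as.integer(dimension), as.integer(window),
                        as.integer(negative), as.integer(epochs),
                        alpha, as.integer(seed))
  rownames(vec) <- idx$vocab
  structure(list(dimension = as.integer(dimension), vectors = vec,
                 unknown_token = unknown_token),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set: %d words x %d dims>\n", nrow(x$vectors), x$dimension))
  invisible(x)
}

# k-means++ seeding (stats::kmeans has no built-in version of it)
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(X) - X[centers[1L], ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 <= 0)) stop("fewer distinct points than clusters")
    p <- d2 / sum(d2)
    centers[j + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, colSums((t(X) - X[centers[j + 1L], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' Multi-scale k-means clustering of word embeddings
#'
#' Runs an independent k-means (k-means++ seeding, Lloyd iterations,
#' Euclidean distance) per requested scale; every word gets one cluster id
#' per scale, and each scale contributes its own categorical feature stream.
#'
#' @param emb an `embedding_set`.
#' @param scales vector of cluster counts, each at most the vocabulary size.
#' @param seed integer seed.
#' @param model optional existing `cluster_model` (e.g., with Brown codes) to
#'   attach the ids to.
#' @return a `cluster_model` with `kmeans_ids` populated (ids in `[0, k)`).
#' @export
kmeans_multiscale <- function(emb, scales, seed = 1L, model = NULL) {
  stopifnot(inherits(emb, "embedding_set"))
  X <- emb$vectors
  V <- nrow(X)
  ids <- list()
  for (si in seq_along(scales)) {
    k <- as.integer(scales[si])
    if (k > V) stop(sprintf("scale %d exceeds vocabulary size %d", k, V))
    assign_k <- if (k == V) {
      seq_len(V) - 1L  # exact optimum: every word its own cluster
    } else if (k == 1L) {
      rep(0L, V)
    } else {
      with_seed(seed + si, {
        centers <- .kmeanspp_centers(X, k)
        km <- stats::kmeans(X, centers = centers, iter.max = 100L,
                            algorithm = "Lloyd")
        km$cluster - 1L
      })
    }
    names(assign_k) <- rownames(X)
    ids[[as.character(k)]] <- assign_k
  }
  if (is.null(model)) model <- new_cluster_model(rownames(X),
                                                unknown_token = emb$unknown_token)
  model$kmeans_ids <- ids
  if (!model$unknown_token %in% model$vocab && length(ids)) {
    # OOV fallback: ids of the least frequent embedded word
    for (k in names(model$kmeans_ids)) {
      model$kmeans_ids[[k]][model$unknown_token] <-
        model$kmeans_ids[[k]][[nrow(X)]]
    }
  }
  model
}

#' Cluster-id feature of a word at one scale
#'
#' @param model a `cluster_model` with `kmeans_ids`.
#' @param word word surface.
#' @param scale one of the trained scales.
#' @return the cluster id as a string.
#' @export
kmeans_feature <- function(model, word, scale) {
  ids <- model$kmeans_ids[[as.character(scale)]]
  if (is.null(ids)) stop("scale not trained: ", scale)
  as.character(ids[[.lookup_word(model, word)]])
}

#' Write a cluster model as plain text
#'
#' Format: a header line `#scales k1 k2 ...`, then one line per word:
#' `word \t brown_code \t id@k1 \t id@k2 ...` (`-` for an absent code).
#' @param model a `cluster_model`.
#' @param path output path.
#' @export
write_cluster_model <- function(model, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  scales <- names(model$kmeans_ids)
  writeLines(paste(c("#scales", scales), collapse = " "), con)
  words <- union(model$vocab, model$unknown_token)
  code <- if (is.null(model$brown_code)) rep("-", length(words)) else
    ifelse(is.na(model$brown_code[words]), "-", model$brown_code[words])
  cols <- list(words, code)
  for (k in scales) cols[[length(cols) + 1L]] <- model$kmeans_ids[[k]][words]
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a cluster model written by [write_cluster_model()]
#' @param path input path.
#' @param unknown_token the reserved unknown surface used at training time.
#' @export
read_cluster_model <- function(path, unknown_token = "<UNK>") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
  stopifnot(header[1L] == "#scales")
  scales <- header[-1L]
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  m <- do.call(rbind, parts)
  words <- m[, 1L]
  code <- m[, 2L]
  names(code) <- words
  has_code <- any(code != "-")
  kmeans_ids <- list()
  for (si in seq_along(scales)) {
    v <- as.integer(m[, 2L + si])
    names(v) <- words
    kmeans_ids[[scales[si]]] <- v
  }
  vocab <- setdiff(words, unknown_token)
  new_cluster_model(vocab,
                    brown_code = if (has_code) code else NULL,
                    kmeans_ids = kmeans_ids, unknown_token = unknown_token)
}
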