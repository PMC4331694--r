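# Independent oracles and small generators used across the suite. None of
# these call the code paths they are used to check.

# ---- linear-chain CRF by exhaustive path enumeration -----------------------
# feats: integer matrix (n x T), 0 = absent, else 1-based row of W
# Returns best path (1-based labels), logZ, per-position marginals.
enum_crf <- function(feats, W, Tr) {
  n <- nrow(feats)
  L <- ncol(W)
  emit <- matrix(0, n, L)
  for (i in seq_len(n)) {
    for (t in seq_len(ncol(feats))) {
      f <- feats[i, t]
      if (f > 0L) emit[i, ] <- emit[i, ] + W[f, ]
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  score <- numeric(nrow(paths))
  for (i in seq_len(n)) score <- score + emit[i, paths[, i]]
  if (n > 1L) {
    for (i in seq_len(n - 1L)) score <- score + Tr[cbind(paths[, i], paths[, i + 1L])]
  }
  m <- max(score)
  logZ <- m + log(sum(exp(score - m)))
  p <- exp(score - logZ)
  marg <- matrix(0, n, L)
  for (i in seq_len(n)) {
    for (l in seq_len(L)) marg[i, l] <- sum(p[paths[, i] == l])
  }
  best <- which.max(score)
  list(path = unname(paths[best, ]), logZ = logZ, marginals = marg,
       log_prob_path = score[best] - logZ)
}

# ---- average mutual information of a word partition ------------------------
# big: V x V bigram count matrix; assign: integer cluster per word (1-based)
ami_of_partition <- function(big, assign) {
  k <- max(assign)
  cc <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      cc[a, b] <- sum(big[assign == a, assign == b, drop = FALSE])
    }
  }
  N <- sum(cc)
  pl <- rowSums(cc) / N
  pr <- colSums(cc) / N
  q <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (cc[a, b] > 0) {
        q <- q + (cc[a, b] / N) * log((cc[a, b] / N) / (pl[a] * pr[b]))
      }
    }
  }
  q
}

# bigram count matrix of a token-id corpus (ids 1..V, NA breaks sequences)
bigram_counts <- function(ids, V) {
  big <- matrix(0, V, V)
  for (i in seq_len(length(ids) - 1L)) {
    a <- ids[i]; b <- ids[i + 1L]
    if (!is.na(a) && !is.na(b)) big[a, b] <- big[a, b] + 1
  }
  big
}

# all partitions of 1..n into exactly k non-empty blocks (restricted growth)
set_partitions <- function(n, k) {
  out <- list()
  rec <- function(assign, i, used) {
    if (i > n) {
      if (used == k) out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (c in seq_len(min(used + 1L, k))) {
      assign[i] <- c
      rec(assign, i + 1L, max(used, c))
    }
  }
  rec(integer(n), 1L, 0L)
  out
}

# block-structured corpus for the Brown oracle: words fall into latent
# classes and the class sequence follows a near-deterministic cycle, so words
# of one class share contexts; returns list(tokens = list of sequences,
# classes = integer per word, vocab)
make_block_corpus <- function(seed, V = 8L, k = 2L, n_sentences = 40L,
                              sentence_len = 12L) {
  set.seed(seed)
  vocab <- paste0("w", seq_len(V))
  classes <- sort(rep_len(seq_len(k), V))
  tokens <- lapply(seq_len(n_sentences), function(s) {
    cls <- (seq_len(sentence_len) + sample.int(k, 1L)) %% k + 1L
    vapply(cls, function(c) sample(vocab[classes == c], 1L), character(1L))
  })
  list(tokens = tokens, classes = classes, vocab = vocab)
}

# random non-overlapping gold spans aligned to unit boundaries of a sequence
random_gold_for_seq <- function(seq, max_spans = 3L) {
  n <- length(seq$surface)
  if (n == 0L) return(entity_spans())
  picks <- list()
  free <- rep(TRUE, n)
  for (s in seq_len(sample.int(max_spans + 1L, 1L) - 1L)) {
    starts <- which(free)
    if (!length(starts)) break
    a <- starts[sample.int(length(starts), 1L)]
    b <- a
    while (b < n && free[b + 1L] && stats::runif(1) < 0.5) b <- b + 1L
    free[a:b] <- FALSE
    picks[[length(picks) + 1L]] <- c(a, b)
  }
  if (!length(picks)) return(entity_spans())
  do.call(rbind, lapply(picks, function(p) {
    entity_spans(doc_id = seq$doc_id, section = seq$section,
                 start = seq$start[p[1L]], end = seq$end[p[2L]],
                 text = if (!is.null(seq$text))
                   substr(seq$text, seq$start[p[1L]] + 1L, seq$end[p[2L]]) else "x",
                 confidence = 1, source = "GOLD")
  }))
}

# random unicode strings exercising Greek letters, brackets, digits, spaces
random_chem_string <- function(max_len = 40L) {
  alphabet <- c(letters[1:8], LETTERS[1:4], 0:9, "α", "β", "Δ", "±",
                "(", ")", "[", "]", "{", "}", "-", ",", "'", ".", "/",
                " ", " ", "\t")
  n <- sample.int(max_len + 1L, 1L) - 1L
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# shared fixture for the end-to-end acceptance checks: trains the mixed
# system once per test run and caches it
.acceptance_env <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (!is.null(.acceptance_env$fx)) return(.acceptance_env$fx)
  train <- generate_corpus(synth_config(seed = 20260901L, n_docs = 500L))
  test <- generate_corpus(synth_config(seed = 20260902L, n_docs = 100L))
  ctext <- generate_cluster_text(synth_config(seed = 20260901L), 6000L)
  model <- train_chemner(train$docs, train$gold, char_direction = "INVERTED",
                         cluster_mode = "BROWN", cluster_text = ctext,
                         brown_clusters = 16L, max_iter = 120L,
                         seed = 20260901L)
  .acceptance_env$fx <- list(train = train, test = test, model = model)
  .acceptance_env$fx
}

single_model <- function(model, which = c("char", "word")) {
  which <- match.arg(which)
  structure(list(
    char_model = if (which == "char") model$char_model,
    word_model = if (which == "word") model$word_model,
    cluster_model = if (which == "word") model$cluster_model,
    char_direction = model$char_direction,
    cluster_mode = if (which == "word") model$cluster_mode else "NONE",
    seed = model$seed), class = "chemner_model")
}
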