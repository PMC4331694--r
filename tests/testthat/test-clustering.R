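test_that("Brown clustering separates words by shared contexts (toy oracle)", {
  corpus <- rep("a b a b c d c d", 5L)
  model <- train_brown(corpus, 2L, min_count = 1L)
  # independent check: exhaustive AMI maximization over all 2-partitions
  stream <- lapply(corpus, function(x) tokenize_words(x)$surface)
  vocab <- sort(unique(unlist(stream)))
  ids <- unlist(lapply(stream, function(x) c(match(x, vocab), NA)))
  big <- bigram_counts(ids, length(vocab))
  parts <- set_partitions(length(vocab), 2L)
  amis <- vapply(parts, function(p) ami_of_partition(big, p), numeric(1L))
  got <- model$brown_cluster[vocab]
  expect_equal(ami_of_partition(big, got + 1L), max(amis), tolerance = 1e-12)
  # {a,c} vs {b,d}: same-context words cluster together
  expect_identical(got[["a"]], got[["c"]])
  expect_identical(got[["b"]], got[["d"]])
  expect_false(got[["a"]] == got[["b"]])
})

test_that("k = vocabulary size yields singleton clusters with distinct codes", {
  model <- train_brown(rep("a b c d a b c d", 3L), 4L, min_count = 1L)
  expect_identical(sort(unique(unname(model$brown_cluster[model$vocab]))), 0:3)
  codes <- unname(model$brown_code[model$vocab])
  expect_identical(anyDuplicated(codes), 0L)
  # tree consistency: cluster codes are prefix-free and Kraft-complete
  expect_equal(sum(2^-nchar(unique(codes))), 1)
})

test_that("vocabulary smaller than num_clusters is an error", {
  expect_error(train_brown("a b a b", 5L, min_count = 1L), "smaller")
})

test_that("words merged earlier share longer code prefixes", {
  # words of one context class merge into one cluster (earliest merges) and
  # share their entire code; words merged later, across clusters, share only
  # a strictly shorter prefix
  corp <- make_block_corpus(seed = 99L, V = 9L, k = 3L)
  model <- train_brown(corp$tokens, 3L, min_count = 1L)
  codes <- model$brown_code
  common_prefix <- function(x, y) {
    i <- 0L
    while (i < min(nchar(x), nchar(y)) &&
           substr(x, 1L, i + 1L) == substr(y, 1L, i + 1L)) i <- i + 1L
    i
  }
  cl <- model$brown_cluster[corp$vocab]
  for (x in corp$vocab) {
    for (y in corp$vocab) {
      if (x == y) next
      shared <- common_prefix(codes[[x]], codes[[y]])
      if (cl[[x]] == cl[[y]]) {
        expect_identical(shared, nchar(codes[[x]]))
      } else {
        expect_lt(shared, min(nchar(codes[[x]]), nchar(codes[[y]])))
      }
    }
  }
})

test_that("brown_feature returns the code or its prefixes, UNK for OOV", {
  model <- train_brown(rep("a b a b c d c d", 5L), 4L, min_count = 1L)
  w <- model$vocab[1L]
  code <- model$brown_code[[w]]
  expect_identical(brown_feature(model, w), code)
  pref <- brown_feature(model, w, prefix_lengths = c(1L, 99L))
  expect_identical(pref[1L], substr(code, 1L, 1L))
  expect_identical(pref[2L], code)  # short-code rule: returned whole
  expect_identical(brown_feature(model, "neverseen"),
                   model$brown_code[[model$unknown_token]])
})

test_that("rare words pool into the unknown token", {
  model <- train_brown(c(rep("a b a b", 4L), "rareword b"), 2L, min_count = 2L)
  expect_false("rareword" %in% model$vocab)
  expect_true(model$unknown_token %in% model$vocab)
  expect_identical(brown_feature(model, "rareword"),
                   model$brown_code[[model$unknown_token]])
})

test_that("skip-gram embeddings are deterministic and group shared contexts", {
  cfg <- synth_config(seed = 5L)
  text <- generate_cluster_text(cfg, 2000L)
  emb1 <- train_embeddings(text, dimension = 30L, epochs = 8L, seed = 9L)
  emb2 <- train_embeddings(text, dimension = 30L, epochs = 8L, seed = 9L)
  expect_identical(emb1$vectors, emb2$vectors)
  expect_identical(ncol(emb1$vectors), 30L)
  # stems share contexts; nouns do too; cross-group similarity is lower
  stems <- intersect(chemner:::.syn_stems(600L), rownames(emb1$vectors))[1:15]
  nouns <- intersect(chemner:::.syn_nouns, rownames(emb1$vectors))[1:15]
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  V <- emb1$vectors
  pairs_mean <- function(g1, g2) {
    mean(apply(expand.grid(g1, g2, stringsAsFactors = FALSE), 1L,
               function(p) if (p[1] == p[2]) NA else cos(V[p[1], ], V[p[2], ])),
         na.rm = TRUE)
  }
  intra <- pairs_mean(stems, stems)
  inter <- pairs_mean(stems, nouns)
  expect_gt(intra, inter)
  expect_error(train_embeddings(character()), "empty")
})

test_that("k-means scales behave at the degenerate ks and separate blobs", {
  set.seed(31)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = 0.05), ncol = 4L),
             matrix(rnorm(40, mean = 5, sd = 0.05), ncol = 4L))
  rownames(X) <- paste0("w", 1:20)
  emb <- structure(list(dimension = 4L, vectors = X, unknown_token = "<UNK>"),
                   class = "embedding_set")
  model <- kmeans_multiscale(emb, scales = c(1L, 2L, 20L), seed = 3L)
  expect_identical(unname(model$kmeans_ids[["1"]][1:20]), rep(0L, 20L))
  two <- model$kmeans_ids[["2"]][1:20]
  expect_identical(length(unique(two[1:10])), 1L)
  expect_identical(length(unique(two[11:20])), 1L)
  expect_false(two[[1L]] == two[[11L]])
  expect_identical(sort(unname(model$kmeans_ids[["20"]][1:20])), 0:19)
  expect_error(kmeans_multiscale(emb, scales = 21L), "exceeds")
  # reproducible under the same seed
  model2 <- kmeans_multiscale(emb, scales = c(1L, 2L, 20L), seed = 3L)
  expect_identical(model$kmeans_ids, model2$kmeans_ids)
})

test_that("cluster models round trip through the text format", {
  text <- rep(c("a b a b c d c d", "e f e f a b"), 4L)
  model <- train_brown(text, 3L, min_count = 1L)
  emb <- train_embeddings(text, dimension = 8L, epochs = 2L, seed = 1L,
                          min_count = 1L)
  model <- kmeans_multiscale(emb, scales = c(2L, 3L), seed = 1L, model = model)
  path <- withr::local_tempfile()
  write_cluster_model(model, path)
  back <- read_cluster_model(path)
  expect_setequal(back$vocab, model$vocab)
  expect_identical(back$brown_code[model$vocab], model$brown_code[model$vocab])
  for (k in names(model$kmeans_ids)) {
    expect_identical(back$kmeans_ids[[k]][model$vocab],
                     model$kmeans_ids[[k]][model$vocab])
  }
})
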