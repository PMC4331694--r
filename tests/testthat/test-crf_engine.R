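# small random training set builder: word sequences with one marked token
make_separable_data <- function(n_copies = 50L) {
  lapply(seq_len(n_copies), function(i) {
    seq <- tokenize_words("we used drugX in many long assays today", "D1", "A")
    gold <- entity_spans("D1", "A", 8L, 13L, "drugX", source = "GOLD")
    list(features = word_features(seq), labels = spans_to_labels(seq, gold))
  })
}

test_that("a separable pattern is learned to training F = 1", {
  data <- make_separable_data()
  model <- train_crf(data, max_iter = 60L)
  dec <- decode_crf(model, data[[1L]]$features)
  expect_identical(dec$labels, data[[1L]]$labels)
  expect_true(all(abs(rowSums(dec$marginals) - 1) < 1e-9))
})

test_that("training is deterministic: same data gives an identical model file", {
  data <- make_separable_data(10L)
  m1 <- train_crf(data, max_iter = 30L, seed = 1L)
  m2 <- train_crf(data, max_iter = 30L, seed = 1L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_crf_model(m1, f1); write_crf_model(m2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("very strong regularization shrinks weights toward zero and the
           path distribution toward uniform", {
  data <- make_separable_data(10L)
  model <- train_crf(data, l2 = 1e6, max_iter = 50L)
  expect_lt(max(abs(model$W)), 1e-3)
  dec <- decode_crf(model, data[[1L]]$features)
  n <- length(dec$labels)
  # with weights ~ 0 every path is (almost) equally likely
  expect_lt(abs(log(dec$path_probability) - n * log(1 / 8)), 0.01)
})

test_that("misaligned or malformed training data is rejected", {
  data <- make_separable_data(2L)
  bad <- data
  bad[[1L]]$labels <- bad[[1L]]$labels[-1L]
  expect_error(train_crf(bad), "misaligned")
  bad2 <- data
  bad2[[2L]]$labels[1L] <- "Z"
  expect_error(train_crf(bad2), "unknown label")
  expect_error(train_crf(list()), "empty")
})

test_that("decoding rejects features built from another template set", {
  data <- make_separable_data(5L)
  model <- train_crf(data, max_iter = 20L)
  chfm <- char_features(tokenize_chars("drugX"))
  expect_error(decode_crf(model, chfm), "template mismatch")
})

test_that("Viterbi and marginals match exhaustive enumeration (engine core)", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(1:6, 1L)
    L <- sample(2:4, 1L)
    FN <- 12L
    Tn <- 3L
    feats <- matrix(sample(0:FN, n * Tn, replace = TRUE), n, Tn)
    W <- matrix(rnorm(FN * L), FN, L)
    Tr <- matrix(rnorm(L * L), L, L)
    got <- chemner:::crf_infer_cpp(feats, W, Tr)
    exp_ <- enum_crf(feats, W, Tr)
    expect_identical(as.integer(got$path), as.integer(exp_$path))
    expect_lt(abs(got$logZ - exp_$logZ), 1e-9)
    expect_lt(max(abs(got$marginals - exp_$marginals)), 1e-9)
    expect_lt(abs(got$log_prob_path - exp_$log_prob_path), 1e-9)
  }
})

test_that("the analytic gradient matches finite differences", {
  set.seed(92)
  n <- 5L; L <- 3L; FN <- 6L; Tn <- 2L
  feats <- matrix(sample(0:FN, n * Tn, replace = TRUE), n, Tn)
  y <- sample(seq_len(L), n, replace = TRUE)
  par <- rnorm(FN * L + L * L) * 0.3
  nll_of <- function(p) {
    W <- matrix(p[seq_len(FN * L)], FN, L)
    Tr <- matrix(p[FN * L + seq_len(L * L)], L, L)
    chemner:::crf_nll_grad_cpp(list(feats), list(y), W, Tr)$nll
  }
  r <- chemner:::crf_nll_grad_cpp(list(feats), list(y),
                                  matrix(par[seq_len(FN * L)], FN, L),
                                  matrix(par[FN * L + seq_len(L * L)], L, L))
  grad <- c(r$gW, r$gT)
  eps <- 1e-6
  for (j in sample(seq_along(par), 10L)) {
    up <- par; up[j] <- up[j] + eps
    dn <- par; dn[j] <- dn[j] - eps
    expect_lt(abs((nll_of(up) - nll_of(dn)) / (2 * eps) - grad[j]), 1e-5)
  }
})

test_that("a zero-weight model yields uniform marginals", {
  feats <- matrix(0L, 4L, 2L)
  L <- 8L
  got <- chemner:::crf_infer_cpp(feats, matrix(0, 3L, L), matrix(0, L, L))
  expect_true(all(abs(got$marginals - 1 / L) < 1e-12))
})

test_that("entity confidence is the product of assigned-label marginals", {
  marg <- matrix(0.1 / 7, 3L, 8L, dimnames = list(NULL, crf_labels()))
  marg[1L, "S_NER"] <- 0.9; marg[2L, "B_NER"] <- 0.9; marg[3L, "E_NER"] <- 0.9
  marg <- marg / rowSums(marg)
  dec <- structure(list(labels = c("S_NER", "B_NER", "E_NER"),
                        marginals = marg, log_z = 0, path_probability = 1),
                   class = "crf_decoding")
  expect_equal(entity_confidence(dec, 1L), 0.9)
  expect_equal(entity_confidence(dec, 1:3), 0.9^3)
})

test_that("serialization round trip preserves decoding bit-exactly", {
  data <- make_separable_data(10L)
  model <- train_crf(data, max_iter = 40L)
  path <- withr::local_tempfile()
  write_crf_model(model, path)
  back <- read_crf_model(path)
  expect_identical(back$features, model$features)
  expect_identical(back$W, model$W)
  expect_identical(back$Tr, model$Tr)
  d1 <- decode_crf(model, data[[3L]]$features)
  d2 <- decode_crf(back, data[[3L]]$features)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$marginals, d2$marginals)
})

test_that("direction plumbing: a model trained on mirrored data decodes the
           mirror of the forward model's output", {
  cc <- generate_corpus(synth_config(seed = 77L, n_docs = 12L))
  fwd_data <- list(); inv_data <- list()
  seqs <- list()
  for (i in seq_len(nrow(cc$docs))) {
    seq <- tokenize_chars(cc$docs$title[i], cc$docs$doc_id[i], "T")
    if (!length(seq$surface)) next
    lab <- spans_to_labels(seq, cc$gold)
    seqs[[length(seqs) + 1L]] <- seq
    fwd_data[[length(fwd_data) + 1L]] <-
      list(features = char_features(seq), labels = lab)
    inv_data[[length(inv_data) + 1L]] <-
      list(features = char_features(invert(seq)), labels = invert_labels(lab))
  }
  mf <- train_crf(fwd_data, max_iter = 40L)
  mi <- train_crf(inv_data, max_iter = 40L)
  for (j in c(1L, 5L, 9L)) {
    df <- decode_crf(mf, fwd_data[[j]]$features)
    di <- decode_crf(mi, inv_data[[j]]$features)
    expect_identical(invert_labels(di$labels), df$labels)
  }
})
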