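five_units <- function() {
  tokenize_words("aa bb cc dd ee", doc_id = "D1", section = "A")
}
gold_over <- function(seq, first, last) {
  entity_spans(doc_id = "D1", section = "A",
               start = seq$start[first], end = seq$end[last],
               text = substr(seq$text, seq$start[first] + 1L, seq$end[last]),
               confidence = 1, source = "GOLD")
}

test_that("gold spans map to B/M/E/S labels in both families", {
  seq <- five_units()
  expect_identical(spans_to_labels(seq, gold_over(seq, 2L, 4L)),
                   c("S", "B_NER", "M_NER", "E_NER", "S"))
  seq3 <- tokenize_words("aa bb cc", doc_id = "D1", section = "A")
  expect_identical(spans_to_labels(seq3, entity_spans()), c("B", "M", "E"))
  seq2 <- tokenize_words("aa bb", doc_id = "D1", section = "A")
  expect_identical(spans_to_labels(seq2, gold_over(seq2, 1L, 1L)),
                   c("S_NER", "S"))
})

test_that("labels decode back to spans, including malformed-segment repair", {
  seq <- tokenize_words("a bc de", doc_id = "D1", section = "A")
  sp <- labels_to_spans(seq, c("S", "B_NER", "E_NER"))
  expect_identical(sp$start, 2L)
  expect_identical(sp$end, 7L)
  expect_identical(sp$text, "bc de")
  expect_identical(nrow(labels_to_spans(seq, c("B", "M", "E"))), 0L)
  # M_NER without B_NER: the maximal run still becomes one entity
  rep_sp <- labels_to_spans(seq, c("M_NER", "E_NER", "S"))
  expect_identical(nrow(rep_sp), 1L)
  expect_identical(rep_sp$end, 4L)
  # two adjacent well-formed entities split at the segment boundary
  two <- labels_to_spans(seq, c("S_NER", "B_NER", "E_NER"))
  expect_identical(nrow(two), 2L)
})

test_that("span/label round trip is the identity for boundary-compatible gold", {
  set.seed(11)
  for (i in 1:100) {
    txt <- paste(replicate(sample(3:9, 1L),
                           paste(sample(letters, sample(1:4, 1L), TRUE),
                                 collapse = "")), collapse = " ")
    seq <- tokenize_words(txt, doc_id = "D1", section = "A")
    gold <- random_gold_for_seq(seq)
    lab <- spans_to_labels(seq, gold)
    expect_true(labels_wellformed(lab))
    back <- labels_to_spans(seq, lab)
    gold_sorted <- gold[order(gold$start), , drop = FALSE]
    expect_identical(back$start, gold_sorted$start)
    expect_identical(back$end, gold_sorted$end)
  }
})

test_that("word-granularity spans snap outward; char granularity refuses", {
  seq <- tokenize_words("abcdef gh", doc_id = "D1", section = "A")
  inside <- entity_spans("D1", "A", 2L, 6L, "cdef", source = "GOLD")
  expect_warning(lab <- spans_to_labels(seq, inside), "snapped")
  expect_identical(lab, c("S_NER", "S"))
  chseq <- tokenize_chars("ab cd", doc_id = "D1", section = "A")
  # a span ending inside whitespace does not align with any character unit
  bad <- entity_spans("D1", "A", 0L, 3L, "ab ", source = "GOLD")
  expect_error(spans_to_labels(chseq, bad), "boundary mismatch")
})

test_that("overlapping gold spans are rejected", {
  seq <- five_units()
  g <- rbind(gold_over(seq, 1L, 3L), gold_over(seq, 3L, 5L))
  expect_error(spans_to_labels(seq, g), "overlapping")
})

test_that("label mirroring is an involution consistent with invert()", {
  lab <- c("S", "B_NER", "M_NER", "E_NER", "B", "E")
  expect_identical(invert_labels(invert_labels(lab)), lab)
  seq <- five_units()
  gold <- gold_over(seq, 2L, 4L)
  fwd <- spans_to_labels(seq, gold)
  # labels of the inverted sequence = mirrored labels of the forward one
  expect_identical(invert_labels(fwd), c("S", "B_NER", "M_NER", "E_NER", "S"))
})

test_that("spans decoded on an inverted sequence map back to the original", {
  set.seed(12)
  for (i in 1:50) {
    txt <- paste(replicate(sample(3:8, 1L),
                           paste(sample(c(letters, "(", ")", "3", "β"),
                                        sample(1:4, 1L), TRUE),
                                 collapse = "")), collapse = " ")
    seq <- tokenize_words(txt, doc_id = "D1", section = "A")
    gold <- random_gold_for_seq(seq)
    if (!nrow(gold)) next
    inv <- invert(seq)
    lab_inv <- invert_labels(spans_to_labels(seq, gold))
    dec <- labels_to_spans(inv, lab_inv)
    mapped <- map_inverted_spans(dec, seq)
    gold_sorted <- gold[order(gold$start), , drop = FALSE]
    expect_identical(mapped$start, gold_sorted$start)
    expect_identical(mapped$end, gold_sorted$end)
    expect_identical(mapped$text, gold_sorted$text)
  }
})
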