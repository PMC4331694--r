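span <- function(start, end, conf, source, doc = "D1", sec = "A",
                 text = strrep("x", end - start)) {
  entity_spans(doc, sec, start, end, text, confidence = conf, source = source)
}

test_that("one shared boundary: confidence gap decides, else length", {
  # gap 0.85 > 0.7: keep the confident char span
  out <- merge_spans(span(0L, 7L, 0.95, "CHAR_MODEL"),
                     span(0L, 12L, 0.10, "WORD_MODEL"))
  expect_identical(out$start, 0L); expect_identical(out$end, 7L)
  # gap 0.2 <= 0.7: keep the longer word span
  out <- merge_spans(span(0L, 7L, 0.60, "CHAR_MODEL"),
                     span(0L, 12L, 0.40, "WORD_MODEL"))
  expect_identical(out$end, 12L)
  # the threshold comparison is strict: a gap exactly at the threshold keeps
  # the longer span (threshold 0.5 and confidences 0.75/0.25 are all exact
  # binary fractions, so the comparison is exact)
  out <- merge_spans(span(0L, 7L, 0.75, "CHAR_MODEL"),
                     span(0L, 12L, 0.25, "WORD_MODEL"),
                     merge_policy(confidence_diff_threshold = 0.5))
  expect_identical(out$end, 12L)
})

test_that("identical spans collapse to one with the max confidence", {
  out <- merge_spans(span(3L, 9L, 0.5, "CHAR_MODEL"),
                     span(3L, 9L, 0.8, "WORD_MODEL"))
  expect_identical(nrow(out), 1L)
  expect_identical(out$confidence, 0.8)
  expect_identical(out$source, "MERGED")
})

test_that("overlap with no shared boundary keeps the higher confidence;
           unopposed spans pass through", {
  out <- merge_spans(rbind(span(2L, 8L, 0.9, "CHAR_MODEL"),
                           span(20L, 24L, 0.7, "CHAR_MODEL")),
                     span(4L, 10L, 0.3, "WORD_MODEL"))
  expect_identical(out$start, c(2L, 20L))
  out2 <- merge_spans(span(0L, 4L, 0.9, "CHAR_MODEL"),
                      span(10L, 14L, 0.2, "WORD_MODEL"))
  expect_identical(nrow(out2), 2L)  # disjoint: union
})

test_that("merged output is sorted, non-overlapping, and merge is idempotent", {
  set.seed(41)
  for (rep in 1:100) {
    mk <- function(source) {
      k <- sample(0:4, 1L)
      if (k == 0L) return(entity_spans())
      starts <- sort(sample(seq(0L, 60L, by = 3L), k))
      ends <- starts + sample(1:3, k, replace = TRUE)
      ends <- pmin(ends, c(starts[-1L], 99L))  # non-overlapping per model
      keep <- ends > starts
      if (!any(keep)) return(entity_spans())
      entity_spans(rep("D1", sum(keep)), rep("A", sum(keep)),
                   starts[keep], ends[keep],
                   strrep("x", (ends - starts)[keep]),
                   confidence = round(stats::runif(sum(keep)), 3L),
                   source = source)
    }
    out <- merge_spans(mk("CHAR_MODEL"), mk("WORD_MODEL"))
    if (nrow(out) > 1L) {
      expect_true(all(diff(out$start) >= 0))
      expect_true(all(out$start[-1L] >= out$end[-nrow(out)]))
    }
    a <- out; a$source <- rep("CHAR_MODEL", nrow(a))
    b <- out; b$source <- rep("WORD_MODEL", nrow(b))
    again <- merge_spans(a, b)
    expect_identical(again[c("start", "end", "confidence")],
                     out[c("start", "end", "confidence")])
  }
})

test_that("overlapping spans from one model are rejected", {
  bad <- rbind(span(0L, 5L, 0.9, "CHAR_MODEL"), span(3L, 8L, 0.8, "CHAR_MODEL"))
  expect_error(merge_spans(bad, entity_spans()), "same model")
})

test_that("confidence filter removes strictly-below-threshold spans only", {
  spans <- rbind(span(0L, 3L, 0.00009, "MERGED"),
                 span(5L, 8L, 0.0001, "MERGED"),
                 span(9L, 12L, 0.5, "MERGED"))
  out <- filter_confidence(spans, merge_policy())
  expect_identical(out$start, c(5L, 9L))
  expect_identical(nrow(filter_confidence(entity_spans())), 0L)
})

test_that("bracket repair extends by one character or deletes", {
  pol <- merge_policy()
  txt <- "x (2E,4R)-ol y"
  sp <- entity_spans("D1", "A", 2L, 8L, "(2E,4R", source = "MERGED")
  out <- adjust_brackets(sp, txt, pol)
  expect_identical(out$end, 9L)
  expect_identical(out$text, "(2E,4R)")

  sp2 <- entity_spans("D1", "A", 3L, 9L, "2E,4R)", source = "MERGED")
  out2 <- adjust_brackets(sp2, txt, pol)
  expect_identical(out2$start, 2L)
  expect_identical(out2$text, "(2E,4R)")

  txt3 <- "xx4R) yy"
  sp3 <- entity_spans("D1", "A", 2L, 5L, "4R)", source = "MERGED")
  expect_identical(nrow(adjust_brackets(sp3, txt3, pol)), 0L)

  txt4 <- "β-(3,4-dihydroxyphenyl) rest"
  sp4 <- entity_spans("D1", "A", 0L, 23L, "β-(3,4-dihydroxyphenyl)",
                      source = "MERGED")
  expect_identical(adjust_brackets(sp4, txt4, pol)$text, sp4$text)
})

test_that("a repaired span is re-checked against the remaining pairs", {
  # missing ')' and ']': both neighbors present, two extensions
  txt <- "a ([b)] c"
  sp <- entity_spans("D1", "A", 2L, 5L, "([b", source = "MERGED")
  out <- adjust_brackets(sp, txt, merge_policy())
  expect_identical(out$text, "([b)]")
  # missing ')' repaired, then ']' unrepairable: delete
  txt2 <- "a ([b) c"
  sp2 <- entity_spans("D1", "A", 2L, 5L, "([b", source = "MERGED")
  expect_identical(nrow(adjust_brackets(sp2, txt2, merge_policy())), 0L)
})
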