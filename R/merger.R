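# Combination of character-model and word-model predictions, confidence
# filtering, and bracket-balance repair of entity boundaries.
#
# Merge heuristic: identical spans collapse (max confidence); a char/word
# pair sharing exactly one boundary offset keeps the higher-confidence span
# if the confidence difference exceeds the threshold and the longer span
# otherwise; overlapping pairs sharing no boundary keep the higher-confidence
# span; spans with no counterpart pass through (union of both models).

#' Merge policy parameters
#'
#' @param confidence_diff_threshold confidence-difference threshold for the
#'   one-shared-offset rule (strict `>`).
#' @param min_confidence spans with confidence strictly below this are
#'   dropped by [filter_confidence()].
#' @param bracket_pairs 2-column matrix of open/close bracket characters, in
#'   the order the repair rules are applied.
#' @return a `merge_policy` list.
#' @export
merge_policy <- function(confidence_diff_threshold = 0.7,
                         min_confidence = 0.0001,
                         bracket_pairs = NULL) {
  if (is.null(bracket_pairs)) {
    bracket_pairs <- matrix(c("(", ")", "[", "]", "{", "}"),
                            ncol = 2L, byrow = TRUE)
  }
  stopifnot(min_confidence >= 0, min_confidence < 1,
            confidence_diff_threshold >= 0)
  structure(list(confidence_diff_threshold = confidence_diff_threshold,
                 min_confidence = min_confidence,
                 bracket_pairs = bracket_pairs),
            class = "merge_policy")
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

.check_no_same_model_overlap <- function(spans) {
  for (src in unique(spans$source)) {
    d <- spans[spans$source == src, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      stop("overlapping spans from the same model (", src,
           "): models decode non-overlapping segments")
    }
  }
}

# resolve one conflicting char/word pair; returns index (1 or 2) of winner
.resolve_pair <- function(a, b, policy) {
  same_start <- a$start == b$start
  same_end <- a$end == b$end
  pick_conf <- function() {
    if (a$confidence != b$confidence) return(if (a$confidence > b$confidence) 1L else 2L)
    len_a <- a$end - a$start; len_b <- b$end - b$start
    if (len_a != len_b) return(if (len_a > len_b) 1L else 2L)
    if (a$start != b$start) return(if (a$start < b$start) 1L else 2L)
    if (a$source == "CHAR_MODEL") 1L else 2L
  }
  pick_longer <- function() {
    len_a <- a$end - a$start; len_b <- b$end - b$start
    if (len_a != len_b) return(if (len_a > len_b) 1L else 2L)
    pick_conf()
  }
  if (same_start && same_end) return(pick_conf())
  if (xor(same_start, same_end)) {
    if (abs(a$confidence - b$confidence) > policy$confidence_diff_threshold) {
      return(pick_conf())
    }
    return(pick_longer())
  }
  pick_conf()
}

#' Merge character-model and word-model entity predictions
#'
#' Within each document section: identical spans collapse to one with the
#' maximum confidence; conflicting cross-model pairs are resolved in
#' descending confidence order (a span eliminated by one comparison does not
#' take part in later ones); unopposed spans pass through. Output spans are
#' sorted, non-overlapping and carry `source = "MERGED"`.
#'
#' @param char_spans,word_spans entity-span data.frames with sources
#'   `CHAR_MODEL` / `WORD_MODEL` and confidences set.
#' @param policy a [merge_policy()].
#' @return entity-span data.frame.
#' @export
merge_spans <- function(char_spans, word_spans, policy = merge_policy()) {
  all <- rbind(char_spans, word_spans)
  if (!nrow(all)) return(entity_spans())
  if (any(!all$source %in% c("CHAR_MODEL", "WORD_MODEL"))) {
    stop("merge_spans expects CHAR_MODEL / WORD_MODEL sources")
  }
  out <- list()
  for (key in unique(paste(all$doc_id, all$section))) {
    d <- all[paste(all$doc_id, all$section) == key, , drop = FALSE]
    .check_no_same_model_overlap(d)
    # collapse identical spans (max confidence)
    dup_key <- paste(d$start, d$end)
    if (anyDuplicated(dup_key)) {
      conf <- tapply(d$confidence, dup_key, max)
      d <- d[!duplicated(dup_key), , drop = FALSE]
      d$confidence <- as.numeric(conf[paste(d$start, d$end)])
    }
    # descending confidence processing order (ties: earlier, shorter)
    d <- d[order(-d$confidence, d$start, d$end - d$start), , drop = FALSE]
    alive <- rep(TRUE, nrow(d))
    n <- nrow(d)
    for (i in seq_len(n)) {
      if (!alive[i]) next
      j <- i + 1L
      while (j <= n) {
        if (alive[j] && d$source[i] != d$source[j] &&
            .overlaps(d$start[i], d$end[i], d$start[j], d$end[j])) {
          w <- .resolve_pair(d[i, ], d[j, ], policy)
          if (w == 1L) alive[j] <- FALSE else { alive[i] <- FALSE; break }
        }
        j <- j + 1L
      }
    }
    d <- d[alive, , drop = FALSE]
    d$source <- "MERGED"
    out[[key]] <- d[order(d$start, d$end), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop low-confidence spans
#'
#' Removes spans whose confidence is strictly below
#' `policy$min_confidence`; order is preserved.
#'
#' @param spans entity-span data.frame.
#' @param policy a [merge_policy()].
#' @export
filter_confidence <- function(spans, policy = merge_policy()) {
  spans[spans$confidence >= policy$min_confidence, , drop = FALSE]
}

#' Repair bracket imbalance at an entity boundary
#'
#' For each bracket pair (o, c), in policy order: if the span contains one
#' more `o` than `c` and the character just after the span is `c`, the span
#' is extended one character to the right — otherwise the span is deleted;
#' symmetrically, one more `c` than `o` extends one character to the left
#' when the character just before the span is `o`, else deletes. An extended
#' span is re-checked against all rules. Balanced spans pass unchanged.
#'
#' @param span one-row entity-span data.frame.
#' @param text the section text the span refers to.
#' @param policy a [merge_policy()].
#' @return a one-row data.frame (possibly with adjusted offsets and text) or
#'   a zero-row data.frame if the span was deleted.
#' @export
adjust_brackets <- function(span, text, policy = merge_policy()) {
  stopifnot(nrow(span) == 1L)
  start <- span$start; end <- span$end
  n <- nchar(text)
  pairs <- policy$bracket_pairs
  count_char <- function(s, ch) {
    sum(strsplit(s, "", fixed = TRUE)[[1L]] == ch)
  }
  repeat {
    stxt <- .substr0(text, start, end)
    changed <- FALSE
    for (p in seq_len(nrow(pairs))) {
      o <- pairs[p, 1L]; cl <- pairs[p, 2L]
      no <- count_char(stxt, o); nc <- count_char(stxt, cl)
      if (no == nc + 1L) {
        if (end < n && .substr0(text, end, end + 1L) == cl) {
          end <- end + 1L; changed <- TRUE; break
        }
        return(span[0L, , drop = FALSE])
      } else if (nc == no + 1L) {
        if (start > 0L && .substr0(text, start - 1L, start) == o) {
          start <- start - 1L; changed <- TRUE; break
        }
        return(span[0L, , drop = FALSE])
      }
    }
    if (!changed) break
  }
  span$start <- start; span$end <- end
  span$text <- .substr0(text, start, end)
  span
}

#' Apply bracket repair to all spans of a prediction
#'
#' @param spans entity-span data.frame.
#' @param docs document table providing the section texts.
#' @param policy a [merge_policy()].
#' @return the repaired entity-span data.frame (deleted spans removed).
#' @export
adjust_all_brackets <- function(spans, docs, policy = merge_policy()) {
  if (!nrow(spans)) return(spans)
  out <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    txt <- section_text(docs, spans$doc_id[i], spans$section[i])
    out[[i]] <- adjust_brackets(spans[i, , drop = FALSE], txt, policy)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
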