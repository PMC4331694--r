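# Conversion between entity spans and the 8-label tagging scheme.
#
# Both entity ("NER") and non-entity ("normal") stretches are segmented with
# Begin/Middle/End/Single labels, giving the alphabet
#   B, M, E, S          - segments of the normal (non-entity) text
#   B_NER, M_NER, E_NER, S_NER - entity segments
# A "normal sequence" is a maximal run of units between two entities (or a
# sequence end and an entity); this finer-grained scheme distinguishes name
# components better than plain BIO.

#' The CRF label alphabet
#' @return character vector of the 8 labels.
#' @export
crf_labels <- function() c("B", "M", "E", "S", "B_NER", "M_NER", "E_NER", "S_NER")

.ner_labels <- c("B_NER", "M_NER", "E_NER", "S_NER")

.run_labels <- function(n, ner) {
  if (n == 1L) return(if (ner) "S_NER" else "S")
  base <- c("B", rep("M", n - 2L), "E")
  if (ner) paste0(base, "_NER") else base
}

#' Encode gold spans as a label sequence
#'
#' Units covered by a gold span receive `B_NER`/`M_NER`/`E_NER` (or `S_NER`
#' for a single unit); each maximal uncovered run receives `B`/`M`/`E` (or
#' `S`). At word granularity a span whose boundary falls strictly inside a
#' token is snapped outward to the smallest covering token boundaries (with a
#' warning); at character granularity a boundary that falls on no unit is an
#' error.
#'
#' @param seq a `token_sequence`.
#' @param gold entity-span data.frame; rows for other documents/sections than
#'   `seq`'s are ignored.
#' @return character vector of labels, one per unit of `seq`.
#' @export
spans_to_labels <- function(seq, gold) {
  stopifnot(inherits(seq, "token_sequence"))
  n <- length(seq$surface)
  if (!is.na(seq$doc_id)) gold <- gold[gold$doc_id == seq$doc_id, , drop = FALSE]
  if (!is.na(seq$section)) gold <- gold[gold$section == seq$section, , drop = FALSE]
  covered <- logical(n)
  seg <- integer(0)  # first unit index of each entity
  seg_end <- integer(0)
  if (nrow(gold)) {
    gold <- gold[order(gold$start), , drop = FALSE]
    for (i in seq_len(nrow(gold))) {
      s <- gold$start[i]; e <- gold$end[i]
      first <- which(seq$end > s & seq$start < e)
      if (!length(first)) {
        stop(sprintf("gold span [%d,%d) covers no unit of the sequence", s, e))
      }
      lo <- min(first); hi <- max(first)
      exact <- seq$start[lo] == s && seq$end[hi] == e
      if (!exact) {
        if (seq$granularity == "CHAR") {
          stop(sprintf(
            "boundary mismatch: span [%d,%d) does not align with character units [%d,%d)",
            s, e, seq$start[lo], seq$end[hi]))
        }
        warning(sprintf(
          "span [%d,%d) %s snapped outward to token boundaries [%d,%d)",
          s, e, dQuote(gold$text[i]), seq$start[lo], seq$end[hi]))
      }
      if (any(covered[lo:hi])) {
        stop(sprintf("overlapping gold spans at units %d..%d", lo, hi))
      }
      covered[lo:hi] <- TRUE
      seg <- c(seg, lo); seg_end <- c(seg_end, hi)
    }
  }
  labels <- character(n)
  for (k in seq_along(seg)) {
    labels[seg[k]:seg_end[k]] <- .run_labels(seg_end[k] - seg[k] + 1L, TRUE)
  }
  if (n) {
    r <- rle(covered)
    pos <- 1L
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) {
        labels[pos:(pos + r$lengths[j] - 1L)] <- .run_labels(r$lengths[j], FALSE)
      }
      pos <- pos + r$lengths[j]
    }
  }
  labels
}

#' Decode a label sequence back to entity spans
#'
#' Each maximal run of `*_NER` labels becomes one span, regardless of the
#' internal order of the run's labels (standard segment repair: a malformed
#' `M_NER` without a `B_NER` still yields an entity). Works on inverted
#' sequences too, because every unit retains its original offsets.
#'
#' @param seq the `token_sequence` the labels annotate.
#' @param labels character vector of labels, same length as `seq`.
#' @param marginals optional numeric matrix (`length(seq)` x 8, columns in
#'   [crf_labels()] order) of per-position label probabilities; if given, each
#'   span's confidence is the product of the marginals of its assigned labels.
#' @param source value for the `source` column of the result.
#' @return an entity-span data.frame.
#' @export
labels_to_spans <- function(seq, labels, marginals = NULL, source = "GOLD") {
  stopifnot(inherits(seq, "token_sequence"), length(labels) == length(seq$surface))
  n <- length(labels)
  if (!n) return(entity_spans())
  is_ner <- labels %in% .ner_labels
  r <- rle(is_ner)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- list()
  for (j in which(r$values)) {
    run <- starts[j]:ends[j]
    parsed <- .parse_segments(sub("_NER$", "", labels[run]))
    if (is.null(parsed)) {
      segments[[length(segments) + 1L]] <- run  # malformed: repair to one entity
    } else {
      for (p in parsed) segments[[length(segments) + 1L]] <- run[p]
    }
  }
  out <- list()
  for (units in segments) {
    s <- min(seq$start[units]); e <- max(seq$end[units])
    txt <- if (!is.null(seq$text)) .substr0(seq$text, s, e) else
      paste(seq$surface[units], collapse = "")
    conf <- if (is.null(marginals)) 1 else
      prod(marginals[cbind(units, match(labels[units], crf_labels()))])
    out[[length(out) + 1L]] <- entity_spans(
      doc_id = seq$doc_id, section = seq$section, start = s, end = e,
      text = txt, confidence = conf, source = source)
  }
  if (!length(out)) return(entity_spans())
  do.call(rbind, out)
}

#' Re-express spans decoded on an inverted sequence in original orientation
#'
#' Units of an inverted sequence retain their original offsets, so a span
#' over reversed units k..m already carries original-orientation offsets;
#' this re-reads the mention text from the original section and sorts the
#' spans by start offset.
#'
#' @param spans entity-span data.frame decoded from `invert(seq)`.
#' @param seq the original (forward) `token_sequence`.
#' @return entity-span data.frame in original orientation.
#' @export
map_inverted_spans <- function(spans, seq) {
  stopifnot(inherits(seq, "token_sequence"))
  if (!nrow(spans)) return(spans)
  if (!is.null(seq$text)) {
    spans$text <- .substr0(seq$text, spans$start, spans$end)
  }
  spans[order(spans$start, spans$end), , drop = FALSE]
}

# Parse a run of B/M/E/S core labels into complete segments, each a vector of
# indices into the run; NULL if the run does not parse.
.parse_segments <- function(core) {
  n <- length(core)
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (core[i] == "S") {
      segs[[length(segs) + 1L]] <- i
      i <- i + 1L
    } else if (core[i] == "B") {
      j <- i + 1L
      while (j <= n && core[j] == "M") j <- j + 1L
      if (j > n || core[j] != "E") return(NULL)
      segs[[length(segs) + 1L]] <- i:j
      i <- j + 1L
    } else return(NULL)
  }
  segs
}

#' Check label-sequence well-formedness
#'
#' A sequence is well-formed when every segment (entity or normal) is one of
#' `S`, or `B [M]* E`, in its own label family.
#'
#' @param labels character vector over the 8-label alphabet.
#' @return `TRUE` or `FALSE`.
#' @export
labels_wellformed <- function(labels) {
  if (!length(labels)) return(TRUE)
  if (any(!labels %in% crf_labels())) return(FALSE)
  fam <- labels %in% .ner_labels
  core <- sub("_NER$", "", labels)
  r <- rle(fam)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (is.null(.parse_segments(core[starts[j]:ends[j]]))) return(FALSE)
  }
  TRUE
}
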