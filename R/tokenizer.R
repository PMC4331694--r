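# Tokenization into word-level tokens and character-level units.
#
# Chemical names mix Latin stems with digits, brackets, Greek letters and
# punctuation ("(22E,24R)-6β-methoxyergosta-7,22-diene-3β,5α-diol"), so the
# word tokenizer keeps maximal runs of Latin letters together and makes every
# other non-whitespace character its own one-character token. Offsets are
# 0-based, half-open, counted in Unicode code points of the section string.

# Latin-letter runs are one token; any other non-whitespace character is a
# single-character symbol token (digits, brackets, Greek letters, math signs).
.word_token_pattern <- "[\\p{Latin}]+|[^\\p{Latin}\\s]"

#' Construct a token sequence
#'
#' @param surface character vector of unit surfaces.
#' @param start,end integer vectors of 0-based half-open character offsets.
#' @param granularity `"WORD"` or `"CHAR"`.
#' @param doc_id,section identifiers carried along for span conversion
#'   (`section` is `"T"` for title, `"A"` for abstract).
#' @param text the source section text the offsets refer to (kept so spans can
#'   be re-read from the source).
#' @return an object of class `token_sequence`.
#' @keywords internal
new_token_sequence <- function(surface, start, end, granularity,
                               doc_id = NA_character_, section = NA_character_,
                               text = NULL) {
  stopifnot(length(surface) == length(start), length(start) == length(end))
  structure(
    list(surface = as.character(surface),
         start = as.integer(start), end = as.integer(end),
         granularity = match.arg(granularity, c("WORD", "CHAR")),
         doc_id = doc_id, section = section, text = text),
    class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence %s, %d units%s>\n", x$granularity,
              length(x$surface),
              if (!is.na(x$doc_id)) paste0(", doc ", x$doc_id, "/", x$section) else ""))
  if (length(x$surface)) {
    n <- min(length(x$surface), 10L)
    cat(paste(sprintf("  %-12s [%d,%d)", x$surface[seq_len(n)],
                      x$start[seq_len(n)], x$end[seq_len(n)]), collapse = "\n"),
        "\n")
    if (length(x$surface) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Number of units in a token sequence
#' @param x a `token_sequence`.
#' @export
length.token_sequence <- function(x) length(x$surface)

#' Tokenize text into word-level tokens
#'
#' Splits on whitespace; within each chunk, every maximal run of Latin letters
#' is one token and every other character is its own single-character symbol
#' token. Greek letters, digits, brackets and all punctuation are symbol
#' tokens. Concatenating the surfaces and re-inserting the skipped whitespace
#' reconstructs the input exactly.
#'
#' @param text a single string (may be empty).
#' @inheritParams new_token_sequence
#' @return a `token_sequence` with `granularity = "WORD"`.
#' @examples
#' tokenize_words("(±)-methamphetamine")$surface
#' @export
tokenize_words <- function(text, doc_id = NA_character_, section = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(new_token_sequence(character(), integer(), integer(), "WORD",
                              doc_id, section, text))
  }
  m <- gregexpr(.word_token_pattern, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(new_token_sequence(character(), integer(), integer(), "WORD",
                              doc_id, section, text))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  new_token_sequence(regmatches(text, list(m))[[1L]], start, start + len,
                     "WORD", doc_id, section, text)
}

#' Tokenize text into character units
#'
#' One unit per non-whitespace character; whitespace produces no unit.
#'
#' @inheritParams tokenize_words
#' @return a `token_sequence` with `granularity = "CHAR"`.
#' @export
tokenize_chars <- function(text, doc_id = NA_character_, section = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(new_token_sequence(character(), integer(), integer(), "CHAR",
                              doc_id, section, text))
  }
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  keep <- !grepl("^\\s$", ch, perl = TRUE)
  start <- which(keep) - 1L
  new_token_sequence(ch[keep], start, start + 1L, "CHAR", doc_id, section, text)
}

#' Reverse a token sequence (character inverter)
#'
#' Returns the sequence with units in reversed order and each surface reversed
#' character-wise, retaining every unit's original offsets so that spans
#' decoded on the inverted sequence can be mapped back. The operation is an
#' involution: `invert(invert(s))` equals `s`.
#'
#' @param seq a `token_sequence`.
#' @return a `token_sequence` of the same granularity.
#' @export
invert <- function(seq) {
  stopifnot(inherits(seq, "token_sequence"))
  n <- length(seq$surface)
  if (n == 0L) return(seq)
  idx <- rev(seq_len(n))
  rev_surface <- vapply(strsplit(seq$surface[idx], "", fixed = TRUE),
                        function(ch) paste(rev(ch), collapse = ""), character(1L))
  new_token_sequence(rev_surface, seq$start[idx], seq$end[idx],
                     seq$granularity, seq$doc_id, seq$section, seq$text)
}

#' Optional naive sentence splitter
#'
#' Splits a section at a period followed by whitespace and an uppercase Latin
#' letter. Off by default throughout the package: titles and abstracts are
#' treated as one sequence each, so no entity can straddle a split point.
#'
#' @param text a single string.
#' @return integer vector of 0-based sentence start offsets (always contains 0
#'   for non-empty text).
#' @export
sentence_starts <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(integer())
  m <- gregexpr("\\.\\s+(?=[A-Z])", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(0L)
  c(0L, as.integer(m) - 1L + attr(m, "match.length"))
}
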