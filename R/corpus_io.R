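# Reading and writing BioCreative-style corpora: abstracts as tab-separated
# lines, gold annotations as stand-off records, and CDI/CEM prediction files.
#
# File dialects (configurable only in that the formats are plain functions):
#   abstracts:   <doc_id>\t<title>\t<abstract>
#   annotations: <doc_id>\t<T|A>\t<start>\t<end>\t<text>\t<type>
#   CEM output:  <doc_id>\t<T|A>:<start>:<end>\t<rank>\t<confidence>
#   CDI output:  <doc_id>\t<text>\t<rank>\t<confidence>
# Offsets are 0-based, half-open, in Unicode code points of the section string;
# title and abstract offset spaces are independent.

.sections <- c("T", "A")
.span_sources <- c("CHAR_MODEL", "WORD_MODEL", "MERGED", "GOLD")

#' Construct an entity-span table
#'
#' Entity spans are kept as a plain data frame, one row per mention, with
#' 0-based half-open character offsets into the title (`section == "T"`) or
#' abstract (`section == "A"`) of the referenced document.
#'
#' @param doc_id,section,start,end,text,type,confidence,source vectors, one
#'   element per span (recycled scalars allowed for `type`, `confidence`,
#'   `source`).
#' @return a data.frame with columns `doc_id`, `section`, `start`, `end`,
#'   `text`, `type`, `confidence`, `source`.
#' @export
entity_spans <- function(doc_id = character(), section = character(),
                         start = integer(), end = integer(),
                         text = character(), type = "CHEMICAL",
                         confidence = 1, source = "GOLD") {
  n <- length(doc_id)
  out <- data.frame(doc_id = as.character(doc_id),
                    section = as.character(section),
                    start = as.integer(start), end = as.integer(end),
                    text = as.character(text),
                    type = rep_len(as.character(type), n),
                    confidence = rep_len(as.numeric(confidence), n),
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$source), .span_sources)
  if (length(bad)) stop("unknown span source(s): ", paste(bad, collapse = ", "))
  if (any(!out$section %in% .sections)) stop("section must be 'T' or 'A'")
  if (n && any(out$start >= out$end)) stop("spans must satisfy start < end")
  out
}

#' Read a tab-separated abstracts file
#'
#' @param path path to a file with lines `<doc_id>\t<title>\t<abstract>`.
#' @return a data.frame with columns `doc_id`, `title`, `abstract`, one row
#'   per input line, input order preserved.
#' @export
read_abstracts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(doc_id = character(), title = character(),
                      abstract = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    i <- which(nf != 3L)[1L]
    stop(sprintf("malformed abstracts line %d: expected 3 tab-separated fields, got %d",
                 i, nf[i]))
  }
  m <- do.call(rbind, parts)
  if (anyDuplicated(m[, 1L])) stop("duplicated doc_id in abstracts file")
  data.frame(doc_id = m[, 1L], title = m[, 2L], abstract = m[, 3L],
             stringsAsFactors = FALSE)
}

#' Write an abstracts file
#' @param docs data.frame as returned by [read_abstracts()].
#' @param path output path.
#' @export
write_abstracts <- function(docs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(docs)) {
    writeLines(paste(docs$doc_id, docs$title, docs$abstract, sep = "\t"), con)
  }
  invisible(path)
}

#' Section text lookup
#'
#' @param docs document table.
#' @param doc_id document identifier.
#' @param section `"T"` (title) or `"A"` (abstract).
#' @return the section string.
#' @export
section_text <- function(docs, doc_id, section) {
  i <- match(doc_id, docs$doc_id)
  if (is.na(i)) stop("unknown doc_id: ", doc_id)
  if (identical(section, "T")) docs$title[i]
  else if (identical(section, "A")) docs$abstract[i]
  else stop("section must be 'T' or 'A'")
}

# substring by 0-based half-open character offsets (vectorized over offsets)
.substr0 <- function(text, start, end) substring(text, start + 1L, end)

#' Read a stand-off annotation file
#'
#' Every record is validated against the referenced document: the record's
#' text field must equal the substring of the section at `[start, end)`.
#'
#' @param path path to a file with lines
#'   `<doc_id>\t<T|A>\t<start>\t<end>\t<text>\t<type>`.
#' @param docs document table the records refer to.
#' @return an entity-span data.frame with `source = "GOLD"`, `confidence = 1`.
#' @export
read_annotations <- function(path, docs) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(entity_spans())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    i <- which(nf != 6L)[1L]
    stop(sprintf("malformed annotation line %d: expected 6 fields, got %d", i, nf[i]))
  }
  m <- do.call(rbind, parts)
  spans <- entity_spans(doc_id = m[, 1L], section = m[, 2L],
                        start = as.integer(m[, 3L]), end = as.integer(m[, 4L]),
                        text = m[, 5L], type = m[, 6L],
                        confidence = 1, source = "GOLD")
  validate_spans(spans, docs)
  spans
}

#' Validate spans against their documents
#'
#' Checks that offsets are in range and that each span's `text` equals the
#' section substring at `[start, end)`.
#'
#' @param spans entity-span data.frame.
#' @param docs document table.
#' @return `spans`, invisibly; stops with an informative error otherwise.
#' @export
validate_spans <- function(spans, docs) {
  for (i in seq_len(nrow(spans))) {
    txt <- section_text(docs, spans$doc_id[i], spans$section[i])
    if (spans$start[i] < 0L || spans$end[i] > nchar(txt)) {
      stop(sprintf("span out of range in %s/%s: [%d,%d) over %d characters",
                   spans$doc_id[i], spans$section[i],
                   spans$start[i], spans$end[i], nchar(txt)))
    }
    sub <- .substr0(txt, spans$start[i], spans$end[i])
    if (!identical(sub, spans$text[i])) {
      stop(sprintf("span text mismatch in %s/%s [%d,%d): file says %s, document has %s",
                   spans$doc_id[i], spans$section[i], spans$start[i], spans$end[i],
                   dQuote(spans$text[i]), dQuote(sub)))
    }
  }
  invisible(spans)
}

#' Write an annotation file
#' @param spans entity-span data.frame.
#' @param path output path.
#' @export
write_annotations <- function(spans, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(spans)) {
    writeLines(paste(spans$doc_id, spans$section, spans$start, spans$end,
                     spans$text, spans$type, sep = "\t"), con)
  }
  invisible(path)
}

# rank order within one document: descending confidence, then earlier start,
# then shorter span (deterministic tie-break)
.rank_order <- function(df) order(-df$confidence, df$start, df$end - df$start)

#' Write a CDI or CEM prediction file
#'
#' CEM mode writes one line per span with a `section:start:end` locator. CDI
#' mode reduces to one line per unique mention string per document, carrying
#' the maximum confidence over that string's spans. Ranks are 1-based and
#' contiguous per document, by descending confidence (ties: earlier start,
#' then shorter span).
#'
#' @param spans entity-span data.frame with confidences set.
#' @param task `"CDI"` or `"CEM"`.
#' @param path output path.
#' @export
write_predictions <- function(spans, task = c("CEM", "CDI"), path) {
  task <- match.arg(task)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!nrow(spans)) return(invisible(path))
  out <- character()
  for (id in unique(spans$doc_id)) {
    d <- spans[spans$doc_id == id, , drop = FALSE]
    if (task == "CEM") {
      d <- d[.rank_order(d), , drop = FALSE]
      out <- c(out, paste(d$doc_id,
                          paste0(d$section, ":", d$start, ":", d$end),
                          seq_len(nrow(d)),
                          format(d$confidence, scientific = FALSE, trim = TRUE),
                          sep = "\t"))
    } else {
      conf <- tapply(d$confidence, d$text, max)
      # representative row per string for the tie-break offsets
      first <- d[!duplicated(d$text), , drop = FALSE]
      first$confidence <- as.numeric(conf[first$text])
      first <- first[.rank_order(first), , drop = FALSE]
      out <- c(out, paste(first$doc_id, first$text, seq_len(nrow(first)),
                          format(first$confidence, scientific = FALSE, trim = TRUE),
                          sep = "\t"))
    }
  }
  writeLines(out, con)
  invisible(path)
}

#' Read a CDI or CEM prediction file
#'
#' Inverse of [write_predictions()]. CEM locators are resolved against the
#' document table; CDI records (which carry no offsets) are returned with the
#' mention string and zero-width placeholder offsets unset (`NA`).
#'
#' @param path prediction file.
#' @param task `"CDI"` or `"CEM"`.
#' @param docs document table (required for CEM, used to re-read mention
#'   text).
#' @return a data.frame shaped like [entity_spans()] (for CDI, `start`/`end`
#'   are `NA`).
#' @export
read_predictions <- function(path, task = c("CEM", "CDI"), docs = NULL) {
  task <- match.arg(task)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(entity_spans())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    stop(sprintf("malformed prediction line %d: expected 4 fields, got %d",
                 which(nf != 4L)[1L], nf[nf != 4L][1L]))
  }
  m <- do.call(rbind, parts)
  if (task == "CDI") {
    out <- data.frame(doc_id = m[, 1L], section = NA_character_,
                      start = NA_integer_, end = NA_integer_, text = m[, 2L],
                      type = "CHEMICAL", confidence = as.numeric(m[, 4L]),
                      source = "MERGED", stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(docs)) stop("CEM predictions need the document table")
  loc <- strsplit(m[, 2L], ":", fixed = TRUE)
  if (any(lengths(loc) != 3L)) stop("malformed CEM locator")
  lm <- do.call(rbind, loc)
  spans <- entity_spans(doc_id = m[, 1L], section = lm[, 1L],
                        start = as.integer(lm[, 2L]), end = as.integer(lm[, 3L]),
                        text = "", confidence = as.numeric(m[, 4L]),
                        source = "MERGED")
  for (i in seq_len(nrow(spans))) {
    txt <- section_text(docs, spans$doc_id[i], spans$section[i])
    spans$text[i] <- .substr0(txt, spans$start[i], spans$end[i])
  }
  spans
}
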