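# Expansion of the n-gram feature templates into per-unit feature strings.
#
# Character level (23 templates per position): unigrams at offsets -4..+4 and
# all contiguous n-grams of orders 2..5 that include position i. Word level
# (13 templates per stream): unigrams at offsets -2..+2, 2-grams, and the
# 4-token windows (i-3..i) .. (i..i+3); cluster streams repeat the same 13
# templates over cluster labels (one stream for Brown codes, one per scale
# for multi-scale k-means ids). Positions beyond the sequence use distinct
# boundary sentinels _B-k / _E+k, so every template fires at every position.

# spans (a, b) of offsets relative to i, for the character template set
.char_spans <- list(
  c(-1L, 0L), c(0L, 1L),                                  # 2-grams
  c(-2L, 0L), c(-1L, 1L), c(0L, 2L),                      # 3-grams
  c(-3L, 0L), c(-2L, 1L), c(-1L, 2L), c(0L, 3L),          # 4-grams
  c(-4L, 0L), c(-3L, 1L), c(-2L, 2L), c(-1L, 3L), c(0L, 4L)) # 5-grams
.char_uni <- -4L:4L

.word_spans <- list(
  c(-2L, -1L), c(-1L, 0L), c(0L, 1L), c(1L, 2L),          # 2-grams
  c(-3L, 0L), c(-2L, 1L), c(-1L, 2L), c(0L, 3L))          # 4-token windows
.word_uni <- -2L:2L

# values: character vector (one per unit); returns matrix n x n_templates of
# "<prefix><name>:<joined values>" strings
.expand_templates <- function(values, uni, spans, prefix) {
  n <- length(values)
  pad <- max(4L, -min(uni), max(uni),
             max(vapply(spans, function(s) max(abs(s)), integer(1L))))
  p <- c(sprintf("_B-%d", pad:1), values, sprintf("_E+%d", 1:pad))
  cols <- list()
  for (d in uni) {
    cols[[sprintf("%sU%+d", prefix, d)]] <- p[seq_len(n) + pad + d]
  }
  for (s in spans) {
    v <- p[seq_len(n) + pad + s[1L]]
    for (d in (s[1L] + 1L):s[2L]) v <- paste(v, p[seq_len(n) + pad + d], sep = "/")
    cols[[sprintf("%sG%+d_%+d", prefix, s[1L], s[2L])]] <- v
  }
  out <- matrix("", nrow = n, ncol = length(cols),
                dimnames = list(NULL, names(cols)))
  for (j in seq_along(cols)) {
    out[, j] <- paste0(names(cols)[j], ":", cols[[j]])
  }
  out
}

#' Character-level feature matrix
#'
#' Expands the 23 character templates (unigrams at offsets -4..+4 and the
#' contiguous 2- to 5-grams that include the position) for every unit.
#'
#' @param seq a `token_sequence` with `granularity = "CHAR"`.
#' @return a character matrix, one row per unit, with attribute
#'   `template_id = "CHAR"`.
#' @export
char_features <- function(seq) {
  stopifnot(inherits(seq, "token_sequence"))
  if (seq$granularity != "CHAR") stop("char_features requires CHAR granularity")
  out <- .expand_templates(seq$surface, .char_uni, .char_spans, "c")
  attr(out, "template_id") <- "CHAR"
  out
}

#' Word-level feature matrix
#'
#' Expands the 13 word templates over token surfaces and, depending on
#' `mode`, the same 13 templates over cluster labels: one stream of Brown
#' path codes (`"BROWN"`) or one stream of k-means ids per trained scale
#' (`"MULTISCALE"`). `"NONE"` is the baseline without cluster features.
#'
#' @param seq a `token_sequence` with `granularity = "WORD"`.
#' @param clusters a `cluster_model` (required unless `mode = "NONE"`).
#' @param mode `"NONE"`, `"BROWN"` or `"MULTISCALE"`.
#' @return a character matrix, one row per unit, with attribute
#'   `template_id` recording the mode and scales.
#' @export
word_features <- function(seq, clusters = NULL,
                          mode = c("NONE", "BROWN", "MULTISCALE")) {
  stopifnot(inherits(seq, "token_sequence"))
  if (seq$granularity != "WORD") stop("word_features requires WORD granularity")
  mode <- match.arg(mode)
  if (mode != "NONE" && is.null(clusters)) {
    stop("cluster mode ", mode, " requires a cluster_model")
  }
  out <- .expand_templates(seq$surface, .word_uni, .word_spans, "w")
  template_id <- "WORD"
  if (mode == "BROWN") {
    idx <- match(seq$surface, clusters$vocab)
    codes <- clusters$brown_code[clusters$vocab][idx]
    codes[is.na(codes)] <- clusters$brown_code[[clusters$unknown_token]]
    out <- cbind(out, .expand_templates(unname(codes), .word_uni, .word_spans, "b"))
    template_id <- "WORD+BROWN"
  } else if (mode == "MULTISCALE") {
    if (!length(clusters$kmeans_ids)) stop("cluster_model has no k-means scales")
    for (k in names(clusters$kmeans_ids)) {
      ids <- clusters$kmeans_ids[[k]]
      v <- ids[match(seq$surface, names(ids))]
      v[is.na(v)] <- ids[[clusters$unknown_token]]
      out <- cbind(out, .expand_templates(as.character(v), .word_uni,
                                          .word_spans, paste0("k", k, ".")))
    }
    template_id <- paste0("WORD+MS{", paste(names(clusters$kmeans_ids),
                                            collapse = ","), "}")
  }
  attr(out, "template_id") <- template_id
  out
}
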