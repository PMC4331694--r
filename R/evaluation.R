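# Micro-averaged precision / recall / F scoring for the two tasks:
#   CEM - a prediction is correct iff (doc_id, section, start, end) exactly
#         matches a gold span;
#   CDI - gold and predictions reduce to per-document sets of unique mention
#         strings (case-sensitive by default) before set comparison.

.report <- function(task, tp, fp, fn) {
  if (tp + fp + fn == 0L) {
    p <- r <- f <- 1  # both sets empty: fixed point
  } else {
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  structure(list(task = task, tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f_score = f),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s: TP=%d FP=%d FN=%d\n", x$task, x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.5f  recall %.5f  F-score %.5f\n",
              x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Score mention-level (CEM) predictions
#'
#' @param gold,pred entity-span data.frames over the same document set.
#' @return an `eval_report` (micro-averaged).
#' @export
evaluate_cem <- function(gold, pred) {
  gk <- unique(paste(gold$doc_id, gold$section, gold$start, gold$end, sep = "\r"))
  pk <- unique(paste(pred$doc_id, pred$section, pred$start, pred$end, sep = "\r"))
  tp <- length(intersect(gk, pk))
  .report("CEM", tp, length(pk) - tp, length(gk) - tp)
}

#' Score document-indexing (CDI) predictions
#'
#' @inheritParams evaluate_cem
#' @param casefold lowercase mention strings before comparison (the default
#'   is exact, case-sensitive matching).
#' @return an `eval_report` (micro-averaged).
#' @export
evaluate_cdi <- function(gold, pred, casefold = FALSE) {
  key <- function(d) {
    txt <- if (casefold) tolower(d$text) else d$text
    unique(paste(d$doc_id, txt, sep = "\r"))
  }
  gk <- key(gold); pk <- key(pred)
  tp <- length(intersect(gk, pk))
  .report("CDI", tp, length(pk) - tp, length(gk) - tp)
}
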