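# Linear-chain CRF training and decoding over the 8-label scheme.
#
# State features tie a feature string to a label; label-pair transitions are
# first order. Training maximizes the L2-regularized conditional
# log-likelihood with L-BFGS (stats::optim); decoding returns the Viterbi
# path plus per-position marginals from forward-backward, from which entity
# confidences are computed as products of the assigned labels' marginals.

#' Train a linear-chain CRF
#'
#' @param data list of training sequences; each element a list with
#'   `features` (character matrix from [char_features()] or
#'   [word_features()]) and `labels` (character vector over [crf_labels()],
#'   same length as the matrix has rows).
#' @param l2 L2 regularization coefficient (penalty `l2/2 * ||theta||^2`).
#' @param max_iter maximum L-BFGS iterations.
#' @param seed kept for interface stability; training is deterministic given
#'   the data order (zero initialization, batch optimization).
#' @param meta named list recorded on the model (granularity, direction,
#'   cluster mode and the like).
#' @param verbose print optimizer progress.
#' @return a `crf_model`.
#' @export
train_crf <- function(data, l2 = 1.0, max_iter = 150L, seed = 1L,
                      meta = list(), verbose = FALSE) {
  if (!length(data)) stop("empty training data")
  template_id <- attr(data[[1L]]$features, "template_id")
  arity <- ncol(data[[1L]]$features)
  for (d in data) {
    if (nrow(d$features) != length(d$labels)) {
      stop("features and labels misaligned: ", nrow(d$features), " rows vs ",
           length(d$labels), " labels")
    }
    if (ncol(d$features) != arity) stop("inconsistent template arity across sequences")
    if (any(!d$labels %in% crf_labels())) stop("unknown label in training data")
  }
  labels <- crf_labels()
  L <- length(labels)
  # one global feature index (order of first appearance, deterministic)
  all_feats <- unlist(lapply(data, function(d) as.vector(d$features)),
                      use.names = FALSE)
  feat_index <- unique(all_feats)
  ids <- match(all_feats, feat_index)
  sizes <- vapply(data, function(d) length(d$features), integer(1L))
  offsets <- cumsum(c(0L, sizes))
  feats_list <- vector("list", length(data))
  y_list <- vector("list", length(data))
  for (s in seq_along(data)) {
    n <- nrow(data[[s]]$features)
    feats_list[[s]] <- matrix(ids[(offsets[s] + 1L):offsets[s + 1L]],
                              nrow = n, ncol = arity)
    y_list[[s]] <- match(data[[s]]$labels, labels)
  }
  FN <- length(feat_index)
  npar <- FN * L + L * L
  par0 <- numeric(npar)
  objective <- function(par) {
    W <- matrix(par[seq_len(FN * L)], FN, L)
    Tr <- matrix(par[FN * L + seq_len(L * L)], L, L)
    r <- crf_nll_grad_cpp(feats_list, y_list, W, Tr)
    val <- r$nll + 0.5 * l2 * sum(par^2)
    attr(val, "gradient") <- c(r$gW, r$gT) + l2 * par
    val
  }
  grad_cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    v <- objective(par)
    grad_cache$par <- par
    grad_cache$grad <- attr(v, "gradient")
    as.numeric(v)
  }
  gr <- function(par) {
    if (!is.null(grad_cache$par) && identical(grad_cache$par, par)) {
      return(grad_cache$grad)
    }
    attr(objective(par), "gradient")
  }
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = as.integer(max_iter),
                                     factr = 1e7,
                                     trace = if (verbose) 1L else 0L))
  W <- matrix(opt$par[seq_len(FN * L)], FN, L)
  Tr <- matrix(opt$par[FN * L + seq_len(L * L)], L, L)
  structure(list(labels = labels, features = feat_index, W = W, Tr = Tr,
                 l2 = l2, template_id = template_id,
                 meta = meta, nll = opt$value, convergence = opt$convergence),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model: %d features x %d labels, templates %s%s>\n",
              length(x$features), length(x$labels), x$template_id,
              if (length(x$meta)) paste0(", ",
                paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "))
              else ""))
  invisible(x)
}

#' Decode a sequence with a trained CRF
#'
#' @param model a `crf_model`.
#' @param features character feature matrix built with the model's template
#'   set (its `template_id` must match).
#' @return a `crf_decoding`: list with `labels` (Viterbi path),
#'   `marginals` (matrix, one row per position, columns [crf_labels()]),
#'   `log_z`, and `path_probability` (conditional probability of the path).
#' @export
decode_crf <- function(model, features) {
  stopifnot(inherits(model, "crf_model"))
  tid <- attr(features, "template_id")
  if (!is.null(tid) && !identical(tid, model$template_id)) {
    stop("template mismatch: model built with ", model$template_id,
         ", features are ", tid)
  }
  ids <- match(as.vector(features), model$features)
  ids[is.na(ids)] <- 0L  # unseen features contribute nothing
  m <- matrix(ids, nrow = nrow(features), ncol = ncol(features))
  r <- crf_infer_cpp(m, model$W, model$Tr)
  marg <- r$marginals
  colnames(marg) <- model$labels
  structure(list(labels = model$labels[r$path], marginals = marg,
                 log_z = r$logZ, path_probability = exp(r$log_prob_path)),
            class = "crf_decoding")
}

#' Confidence of a decoded entity segment
#'
#' The product over the segment's positions of the marginal probability of
#' the assigned label — monotone in per-position certainty and in `[0, 1]`.
#'
#' @param dec a `crf_decoding`.
#' @param units integer vector of (contiguous) position indices.
#' @return a probability.
#' @export
entity_confidence <- function(dec, units) {
  stopifnot(inherits(dec, "crf_decoding"))
  prod(dec$marginals[cbind(units, match(dec$labels[units], colnames(dec$marginals)))])
}

#' Serialize a CRF model to a plain-text file
#'
#' Versioned text format; weights are written with 17 significant digits so
#' the round trip preserves decoding behavior bit-exactly.
#'
#' @param model a `crf_model`.
#' @param path output path.
#' @export
write_crf_model <- function(model, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("chemner-crf 1",
               paste("template_id", model$template_id),
               paste("l2", sprintf("%.17g", model$l2)),
               paste("meta", length(model$meta))), con)
  for (k in names(model$meta)) writeLines(paste0(k, "\t", model$meta[[k]]), con)
  writeLines(paste("labels", paste(model$labels, collapse = " ")), con)
  writeLines("transitions", con)
  writeLines(apply(model$Tr, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(paste("features", length(model$features)), con)
  if (length(model$features)) {
    writeLines(paste(model$features,
                     apply(model$W, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a CRF model written by [write_crf_model()]
#' @param path input path.
#' @return a `crf_model`.
#' @export
read_crf_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stopifnot(lines[1L] == "chemner-crf 1")
  template_id <- sub("^template_id ", "", lines[2L])
  l2 <- as.numeric(sub("^l2 ", "", lines[3L]))
  n_meta <- as.integer(sub("^meta ", "", lines[4L]))
  meta <- list()
  i <- 5L
  for (j in seq_len(n_meta)) {
    kv <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- kv[2L]
    i <- i + 1L
  }
  labels <- strsplit(sub("^labels ", "", lines[i]), " ", fixed = TRUE)[[1L]]
  L <- length(labels)
  stopifnot(lines[i + 1L] == "transitions")
  Tr <- do.call(rbind, lapply(lines[(i + 2L):(i + 1L + L)], function(x)
    as.numeric(strsplit(x, " ", fixed = TRUE)[[1L]])))
  i <- i + 2L + L
  FN <- as.integer(sub("^features ", "", lines[i]))
  features <- character(FN)
  W <- matrix(0, FN, L)
  if (FN > 0L) {
    body <- lines[(i + 1L):(i + FN)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    features <- vapply(parts, `[[`, character(1L), 1L)
    W <- do.call(rbind, lapply(parts, function(p)
      as.numeric(strsplit(p[[2L]], " ", fixed = TRUE)[[1L]])))
  }
  structure(list(labels = labels, features = features, W = W, Tr = Tr,
                 l2 = l2, template_id = template_id, meta = meta),
            class = "crf_model")
}
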