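# Question-conditioned span extraction (the core method).
#
# Pipeline: lay the input out as (CLS, q_1..q_m, SEP, x_1..x_n), encode,
# project the report rows E (n x d) through learned d x 2 matrices T_start
# and T_end, soft-max each row into start/end position probabilities,
# binarize by row argmax, and pair start/end markers by sequential matching.
# Training minimizes the sum of per-position cross-entropies of the two
# heads.
#
# Probability rows put the positive ("is boundary") class in column 1, so a
# row like (0.8, 0.2) marks a boundary and (0.3, 0.7) does not. Span pairs
# are reported in 1-based inclusive positions (the convention of the
# decoding examples); annotations use the package-wide 0-based half-open
# convention, with converters in evaluation.R.

#' The default extraction question
#'
#' "Find the DWI high-signal parts in the report" (in Chinese, normalized
#' form). Changing the question retargets the extractor, e.g. to all body
#' parts, without code change.
#' @return a string
#' @export
default_question <- function() {
  "\u627e\u51fa\u62a5\u544a\u4e2ddwi\u9ad8\u4fe1\u53f7\u90e8\u4f4d"
}

#' Build the question-conditioned model input
#'
#' Lays out (CLS, q, SEP, x) token ids, truncating the report so the total
#' length does not exceed `max_length`. Annotations extending past the
#' truncation point are dropped with a warning.
#'
#' @param question nonempty question string
#' @param report a `report_document` or a plain string
#' @param vocab a `dwispan_vocab`
#' @param max_length total input length cap (default 400)
#' @return object of class `mrc_input` with fields `tokens` (0-based ids),
#'   `m`, `n`, `report_offset` (0-based index of x_1), `text`,
#'   `annotations`, `doc_id`
#' @export
build_mrc_input <- function(question, report, vocab, max_length = 400L) {
  if (!nzchar(question))
    stop_dwispan("question must be nonempty", "dwispan_bad_question")
  if (is.character(report)) report <- report_document("doc", report)
  q_ids <- vocab_ids(vocab, question)
  m <- length(q_ids)
  n_room <- max_length - m - 2L
  if (n_room < 1L)
    stop_dwispan("question alone exceeds max_length", "dwispan_too_long")
  text <- report$text
  n_full <- nchar(text)
  n <- min(n_full, n_room)
  ann <- report$annotations
  if (n < n_full) {
    keep <- ann$end <= n
    if (any(!keep))
      warning(sprintf("%s: %d annotation(s) beyond truncation at %d dropped",
                      report$doc_id, sum(!keep), n), call. = FALSE)
    ann <- ann[keep, , drop = FALSE]
    text <- substring(text, 1L, n)
  }
  x_ids <- if (n > 0L) vocab_ids(vocab, text) else integer(0)
  structure(list(tokens = c(vocab$cls_id, q_ids, vocab$sep_id, x_ids),
                 m = m, n = n, report_offset = m + 2L,
                 text = text, annotations = ann, doc_id = report$doc_id,
                 question = question),
            class = "mrc_input")
}

#' Per-position boundary probabilities
#'
#' Computes softmax_each_row(E T), an n x 2 row-stochastic matrix; column 1
#' is the probability that the character is a boundary (start or end,
#' depending on which projection is supplied).
#'
#' @param E n x d encoded matrix
#' @param T_mat d x 2 projection (`T_start` or `T_end`)
#' @param role "start" or "end" (metadata only)
#' @return matrix of class `position_probs`
#' @export
position_probabilities <- function(E, T_mat, role = c("start", "end")) {
  role <- match.arg(role)
  if (ncol(E) != nrow(T_mat))
    stop_dwispan("dimension mismatch between E and T", "dwispan_dim_mismatch")
  if (ncol(T_mat) != 2L)
    stop_dwispan("T must have exactly 2 columns", "dwispan_dim_mismatch")
  P <- softmax_rows(E %*% T_mat)
  structure(P, class = c("position_probs", class(P)), role = role)
}

#' Binarize position probabilities by row argmax
#'
#' Position i is marked 1 iff the positive column is the strict row
#' maximum; exact ties resolve to 0 (no boundary), a conservative
#' tie-break.
#'
#' @param P a `position_probs` matrix (or any n x 2 matrix)
#' @return integer 0/1 vector of length n
#' @export
indicators <- function(P) {
  as.integer(P[, 1L] > P[, 2L])
}

#' Pair start/end markers into spans by sequential matching
#'
#' Scans positions in ascending order; each start marker is paired with the
#' earliest unused end marker at a position at or after it; a start falling
#' inside an already-formed span is discarded, as are unmatched markers.
#' The returned pairs are non-overlapping and ordered; positions are
#' 1-based inclusive.
#'
#' @param i_start,i_end equal-length 0/1 indicator vectors
#' @return data.frame with columns `start`, `end`
#' @export
match_spans <- function(i_start, i_end) {
  if (length(i_start) != length(i_end))
    stop_dwispan("indicator length mismatch", "dwispan_length_mismatch")
  starts <- which(i_start == 1L)
  ends <- which(i_end == 1L)
  out_s <- integer(0); out_e <- integer(0)
  e_ptr <- 1L
  last_end <- 0L
  for (s in starts) {
    if (s <= last_end) next                 # inside the previous span
    while (e_ptr <= length(ends) && ends[e_ptr] < s) e_ptr <- e_ptr + 1L
    if (e_ptr > length(ends)) break
    out_s <- c(out_s, s); out_e <- c(out_e, ends[e_ptr])
    last_end <- ends[e_ptr]
    e_ptr <- e_ptr + 1L
  }
  data.frame(start = out_s, end = out_e)
}

#' Gold start/end position labels for a report
#'
#' `y_start` is 1 exactly at DWI high-signal span starts and `y_end` at
#' their (inclusive) ends; other-part spans contribute nothing. Positions
#' are 1-based over the (possibly truncated) report.
#'
#' @param doc a `report_document` or `mrc_input`
#' @param target_label which label constitutes a positive span (default
#'   "DWI_HIGH"; set to e.g. c("DWI_HIGH","OTHER_PART","PART") when the
#'   question targets all parts)
#' @return list with integer vectors `y_start`, `y_end`
#' @export
spans_to_gold_labels <- function(doc, target_label = "DWI_HIGH") {
  n <- if (inherits(doc, "mrc_input")) doc$n else nchar(doc$text)
  ann <- doc$annotations
  ann <- ann[ann$label %in% target_label, , drop = FALSE]
  y_start <- integer(n); y_end <- integer(n)
  if (nrow(ann) > 0L) {
    y_start[ann$start + 1L] <- 1L
    y_end[ann$end] <- 1L                    # half-open end == 1-based incl.
  }
  list(y_start = y_start, y_end = y_end)
}

#' Summed start/end cross-entropy loss
#'
#' Two-class cross-entropy averaged over positions, computed separately for
#' the start and end heads and summed. Probabilities are clamped at 1e-12
#' inside the logarithm.
#'
#' @param p_start,p_end n x 2 position-probability matrices
#' @param labels gold labels from [spans_to_gold_labels()]
#' @param positive_weight optional weight for positive positions (default
#'   NULL: plain cross-entropy)
#' @return list with `l_start`, `l_end`, `total`
#' @export
mrc_loss <- function(p_start, p_end, labels, positive_weight = NULL) {
  head_loss <- function(P, y) {
    n <- length(y)
    if (nrow(P) != n)
      stop_dwispan("probability/label shape mismatch",
                   "dwispan_dim_mismatch")
    col <- ifelse(y == 1L, 1L, 2L)
    p <- pmax(P[cbind(seq_len(n), col)], 1e-12)
    wts <- rep(1, n)
    if (!is.null(positive_weight)) wts[y == 1L] <- positive_weight
    sum(wts * -log(p)) / n
  }
  l_start <- head_loss(p_start, labels$y_start)
  l_end <- head_loss(p_end, labels$y_end)
  list(l_start = l_start, l_end = l_end, total = l_start + l_end)
}

# gradient of the (possibly weighted) mean cross-entropy w.r.t. logits
head_dlogits <- function(P, y, positive_weight = NULL) {
  n <- length(y)
  Y <- cbind(as.numeric(y == 1L), as.numeric(y != 1L))
  G <- (P - Y) / n
  if (!is.null(positive_weight)) G[y == 1L, ] <- G[y == 1L, ] * positive_weight
  G
}

#' Train the question-conditioned span extractor
#'
#' @param train_docs nonempty list of `report_document`s
#' @param question extraction question (default [default_question()])
#' @param encoder_cfg an [encoder_config()]
#' @param train_cfg a [training_config()]; defaults are the reference
#'   hyperparameters (lr 3e-5, batch 32, 5 epochs, Adam)
#' @param target_label label(s) counted as positive spans
#' @param verbose print per-epoch loss
#' @return object of class `mrc_model` with fields `weights`,
#'   `encoder_config`, `vocab`, `question`, `history` (per-epoch mean loss)
#' @export
train_mrc <- function(train_docs, question = default_question(),
                      encoder_cfg = encoder_config(),
                      train_cfg = training_config(),
                      target_label = "DWI_HIGH", verbose = FALSE) {
  if (length(train_docs) == 0L)
    stop_dwispan("empty training corpus", "dwispan_empty_corpus")
  vocab <- build_vocab(train_docs, question)
  if (length(encoder_cfg$segment_ids) == 0L)
    encoder_cfg$segment_ids <- segment_break_ids(vocab)
  d <- encoder_cfg$hidden_dim
  weights <- init_encoder_weights(encoder_cfg, vocab$size)
  weights$T_start <- matrix(0, d, 2L)
  weights$T_end <- matrix(0, d, 2L)

  inputs <- lapply(train_docs, function(doc)
    build_mrc_input(question, doc, vocab, encoder_cfg$max_length))
  labels <- lapply(inputs, spans_to_gold_labels, target_label = target_label)
  keep <- vapply(inputs, function(x) x$n > 0L, logical(1))
  inputs <- inputs[keep]; labels <- labels[keep]

  state <- adam_init(weights)
  history <- numeric(train_cfg$epochs)
  pw <- train_cfg$positive_weight
  warmup_steps <- as.integer(round(train_cfg$warmup_frac * train_cfg$epochs *
                                     ceiling(length(inputs) /
                                               train_cfg$batch_size)))
  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      perm <- sample.int(length(inputs))
      batch_starts <- seq(1L, length(perm), by = train_cfg$batch_size)
      epoch_loss <- 0
      for (bs in batch_starts) {
        idx <- perm[bs:min(bs + train_cfg$batch_size - 1L, length(perm))]
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          inp <- inputs[[i]]
          fwd <- encoder_forward(inp$tokens, weights, encoder_cfg,
                                 train = TRUE)
          rows <- (inp$report_offset + 1L):(inp$report_offset + inp$n)
          E <- fwd$E[rows, , drop = FALSE]
          Ps <- softmax_rows(E %*% weights$T_start)
          Pe <- softmax_rows(E %*% weights$T_end)
          loss <- mrc_loss(Ps, Pe, labels[[i]], pw)
          batch_loss <- batch_loss + loss$total
          Gs <- head_dlogits(Ps, labels[[i]]$y_start, pw)
          Ge <- head_dlogits(Pe, labels[[i]]$y_end, pw)
          dE <- Gs %*% t(weights$T_start) + Ge %*% t(weights$T_end)
          dE_full <- matrix(0, length(inp$tokens), d)
          dE_full[rows, ] <- dE
          g <- encoder_backward(dE_full, fwd, weights, encoder_cfg)
          g$T_start <- crossprod(E, Gs)
          g$T_end <- crossprod(E, Ge)
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(x) x / length(idx))
        upd <- adam_step(weights, grads, state, train_cfg$learning_rate,
                         beta1 = train_cfg$beta1, beta2 = train_cfg$beta2,
                         update_scale = train_cfg$update_scale,
                         warmup = warmup_steps)
        weights <- upd$weights
        state <- upd$state
        epoch_loss <- epoch_loss + batch_loss
      }
      history[epoch] <- epoch_loss / length(inputs)
      if (!is.finite(history[epoch]))
        stop_dwispan(sprintf("training diverged at epoch %d (loss %s)",
                             epoch, history[epoch]), "dwispan_divergence")
      if (verbose)
        message(sprintf("epoch %d: mean loss %.5f", epoch, history[epoch]))
    }
  })
  structure(list(weights = weights, encoder_config = encoder_cfg,
                 training_config = train_cfg, vocab = vocab,
                 question = question, target_label = target_label,
                 history = history),
            class = "mrc_model")
}

#' @export
print.mrc_model <- function(x, ...) {
  cat(sprintf(
    "<mrc_model> %s encoder d=%d, %d layers; question \"%s\"; final loss %.4f\n",
    x$encoder_config$kind, x$encoder_config$hidden_dim,
    x$encoder_config$n_layers, x$question, utils::tail(x$history, 1L)))
  invisible(x)
}

#' Predict DWI high-signal spans for one report
#'
#' Runs the full pipeline (build input, encode, position probabilities,
#' indicators, sequential matching) and converts the resulting 1-based
#' inclusive pairs into 0-based half-open annotations.
#'
#' @param model a trained `mrc_model`
#' @param report a `report_document`
#' @param question question override (default: the model's question)
#' @return annotation data.frame (label `DWI_HIGH`)
#' @export
predict_spans <- function(model, report, question = NULL) {
  question <- question %||% model$question
  out_label <- if (identical(model$target_label, "DWI_HIGH")) "DWI_HIGH"
               else "PART"
  if (nchar(report$text) == 0L) return(span_annotations())
  inp <- build_mrc_input(question, report, model$vocab,
                         model$encoder_config$max_length)
  if (inp$n == 0L) return(span_annotations())
  E <- encode_sequence(inp, model$weights, model$encoder_config)
  Ps <- position_probabilities(E, model$weights$T_start, "start")
  Pe <- position_probabilities(E, model$weights$T_end, "end")
  pairs <- match_spans(indicators(Ps), indicators(Pe))
  if (nrow(pairs) == 0L) return(span_annotations())
  span_annotations(doc_id = report$doc_id,
                   start = pairs$start - 1L, end = pairs$end,
                   label = out_label,
                   surface = substring(inp$text, pairs$start, pairs$end))
}

#' Predict spans for a list of reports
#' @param model a trained `mrc_model`
#' @param docs list of `report_document`s
#' @return combined annotation data.frame
#' @export
predict_corpus <- function(model, docs) {
  do.call(rbind, c(list(span_annotations()),
                   lapply(docs, function(d) predict_spans(model, d))))
}
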