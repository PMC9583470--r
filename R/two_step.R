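# The comparison system: classical two-step fine-grained typing.
#
# Stage 1 recognizes all body parts with BIOES sequence labeling (encoder
# emissions + linear-chain CRF; one generic PART label, legality enforced
# at decode through transition masking). Stage 2 classifies each recognized
# mention into DWI-high vs other using concatenated mention and context
# representations. Errors made by stage 1 propagate into stage 2, which is
# precisely the failure mode the one-step reading-comprehension extractor
# avoids.

NER_TAGS <- c("O", "B-PART", "I-PART", "E-PART", "S-PART")

# transitions illegal under BIOES (applied at decode time as -1e9 masks):
# B must be followed by I/E of the same label; I by I/E; E/S/O cannot be
# followed by I/E; paths cannot start at I/E or end at B/I.
bioes_mask <- function(params) {
  tags <- params$tag_vocab
  kind <- substr(tags, 1L, 1L)
  T_ <- length(tags)
  allow <- matrix(TRUE, T_, T_)
  open <- kind %in% c("B", "I")       # inside an entity after these
  closed <- !open                      # O, E, S
  cont <- kind %in% c("I", "E")       # continuation tags
  for (i in seq_len(T_)) for (j in seq_len(T_)) {
    allow[i, j] <- if (open[i]) cont[j] else !cont[j]
  }
  params$trans[!allow] <- params$trans[!allow] - 1e9
  params$bos[cont] <- params$bos[cont] - 1e9
  params$eos[open] <- params$eos[open] - 1e9
  params
}

collapse_to_part <- function(doc) {
  ann <- doc$annotations
  if (nrow(ann) > 0L) ann$label <- "PART"
  report_document(doc$doc_id, doc$text, ann)
}

crf_from_weights <- function(weights, tag_vocab) {
  p <- crf_params(tag_vocab)
  p$trans[] <- weights$crf_trans
  p$bos[] <- weights$crf_bos
  p$eos[] <- weights$crf_eos
  p
}

#' Train the stage-1 body-part tagger (encoder + linear-chain CRF)
#'
#' Tags every body part (single PART label, BIOES scheme); typing is
#' deferred to stage 2. Defaults follow the reference setup (lr 3e-5,
#' batch 32, 5 epochs, Adam).
#'
#' @param train_docs nonempty list of `report_document`s
#' @param encoder_cfg an [encoder_config()]
#' @param train_cfg a [training_config()]
#' @param verbose print per-epoch loss
#' @return object of class `ner_tagger`
#' @export
train_ner <- function(train_docs, encoder_cfg = encoder_config(),
                      train_cfg = training_config(), verbose = FALSE) {
  if (length(train_docs) == 0L)
    stop_dwispan("empty training corpus", "dwispan_empty_corpus")
  vocab <- build_vocab(train_docs)
  if (length(encoder_cfg$segment_ids) == 0L)
    encoder_cfg$segment_ids <- segment_break_ids(vocab)
  d <- encoder_cfg$hidden_dim
  T_ <- length(NER_TAGS)
  weights <- init_encoder_weights(encoder_cfg, vocab$size)
  weights$W_emit <- matrix(0, d, T_)
  weights$crf_trans <- matrix(0, T_, T_)
  weights$crf_bos <- numeric(T_)
  weights$crf_eos <- numeric(T_)

  prep <- lapply(train_docs, function(doc) {
    doc <- collapse_to_part(doc)
    n <- min(nchar(doc$text), encoder_cfg$max_length)
    if (n == 0L) return(NULL)
    if (n < nchar(doc$text)) {
      ann <- doc$annotations
      doc <- report_document(doc$doc_id, substring(doc$text, 1L, n),
                             ann[ann$end <= n, , drop = FALSE])
    }
    list(ids = vocab_ids(vocab, doc$text),
         tag_idx = match(to_bioes(doc), NER_TAGS))
  })
  prep <- Filter(Negate(is.null), prep)

  state <- adam_init(weights)
  history <- numeric(train_cfg$epochs)
  warmup_steps <- as.integer(round(train_cfg$warmup_frac * train_cfg$epochs *
                                     ceiling(length(prep) /
                                               train_cfg$batch_size)))
  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      perm <- sample.int(length(prep))
      epoch_loss <- 0
      for (bs in seq(1L, length(perm), by = train_cfg$batch_size)) {
        idx <- perm[bs:min(bs + train_cfg$batch_size - 1L, length(perm))]
        grads <- NULL
        for (i in idx) {
          item <- prep[[i]]
          n <- length(item$ids)
          fwd <- encoder_forward(item$ids, weights, encoder_cfg,
                                 train = TRUE)
          E <- fwd$E
          emis <- E %*% weights$W_emit
          crf <- crf_from_weights(weights, NER_TAGS)
          marg <- crf_marginals(emis, crf)
          gold <- item$tag_idx
          nll <- (marg$logZ - crf_score(emis, crf, gold)) / n
          epoch_loss <- epoch_loss + nll

          Y <- matrix(0, n, T_)
          Y[cbind(seq_len(n), gold)] <- 1
          d_emis <- (marg$node - Y) / n
          gold_pair <- matrix(0, T_, T_)
          if (n > 1L) {
            tab <- table(factor(gold[-n], levels = seq_len(T_)),
                         factor(gold[-1L], levels = seq_len(T_)))
            gold_pair <- matrix(as.numeric(tab), T_, T_)
          }
          g <- encoder_backward(d_emis %*% t(weights$W_emit), fwd, weights,
                                encoder_cfg)
          g$W_emit <- crossprod(E, d_emis)
          g$crf_trans <- (marg$pair - gold_pair) / n
          bos_onehot <- numeric(T_); bos_onehot[gold[1L]] <- 1
          eos_onehot <- numeric(T_); eos_onehot[gold[n]] <- 1
          g$crf_bos <- (marg$node[1L, ] - bos_onehot) / n
          g$crf_eos <- (marg$node[n, ] - eos_onehot) / n
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(x) x / length(idx))
        upd <- adam_step(weights, grads, state, train_cfg$learning_rate,
                         beta1 = train_cfg$beta1, beta2 = train_cfg$beta2,
                         update_scale = train_cfg$update_scale,
                         warmup = warmup_steps)
        weights <- upd$weights
        state <- upd$state
      }
      history[epoch] <- epoch_loss / length(prep)
      if (!is.finite(history[epoch]))
        stop_dwispan(sprintf("tagger training diverged at epoch %d", epoch),
                     "dwispan_divergence")
      if (verbose)
        message(sprintf("epoch %d: mean NLL %.5f", epoch, history[epoch]))
    }
  })
  structure(list(weights = weights, encoder_config = encoder_cfg,
                 training_config = train_cfg, vocab = vocab,
                 tag_vocab = NER_TAGS, history = history),
            class = "ner_tagger")
}

#' Tag a report with the stage-1 tagger
#'
#' Viterbi decoding under BIOES transition masking, so the returned tag
#' sequence is always legal.
#'
#' @param tagger a trained `ner_tagger`
#' @param report a `report_document`
#' @return character vector of BIOES tags (one per character, up to the
#'   encoder length cap)
#' @export
tag_report <- function(tagger, report) {
  n <- min(nchar(report$text), tagger$encoder_config$max_length)
  if (n == 0L) return(character(0))
  ids <- vocab_ids(tagger$vocab, substring(report$text, 1L, n))
  E <- encode_sequence(ids, tagger$weights, tagger$encoder_config)
  emis <- E %*% tagger$weights$W_emit
  crf <- bioes_mask(crf_from_weights(tagger$weights, tagger$tag_vocab))
  crf_viterbi(emis, crf)
}

#' Extract untyped mentions from a tag sequence
#'
#' Label-agnostic counterpart of [from_bioes()]: decodes maximal legal
#' BIOES segments into PART annotations, dropping and counting illegal
#' fragments.
#'
#' @param tags BIOES tag vector
#' @param text the tagged text (same character length)
#' @param doc_id document id for the annotations
#' @return annotation data.frame with label "PART" and attribute `dropped`
#' @export
extract_mentions <- function(tags, text, doc_id = "doc") {
  doc <- from_bioes(tags, text, doc_id)
  ann <- doc$annotations
  if (nrow(ann) > 0L) ann$label <- "PART"
  attr(ann, "dropped") <- attr(doc, "dropped")
  ann
}

#' Mention-in-context view used by the stage-2 classifier
#' @param doc a `report_document`
#' @param start,end 0-based half-open mention offsets
#' @return object of class `mention_context` with the mention span, its
#'   left/right context strings and the full text
#' @export
mention_context <- function(doc, start, end) {
  if (end <= start) stop_dwispan("empty mention", "dwispan_empty_mention")
  structure(list(doc_id = doc$doc_id,
                 start = start, end = end,
                 mention = substring(doc$text, start + 1L, end),
                 left_context = substring(doc$text, 1L, start),
                 right_context = substring(doc$text, end + 1L,
                                           nchar(doc$text)),
                 full_text = doc$text),
            class = "mention_context")
}

# mention + context feature: concatenated means of encoder rows inside and
# outside the mention span (clipped to the encoder length cap).
typer_features <- function(E, start, end) {
  n <- nrow(E)
  s <- min(start + 1L, n); e <- min(end, n)
  rows <- s:e
  mention_vec <- colMeans(E[rows, , drop = FALSE])
  ctx_rows <- setdiff(seq_len(n), rows)
  ctx_vec <- if (length(ctx_rows) > 0L)
    colMeans(E[ctx_rows, , drop = FALSE]) else numeric(ncol(E))
  c(mention_vec, ctx_vec)
}

#' Training configuration presets for the stage-2 typer
#'
#' The transformer-encoder variant uses lr 3e-5, batch 32, 5 epochs; the
#' recurrent variant uses lr 0.001, batch 256, 15 epochs.
#'
#' @param kind encoder kind the typer will use
#' @param seed seed
#' @return a [training_config()]
#' @export
fet_training_config <- function(kind = c("self_attention",
                                         "recurrent_bidirectional"),
                                seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "self_attention")
    training_config(3e-5, 32L, 5L, seed = seed)
  else training_config(1e-3, 256L, 15L, seed = seed)
}

#' Train the stage-2 mention-type classifier
#'
#' Builds one training instance per gold mention (label DWI_HIGH vs
#' OTHER_PART). Each instance is represented by the concatenated mean
#' encoder representations of the mention span and of its context, fed to
#' a linear soft-max layer; the encoder is fine-tuned jointly. Batches
#' group whole documents (each contributing all its gold mentions), so one
#' optimizer step encodes each batch document once.
#'
#' @param train_docs nonempty list of `report_document`s with gold labels
#' @param encoder_cfg an [encoder_config()]
#' @param train_cfg a [training_config()]; defaults to
#'   [fet_training_config()] for the encoder kind
#' @param verbose print per-epoch loss
#' @return object of class `fet_typer`
#' @export
train_fet <- function(train_docs, encoder_cfg = encoder_config(),
                      train_cfg = NULL, verbose = FALSE) {
  if (length(train_docs) == 0L)
    stop_dwispan("empty training corpus", "dwispan_empty_corpus")
  train_cfg <- train_cfg %||% fet_training_config(encoder_cfg$kind)
  vocab <- build_vocab(train_docs)
  if (length(encoder_cfg$segment_ids) == 0L)
    encoder_cfg$segment_ids <- segment_break_ids(vocab)
  d <- encoder_cfg$hidden_dim
  weights <- init_encoder_weights(encoder_cfg, vocab$size)
  weights$W_type <- matrix(0, 2L * d, 2L)

  prep <- lapply(train_docs, function(doc) {
    ann <- doc$annotations
    if (nrow(ann) == 0L) return(NULL)
    n <- min(nchar(doc$text), encoder_cfg$max_length)
    ann <- ann[ann$start < n, , drop = FALSE]
    if (nrow(ann) == 0L) return(NULL)
    list(ids = vocab_ids(vocab, substring(doc$text, 1L, n)),
         starts = ann$start, ends = pmin(ann$end, n),
         y = as.integer(ann$label == "DWI_HIGH"))
  })
  prep <- Filter(Negate(is.null), prep)
  if (length(prep) == 0L)
    stop_dwispan("no gold mentions in training corpus",
                 "dwispan_empty_corpus")
  n_mentions <- sum(vapply(prep, function(p) length(p$y), integer(1)))

  state <- adam_init(weights)
  history <- numeric(train_cfg$epochs)
  warmup_steps <- as.integer(round(train_cfg$warmup_frac * train_cfg$epochs *
                                     ceiling(length(prep) /
                                               train_cfg$batch_size)))
  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      perm <- sample.int(length(prep))
      epoch_loss <- 0
      for (bs in seq(1L, length(perm), by = train_cfg$batch_size)) {
        idx <- perm[bs:min(bs + train_cfg$batch_size - 1L, length(perm))]
        grads <- NULL
        batch_mentions <- 0L
        for (i in idx) {
          item <- prep[[i]]
          n <- length(item$ids)
          K <- length(item$y)
          batch_mentions <- batch_mentions + K
          fwd <- encoder_forward(item$ids, weights, encoder_cfg,
                                 train = TRUE)
          E <- fwd$E
          Xf <- t(vapply(seq_len(K), function(k)
            typer_features(E, item$starts[k], item$ends[k]),
            numeric(2L * d)))
          P <- softmax_rows(Xf %*% weights$W_type)
          col <- ifelse(item$y == 1L, 1L, 2L)
          epoch_loss <- epoch_loss +
            sum(-log(pmax(P[cbind(seq_len(K), col)], 1e-12)))
          Y <- cbind(as.numeric(item$y == 1L), as.numeric(item$y != 1L))
          G <- (P - Y) / K
          dXf <- G %*% t(weights$W_type)
          # distribute feature gradients back over mention/context rows
          dE <- matrix(0, n, d)
          for (k in seq_len(K)) {
            rows <- (item$starts[k] + 1L):item$ends[k]
            dE[rows, ] <- dE[rows, ] +
              rep(dXf[k, 1:d] / length(rows), each = length(rows))
            ctx <- setdiff(seq_len(n), rows)
            if (length(ctx) > 0L)
              dE[ctx, ] <- dE[ctx, ] +
                rep(dXf[k, (d + 1L):(2L * d)] / length(ctx),
                    each = length(ctx))
          }
          g <- encoder_backward(dE, fwd, weights, encoder_cfg)
          g$W_type <- crossprod(Xf, G)
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(x) x / length(idx))
        upd <- adam_step(weights, grads, state, train_cfg$learning_rate,
                         beta1 = train_cfg$beta1, beta2 = train_cfg$beta2,
                         update_scale = train_cfg$update_scale,
                         warmup = warmup_steps)
        weights <- upd$weights
        state <- upd$state
      }
      history[epoch] <- epoch_loss / n_mentions
      if (!is.finite(history[epoch]))
        stop_dwispan(sprintf("typer training diverged at epoch %d", epoch),
                     "dwispan_divergence")
      if (verbose)
        message(sprintf("epoch %d: mean loss %.5f", epoch, history[epoch]))
    }
  })
  structure(list(W = weights$W_type, encoder_weights = weights,
                 encoder_config = encoder_cfg, training_config = train_cfg,
                 vocab = vocab, history = history),
            class = "fet_typer")
}

#' Classify one mention in context
#'
#' @param typer a trained `fet_typer`
#' @param mc a `mention_context` (see [mention_context()])
#' @return list with `label` ("DWI_HIGH" or "OTHER_PART") and `score`
#'   (positive-class probability)
#' @export
classify_mention <- function(typer, mc) {
  if (!inherits(mc, "mention_context"))
    stop_dwispan("mc must be a mention_context", "dwispan_bad_input")
  n <- min(nchar(mc$full_text), typer$encoder_config$max_length)
  if (mc$start >= n) stop_dwispan("mention beyond encoder length cap",
                                  "dwispan_too_long")
  ids <- vocab_ids(typer$vocab, substring(mc$full_text, 1L, n))
  E <- encode_sequence(ids, typer$encoder_weights, typer$encoder_config)
  f <- typer_features(E, mc$start, mc$end)
  p <- softmax_rows(matrix(f, 1L) %*% typer$W)[1L, ]
  list(label = if (p[1L] > 0.5) "DWI_HIGH" else "OTHER_PART",
       score = unname(p[1L]))
}

#' Full two-step prediction for one report
#'
#' Stage-1 mentions are classified by stage 2; only mentions whose
#' DWI-high score exceeds the threshold are returned.
#'
#' @param tagger a trained `ner_tagger`
#' @param typer a trained `fet_typer`
#' @param report a `report_document`
#' @param threshold positive-class score threshold (default 0.5)
#' @return annotation data.frame with label DWI_HIGH
#' @export
two_step_predict <- function(tagger, typer, report, threshold = 0.5) {
  tags <- tag_report(tagger, report)
  if (length(tags) == 0L) return(span_annotations())
  text <- substring(report$text, 1L, length(tags))
  mentions <- extract_mentions(tags, text, report$doc_id)
  if (nrow(mentions) == 0L) return(span_annotations())
  keep <- logical(nrow(mentions))
  for (k in seq_len(nrow(mentions))) {
    mc <- mention_context(report_document(report$doc_id, text),
                          mentions$start[k], mentions$end[k])
    keep[k] <- classify_mention(typer, mc)$score > threshold
  }
  out <- mentions[keep, , drop = FALSE]
  if (nrow(out) > 0L) out$label <- "DWI_HIGH"
  rownames(out) <- NULL
  out
}
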