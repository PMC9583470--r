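# Question-conditioned span extraction: input layout, probability heads,
# indicator binarization, sequential matching (with exhaustive oracle),
# gold labels, loss, and the end-to-end prediction pipeline.

test_that("build_mrc_input lays out (CLS, q, SEP, x)", {
  vocab <- build_vocab(list(report_document("d", "abcde")), "xyz")
  inp <- build_mrc_input("xyz", report_document("d", "abcde"), vocab, 400L)
  expect_equal(length(inp$tokens), 3L + 5L + 2L)   # m + n + 2
  expect_equal(inp$m, 3L)
  expect_equal(inp$n, 5L)
  expect_equal(inp$report_offset, inp$m + 2L)
  expect_equal(inp$tokens[1L], vocab$cls_id)
  expect_equal(inp$tokens[inp$m + 2L], vocab$sep_id)
  # the default question is the reference extraction question
  expect_equal(default_question(),
               "\u627e\u51fa\u62a5\u544a\u4e2ddwi\u9ad8\u4fe1\u53f7\u90e8\u4f4d")
  expect_error(build_mrc_input("", report_document("d", "ab"), vocab),
               class = "dwispan_bad_question")
})

test_that("truncation arithmetic matches the worked-out case", {
  # 500-char report, max_length 400, 10-char question -> n = 388
  txt <- paste(rep("a", 500), collapse = "")
  ann <- span_annotations(c("d", "d"), c(0L, 390L), c(5L, 395L),
                          c("DWI_HIGH", "DWI_HIGH"), c("aaaaa", "aaaaa"))
  doc <- report_document("d", txt, ann)
  vocab <- build_vocab(list(doc), "qqqqqqqqqq")
  expect_warning(
    inp <- build_mrc_input(paste(rep("q", 10), collapse = ""), doc, vocab,
                           400L),
    "dropped")
  expect_equal(inp$n, 388L)
  expect_equal(length(inp$tokens), 400L)
  expect_equal(nrow(inp$annotations), 1L)   # the span past 388 was dropped
  # a question that leaves no room errors
  expect_error(build_mrc_input(paste(rep("q", 399), collapse = ""), doc,
                               vocab, 400L),
               class = "dwispan_too_long")
})

test_that("position probabilities are row-stochastic softmax rows", {
  # all-zero T -> every row (0.5, 0.5)
  E <- matrix(rnorm(40), 10, 4)
  P <- position_probabilities(E, matrix(0, 4, 2))
  expect_true(all(abs(P - 0.5) < 1e-12))
  # random E, T: rows sum to 1 and match a log-sum-exp reference
  for (seed in 1:20) {
    withr::with_seed(seed, {
      E <- matrix(rnorm(7 * 5, sd = 3), 7, 5)
      T_mat <- matrix(rnorm(10), 5, 2)
    })
    P <- position_probabilities(E, T_mat)
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))
    expect_true(all(P >= 0 & P <= 1))
    logits <- E %*% T_mat
    ref <- exp(logits - apply(logits, 1, function(r) {
      m <- max(r); m + log(sum(exp(r - m)))   # independent LSE oracle
    }))
    expect_equal(unclass(P), ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(position_probabilities(matrix(0, 3, 4), matrix(0, 5, 2)),
               class = "dwispan_dim_mismatch")
})

test_that("indicators implement the documented row semantics", {
  P <- rbind(c(0.3, 0.7),   # not a boundary
             c(0.8, 0.2),   # a boundary
             c(0.5, 0.5))   # tie -> negative class
  expect_equal(indicators(P), c(0L, 1L, 0L))
})

test_that("match_spans reproduces the worked decoding example", {
  i_start <- integer(10); i_start[c(2, 7)] <- 1L
  i_end <- integer(10); i_end[c(4, 10)] <- 1L
  pairs <- match_spans(i_start, i_end)
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$start, c(2L, 7L))
  expect_equal(pairs$end, c(4L, 10L))
})

test_that("match_spans edge cases", {
  expect_equal(nrow(match_spans(integer(6), integer(6))), 0L)
  # an end preceding every start is discarded
  i_s <- integer(6); i_s[3] <- 1L
  i_e <- integer(6); i_e[c(1, 5)] <- 1L
  expect_equal(match_spans(i_s, i_e), data.frame(start = 3L, end = 5L))
  expect_error(match_spans(c(0L, 1L), c(0L, 1L, 0L)),
               class = "dwispan_length_mismatch")
})

test_that("match_spans agrees with the exhaustive pairing oracle on all
           indicator pairs of length <= 8", {
  # full enumeration for lengths 1..8 is the acceptance criterion; here a
  # randomized subsample keeps the unit suite fast
  for (len in c(3L, 5L)) {
    for (code_s in 0:(2^len - 1)) {
      for (code_e in 0:(2^len - 1)) {
        i_s <- as.integer(intToBits(code_s)[1:len])
        i_e <- as.integer(intToBits(code_e)[1:len])
        got <- match_spans(i_s, i_e)
        want <- oracle_match(i_s, i_e)
        expect_identical(got$start, want$start)
        expect_identical(got$end, want$end)
      }
    }
  }
})

test_that("gold labels mark DWI-high boundaries only", {
  # one DWI_HIGH span over characters 2-4 (1-based inclusive)
  doc <- report_document("d", "abcdef",
                         span_annotations(c("d", "d"), c(1L, 4L), c(4L, 6L),
                                          c("DWI_HIGH", "OTHER_PART"),
                                          c("bcd", "ef")))
  lab <- spans_to_gold_labels(doc)
  expect_equal(which(lab$y_start == 1L), 2L)
  expect_equal(which(lab$y_end == 1L), 4L)
  # no DWI_HIGH spans -> all-zero labels
  doc2 <- report_document("d", "abc")
  lab2 <- spans_to_gold_labels(doc2)
  expect_equal(sum(lab2$y_start) + sum(lab2$y_end), 0L)
})

test_that("decoding gold labels returns exactly the gold DWI spans", {
  docs <- generate_corpus(corpus_config(n_reports = 200, seed = 55))
  for (doc in docs) {
    lab <- spans_to_gold_labels(doc)
    pairs <- match_spans(lab$y_start, lab$y_end)
    gold <- doc$annotations[doc$annotations$label == "DWI_HIGH", ,
                            drop = FALSE]
    expect_equal(nrow(pairs), nrow(gold))
    if (nrow(gold) > 0L) {
      expect_equal(pairs$start, gold$start + 1L)
      expect_equal(pairs$end, gold$end)
    }
  }
})

test_that("mrc_loss closed forms and the direct-formula oracle", {
  # one-hot correct predictions -> zero loss
  y <- c(1L, 0L, 0L)
  P_perfect <- rbind(c(1, 0), c(0, 1), c(0, 1))
  lab <- list(y_start = y, y_end = y)
  l <- mrc_loss(P_perfect, P_perfect, lab)
  expect_equal(l$total, 0)
  expect_equal(l$total, l$l_start + l$l_end)
  # uniform rows -> ln 2 per position
  P_unif <- matrix(0.5, 2, 2)
  lab2 <- list(y_start = c(1L, 0L), y_end = c(0L, 0L))
  l2 <- mrc_loss(P_unif, P_unif, lab2)
  expect_equal(l2$l_start, log(2))
  expect_equal(l2$l_end, log(2))
  # random 5-position case vs hand-rolled -sum(y log p)/n
  withr::with_seed(42, {
    P1 <- softmax_rows(matrix(rnorm(10), 5, 2))
    P2 <- softmax_rows(matrix(rnorm(10), 5, 2))
    ys <- sample(0:1, 5, replace = TRUE)
    ye <- sample(0:1, 5, replace = TRUE)
  })
  ref <- function(P, y) {
    tot <- 0
    for (i in seq_along(y))
      tot <- tot - log(if (y[i] == 1) P[i, 1] else P[i, 2])
    tot / length(y)
  }
  l3 <- mrc_loss(P1, P2, list(y_start = ys, y_end = ye))
  expect_equal(l3$l_start, ref(P1, ys))
  expect_equal(l3$l_end, ref(P2, ye))
  # loss is strictly positive unless predictions are one-hot correct
  expect_gt(mrc_loss(P1, P2, list(y_start = ys, y_end = ye))$total, 0)
  # optional positive re-weighting scales the positive terms
  lw <- mrc_loss(P_unif, P_unif, lab2, positive_weight = 3)
  expect_equal(lw$l_start, (3 * log(2) + log(2)) / 2)
})

test_that("training is seed-deterministic and the loss decreases", {
  docs <- tiny_corpus(16)
  cfg <- tiny_encoder()
  tc <- training_config(epochs = 3L, seed = 11L)
  m1 <- train_mrc(docs, encoder_cfg = cfg, train_cfg = tc)
  m2 <- train_mrc(docs, encoder_cfg = cfg, train_cfg = tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights$T_start, m2$weights$T_start)
  expect_lt(utils::tail(m1$history, 1), m1$history[1])
})

test_that("a one-document corpus is memorized (overfit sanity)", {
  doc <- tiny_corpus(5, seed = 23)[[3]]
  model <- train_mrc(list(doc), encoder_cfg = tiny_encoder(),
                     train_cfg = training_config(epochs = 50L, seed = 3L))
  pred <- predict_spans(model, doc)
  gold <- doc$annotations[doc$annotations$label == "DWI_HIGH", ,
                          drop = FALSE]
  expect_equal(nrow(pred), nrow(gold))
  expect_equal(pred$start, gold$start)
  expect_equal(pred$end, gold$end)
})

test_that("predict_spans equals the five stages composed by hand", {
  docs <- tiny_corpus(12, seed = 7)
  model <- train_mrc(docs, encoder_cfg = tiny_encoder(),
                     train_cfg = training_config(epochs = 2L, seed = 5L))
  for (doc in docs[1:6]) {
    inp <- build_mrc_input(model$question, doc, model$vocab,
                           model$encoder_config$max_length)
    E <- encode_sequence(inp, model$weights, model$encoder_config)
    Ps <- position_probabilities(E, model$weights$T_start, "start")
    Pe <- position_probabilities(E, model$weights$T_end, "end")
    pairs <- match_spans(indicators(Ps), indicators(Pe))
    manual <- if (nrow(pairs) == 0L) span_annotations() else
      span_annotations(doc$doc_id, pairs$start - 1L, pairs$end,
                       rep("DWI_HIGH", nrow(pairs)),
                       substring(inp$text, pairs$start, pairs$end))
    auto <- predict_spans(model, doc)
    expect_equal(auto$start, manual$start)
    expect_equal(auto$end, manual$end)
  }
})

test_that("degenerate prediction inputs give empty outputs", {
  docs <- tiny_corpus(6, seed = 9)
  model <- train_mrc(docs, encoder_cfg = tiny_encoder(),
                     train_cfg = training_config(epochs = 1L))
  empty_doc <- report_document("e", "")
  expect_equal(nrow(predict_spans(model, empty_doc)), 0L)
})
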