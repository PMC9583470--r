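# Two-step pipeline: BIOES tagging with CRF decoding, mention extraction,
# mention-type classification, and the composed end-to-end prediction.

test_that("bioes transition masking only permits legal tag paths", {
  params <- dwispan:::bioes_mask(crf_params(dwispan:::NER_TAGS))
  # with zero emissions the best path is all O; with strong B/E emissions
  # the decoder must still respect legality
  emis <- matrix(0, 4, 5)
  expect_equal(crf_viterbi(emis, params), rep("O", 4))
  # force "B" everywhere: a bare B run is illegal, decoder must close it
  emis_b <- matrix(0, 3, 5); emis_b[, 2] <- 10   # B-PART column
  path <- crf_viterbi(emis_b, params)
  doc <- from_bioes(path, "abc")
  expect_true(attr(doc, "dropped") == 0L)        # decoded path is legal
})

test_that("fet_training_config presets mirror the reference settings", {
  a <- fet_training_config("self_attention")
  expect_equal(c(a$learning_rate, a$batch_size, a$epochs), c(3e-5, 32, 5))
  b <- fet_training_config("recurrent_bidirectional")
  expect_equal(c(b$learning_rate, b$batch_size, b$epochs), c(1e-3, 256, 15))
})

test_that("train_ner is seeded and its loss decreases; tags decode legally", {
  docs <- tiny_corpus(16, seed = 41)
  tagger1 <- train_ner(docs, encoder_cfg = tiny_encoder(),
                       train_cfg = training_config(epochs = 3L, seed = 6L))
  tagger2 <- train_ner(docs, encoder_cfg = tiny_encoder(),
                       train_cfg = training_config(epochs = 3L, seed = 6L))
  expect_identical(tagger1$history, tagger2$history)
  expect_lt(utils::tail(tagger1$history, 1), tagger1$history[1])
  tags <- tag_report(tagger1, docs[[1]])
  expect_length(tags, nchar(docs[[1]]$text))
  # decoded tags are always BIOES-legal
  expect_equal(attr(from_bioes(tags, docs[[1]]$text), "dropped"), 0L)
})

test_that("a one-document tagger run memorizes its tags", {
  doc <- tiny_corpus(5, seed = 77)[[2]]
  tagger <- train_ner(list(doc), encoder_cfg = tiny_encoder(),
                      train_cfg = training_config(epochs = 60L, seed = 2L))
  got <- tag_report(tagger, doc)
  want <- to_bioes(dwispan:::collapse_to_part(doc))
  expect_gt(mean(got == want), 0.95)
})

test_that("extract_mentions mirrors from_bioes label-agnostically", {
  tags <- c("B-PART", "E-PART", "O", "S-PART", "I-PART")
  m <- extract_mentions(tags, "abcde", "x")
  expect_equal(m$start, c(0L, 3L))
  expect_equal(m$end, c(2L, 4L))
  expect_equal(unique(m$label), "PART")
  expect_equal(attr(m, "dropped"), 1L)   # dangling I
})

test_that("mention_context splits text around the span", {
  doc <- report_document("d", "abcdefgh")
  mc <- mention_context(doc, 2L, 5L)
  expect_equal(mc$mention, "cde")
  expect_equal(mc$left_context, "ab")
  expect_equal(mc$right_context, "fgh")
  expect_error(mention_context(doc, 3L, 3L), class = "dwispan_empty_mention")
})

test_that("classify_mention is deterministic and 0.5 for a zeroed head", {
  docs <- tiny_corpus(12, seed = 19)
  typer <- train_fet(docs, encoder_cfg = tiny_encoder(),
                     train_cfg = training_config(epochs = 2L, seed = 4L))
  doc <- Find(function(d) nrow(d$annotations) > 0L, docs)
  ann <- doc$annotations
  mc <- mention_context(doc, ann$start[1], ann$end[1])
  r1 <- classify_mention(typer, mc)
  r2 <- classify_mention(typer, mc)
  expect_identical(r1, r2)
  expect_true(r1$label %in% c("DWI_HIGH", "OTHER_PART"))
  expect_gte(r1$score, 0); expect_lte(r1$score, 1)
  # zeroed output layer -> score exactly 0.5
  typer0 <- typer
  typer0$W[] <- 0
  expect_equal(classify_mention(typer0, mc)$score, 0.5)
})

test_that("a trained typer separates the template classes", {
  docs <- generate_corpus(corpus_config(n_reports = 120, seed = 91,
                                        target_mean_length = 60,
                                        max_length = 100))
  # small corpus: grant the same optimizer-step budget the reference corpus
  # size would give (see the acceptance suite for the full-scale run)
  typer <- train_fet(docs, encoder_cfg = tiny_encoder(),
                     train_cfg = training_config(epochs = 40L, seed = 1L))
  # evaluate on gold mentions of held-out docs
  held <- generate_corpus(corpus_config(n_reports = 30, seed = 92,
                                        target_mean_length = 60,
                                        max_length = 100))
  correct <- 0L; total <- 0L
  for (doc in held) {
    ann <- doc$annotations
    for (k in seq_len(nrow(ann))) {
      got <- classify_mention(typer,
                              mention_context(doc, ann$start[k], ann$end[k]))
      correct <- correct + as.integer(got$label == ann$label[k])
      total <- total + 1L
    }
  }
  expect_gt(correct / total, 0.8)
})

test_that("two_step_predict equals the manual composition of its stages", {
  docs <- tiny_corpus(20, seed = 33)
  tagger <- train_ner(docs, encoder_cfg = tiny_encoder(),
                      train_cfg = training_config(epochs = 2L, seed = 5L))
  typer <- train_fet(docs, encoder_cfg = tiny_encoder(),
                     train_cfg = training_config(epochs = 2L, seed = 5L))
  for (doc in docs[1:10]) {
    auto <- two_step_predict(tagger, typer, doc)
    tags <- tag_report(tagger, doc)
    text <- substring(doc$text, 1, length(tags))
    mentions <- extract_mentions(tags, text, doc$doc_id)
    keep <- logical(nrow(mentions))
    for (k in seq_len(nrow(mentions))) {
      mc <- mention_context(report_document(doc$doc_id, text),
                            mentions$start[k], mentions$end[k])
      keep[k] <- classify_mention(typer, mc)$score > 0.5
    }
    manual <- mentions[keep, , drop = FALSE]
    expect_equal(auto$start, manual$start)
    expect_equal(auto$end, manual$end)
    if (nrow(auto) > 0L) expect_equal(unique(auto$label), "DWI_HIGH")
  }
})

test_that("empty stage-1 output or all-other typing gives empty output", {
  docs <- tiny_corpus(8, seed = 3)
  tagger <- train_ner(docs, encoder_cfg = tiny_encoder(),
                      train_cfg = training_config(epochs = 1L))
  typer <- train_fet(docs, encoder_cfg = tiny_encoder(),
                     train_cfg = training_config(epochs = 1L))
  # untrained-enough tagger on an empty report
  expect_equal(nrow(two_step_predict(tagger, typer,
                                     report_document("e", "zzz"))), 0L)
  # threshold 1 discards every mention regardless of the typer
  expect_equal(nrow(two_step_predict(tagger, typer, docs[[1]],
                                     threshold = 1)), 0L)
})
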