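# corpus_io: normalization, BRAT round-trips, BIOES codec, splitting.

test_that("normalize_text removes whitespace and lower-cases ASCII", {
  out <- normalize_text("DWI \u9ad8\u4fe1\u53f7")
  expect_equal(out$text, "dwi\u9ad8\u4fe1\u53f7")
  # already-normalized text is untouched, offsets identical
  ann <- span_annotations("d", 1L, 3L, "DWI_HIGH", "bc")
  out2 <- normalize_text("abcd", ann)
  expect_equal(out2$text, "abcd")
  expect_equal(out2$annotations$start, 1L)
  expect_equal(out2$annotations$end, 3L)
})

test_that("normalization remaps offsets, verified by a char-walking oracle", {
  # independent oracle: walk the raw string, build old->new position map
  remap_oracle <- function(raw, whitespace = c(" ", "\t", "\r", "\n")) {
    ch <- strsplit(raw, "")[[1]]
    map <- integer(length(ch)); newi <- 0L
    for (i in seq_along(ch)) {
      if (!(ch[i] %in% whitespace)) newi <- newi + 1L
      map[i] <- newi
    }
    map
  }
  raw <- "ab cD e\nfg"
  ann <- span_annotations(c("d", "d"), c(2L, 7L), c(5L, 10L),
                          c("DWI_HIGH", "OTHER_PART"),
                          c(" cD", "\nfg"))
  out <- normalize_text(raw, ann)
  map <- remap_oracle(raw)
  expect_equal(out$text, "abcdefg")
  # span [2,5) covers " cD": first kept char is at raw pos 3 -> new pos map[3]
  expect_equal(out$annotations$start[1], map[4] - 1L)  # 'c' is raw index 4
  expect_equal(out$annotations$end[1], map[5])
  expect_equal(out$annotations$surface, c("cd", "fg"))
  # surfaces match their new slices
  expect_equal(substring(out$text, out$annotations$start + 1L,
                         out$annotations$end),
               out$annotations$surface)
  # length bookkeeping: output length = input minus removed count
  expect_equal(nchar(out$text), nchar(raw) - 3L)
})

test_that("annotation made only of removed characters errors", {
  ann <- span_annotations("d", 2L, 4L, "DWI_HIGH", "  ")
  expect_error(normalize_text("ab  cd", ann),
               class = "dwispan_annotation_destroyed")
})

test_that("read_brat parses T entries and validates surfaces", {
  dir <- withr::local_tempdir()
  writeLines("abcdefghij", file.path(dir, "x.txt"))
  writeLines(c("T1\tDWI_HIGH 5 8\tfgh", "T2\tOTHER_PART 0 2\tab"),
             file.path(dir, "x.ann"))
  doc <- read_brat(file.path(dir, "x.txt"), file.path(dir, "x.ann"))
  expect_s3_class(doc, "report_document")
  expect_equal(nrow(doc$annotations), 2L)
  expect_equal(doc$annotations$surface[doc$annotations$start == 5], "fgh")
  expect_equal(substring(doc$text, 6, 8), "fgh")

  # empty .ann -> empty annotations
  writeLines(character(0), file.path(dir, "x.ann"))
  expect_equal(nrow(read_brat(file.path(dir, "x.txt"),
                              file.path(dir, "x.ann"))$annotations), 0L)

  # offset/text disagreement and unknown labels are loud
  writeLines("T1\tDWI_HIGH 5 8\tzzz", file.path(dir, "x.ann"))
  expect_error(read_brat(file.path(dir, "x.txt"), file.path(dir, "x.ann")),
               class = "dwispan_surface_mismatch")
  writeLines("T1\tBANANA 5 8\tfgh", file.path(dir, "x.ann"))
  expect_error(read_brat(file.path(dir, "x.txt"), file.path(dir, "x.ann")),
               class = "dwispan_unknown_label")
  # non-entity lines are ignored with a warning
  writeLines(c("T1\tDWI_HIGH 5 8\tfgh", "R1\tRel Arg1:T1"),
             file.path(dir, "x.ann"))
  expect_warning(
    doc <- read_brat(file.path(dir, "x.txt"), file.path(dir, "x.ann")),
    "non-entity")
  expect_equal(nrow(doc$annotations), 1L)
})

test_that("BRAT write/read round-trips 50 random synthetic documents", {
  dir <- withr::local_tempdir()
  docs <- generate_corpus(corpus_config(n_reports = 50L, seed = 11L))
  write_corpus(docs, dir)
  back <- read_corpus(dir)
  expect_length(back, 50L)
  for (i in seq_along(docs)) expect_true(same_document(docs[[i]], back[[i]]))
})

test_that("write_brat emits T lines in offset order", {
  dir <- withr::local_tempdir()
  ann <- span_annotations(c("d", "d"), c(6L, 1L), c(8L, 3L),
                          c("DWI_HIGH", "OTHER_PART"), c("gh", "bc"))
  doc <- report_document("d", "abcdefghij", ann)
  write_brat(doc, file.path(dir, "d.txt"), file.path(dir, "d.ann"))
  lines <- readLines(file.path(dir, "d.ann"))
  expect_match(lines[1], "^T1\tOTHER_PART 1 3\tbc$")
  expect_match(lines[2], "^T2\tDWI_HIGH 6 8\tgh$")
  # empty document -> empty .ann
  write_brat(report_document("e", "xy"), file.path(dir, "e.txt"),
             file.path(dir, "e.ann"))
  expect_equal(length(readLines(file.path(dir, "e.ann"))), 0L)
})

test_that("to_bioes follows the BIOES scheme", {
  doc <- report_document("d", "abcdef",
                         span_annotations(c("d", "d"), c(0L, 3L), c(1L, 6L),
                                          c("DWI_HIGH", "OTHER_PART"),
                                          c("a", "def")))
  tags <- to_bioes(doc)
  expect_equal(tags, c("S-DWI_HIGH", "O", "O", "B-OTHER_PART",
                       "I-OTHER_PART", "E-OTHER_PART"))
  expect_equal(to_bioes(report_document("d", "xyz")), rep("O", 3))
})

test_that("overlapping annotations are rejected for BIOES", {
  ann <- span_annotations(c("d", "d"), c(0L, 2L), c(4L, 6L),
                          c("DWI_HIGH", "OTHER_PART"), c("abcd", "cdef"))
  expect_error(report_document("d", "abcdef", ann),
               class = "dwispan_overlap")
})

test_that("BIOES round-trips 100 random synthetic documents", {
  docs <- generate_corpus(corpus_config(n_reports = 100L, seed = 21L))
  for (doc in docs) {
    back <- from_bioes(to_bioes(doc), doc$text, doc$doc_id)
    expect_true(same_document(doc, back))
    expect_equal(attr(back, "dropped"), 0L)
  }
})

test_that("from_bioes handles all 2-tag sequences per the legality table", {
  # hand-derived: over text "ab" with one label L, the legal segmentations
  tag2 <- function(a, b) from_bioes(c(a, b), "ab", "d")
  L <- "DWI_HIGH"
  # legal: O O (none), S S (two singletons), B E (one 2-span), S O, O S
  expect_equal(nrow(tag2("O", "O")$annotations), 0L)
  res <- tag2(paste0("S-", L), paste0("S-", L))
  expect_equal(nrow(res$annotations), 2L)
  res <- tag2(paste0("B-", L), paste0("E-", L))
  expect_equal(res$annotations$start, 0L)
  expect_equal(res$annotations$end, 2L)
  # illegal fragments are dropped and counted (hand-derived table)
  zero_ann_cases <- list(
    c("I-DWI_HIGH", "O"),           # dangling I
    c("O", "I-DWI_HIGH"),
    c("E-DWI_HIGH", "O"),           # dangling E
    c("B-DWI_HIGH", "O"),           # unclosed B
    c("B-DWI_HIGH", "I-DWI_HIGH"),  # unclosed B..I
    c("I-DWI_HIGH", "E-DWI_HIGH"))  # orphan I..E run (one fragment)
  for (tags in zero_ann_cases) {
    res <- from_bioes(tags, "ab", "d")
    expect_equal(nrow(res$annotations), 0L)
    expect_equal(attr(res, "dropped"), 1L)
  }
  res <- tag2("B-DWI_HIGH", "S-DWI_HIGH")
  expect_equal(nrow(res$annotations), 1L)       # the S survives
  expect_equal(attr(res, "dropped"), 1L)        # the B is dropped
  res <- tag2("B-DWI_HIGH", "E-OTHER_PART")
  expect_equal(nrow(res$annotations), 0L)
  expect_equal(attr(res, "dropped"), 2L)        # unclosed B + orphan E
  # length mismatch errors
  expect_error(from_bioes(c("O", "O", "O"), "ab"),
               class = "dwispan_length_mismatch")
})

test_that("split_corpus is deterministic, exhaustive and disjoint", {
  docs <- lapply(1:10, function(i) report_document(paste0("d", i), "abc"))
  sp <- split_corpus(docs, 0.8, seed = 7L)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  sp2 <- split_corpus(docs, 0.8, seed = 7L)
  expect_identical(vapply(sp$train, `[[`, "", "doc_id"),
                   vapply(sp2$train, `[[`, "", "doc_id"))
  # union equals input for random N
  for (seed in 1:10) {
    N <- withr::with_seed(seed, sample(2:200, 1))
    docs <- lapply(seq_len(N), function(i)
      report_document(paste0("d", i), "abc"))
    sp <- split_corpus(docs, 0.8, seed = seed)
    ids <- sort(c(vapply(sp$train, `[[`, "", "doc_id"),
                  vapply(sp$test, `[[`, "", "doc_id")))
    expect_equal(ids, sort(paste0("d", seq_len(N))))
    expect_length(sp$train, max(1L, min(N - 1L, round(0.8 * N))))
  }
  expect_error(split_corpus(docs[1], 0.8, 1L), class = "dwispan_too_few")
})
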