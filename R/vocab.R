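# Character vocabulary with reserved ids. Ids are dense from 0:
# PAD=0, CLS=1, SEP=2, UNK=3, then corpus characters in sorted order
# (sorted insertion makes vocabulary construction deterministic).

RESERVED_TOKENS <- c(PAD = "<pad>", CLS = "<cls>", SEP = "<sep>",
                     UNK = "<unk>")

#' Build a character vocabulary from a corpus
#'
#' Covers every character seen in the corpus texts (and the optional
#' question); characters unseen at build time map to the UNK id on lookup.
#'
#' @param corpus nonempty list of `report_document`s (or character vector
#'   of texts)
#' @param question optional question string whose characters are included
#' @return object of class `dwispan_vocab`
#' @export
build_vocab <- function(corpus, question = NULL) {
  texts <- if (is.character(corpus)) corpus
  else vapply(corpus, function(d) d$text, character(1))
  if (length(texts) == 0L)
    stop_dwispan("empty corpus", "dwispan_empty_corpus")
  seen <- sort(unique(unlist(lapply(c(texts, question), chars))))
  id_of <- seq_along(seen) + 3L            # 0-based ids starting at 4
  names(id_of) <- seen
  structure(list(id_of = id_of,
                 chars = c(unname(RESERVED_TOKENS), seen),
                 pad_id = 0L, cls_id = 1L, sep_id = 2L, unk_id = 3L,
                 size = length(seen) + 4L),
            class = "dwispan_vocab")
}

#' Map characters to vocabulary ids
#' @param vocab a `dwispan_vocab`
#' @param x character vector of single characters, or a single string
#' @return integer vector of 0-based ids (UNK for unseen characters)
#' @export
vocab_ids <- function(vocab, x) {
  if (length(x) == 1L && nchar(x) != 1L) x <- chars(x)
  ids <- unname(vocab$id_of[x])
  ids[is.na(ids)] <- vocab$unk_id
  as.integer(ids)
}

#' @export
print.dwispan_vocab <- function(x, ...) {
  cat(sprintf("<dwispan_vocab> %d ids (4 reserved)\n", x$size))
  invisible(x)
}

#' Segment-break token ids for statement-local attention
#'
#' Returns the ids of sentence-final delimiters present in the vocabulary
#' plus the CLS/SEP ids; used to fill `encoder_config()$segment_ids` at
#' training time.
#'
#' @param vocab a `dwispan_vocab`
#' @param break_chars candidate delimiter characters
#' @return integer id vector
#' @export
segment_break_ids <- function(vocab,
                              break_chars = c(".", "\u3002", ";", "\uff1b")) {
  present <- break_chars[break_chars %in% names(vocab$id_of)]
  unique(c(vocab$cls_id, vocab$sep_id, unname(vocab$id_of[present])))
}

#' Write a vocabulary file (one character and id per line, UTF-8)
#' @param vocab a `dwispan_vocab`
#' @param path output path
#' @export
save_vocab <- function(vocab, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(sprintf("%s\t%d", vocab$chars, seq_along(vocab$chars) - 1L), con)
  close(con)
  invisible(path)
}

#' Read a vocabulary file written by [save_vocab()]
#' @param path vocabulary file path
#' @return a `dwispan_vocab`
#' @export
load_vocab <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ch <- vapply(parts, `[[`, character(1), 1L)
  seen <- ch[-(1:4)]
  id_of <- seq_along(seen) + 3L
  names(id_of) <- seen
  structure(list(id_of = id_of, chars = ch,
                 pad_id = 0L, cls_id = 1L, sep_id = 2L, unk_id = 3L,
                 size = length(ch)),
            class = "dwispan_vocab")
}
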