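# Corpus I/O: report documents, BRAT standoff files, text normalization
# with offset remapping, BIOES tag codecs, and train/test splitting.
#
# Conventions: all span offsets inside the package are 0-based, half-open
# [start, end) character offsets. The 1-based inclusive convention used in
# span-pair decoding output has dedicated converters (see evaluation.R).

#' Entity labels recognized by the package
#'
#' `DWI_HIGH` marks a body part reported as high-signal on DWI; `OTHER_PART`
#' marks any other annotated body part.
#' @export
PART_LABELS <- c("DWI_HIGH", "OTHER_PART")

# Whitespace characters removed by normalization. Full-width space (U+3000)
# is included because it is ubiquitous in CJK clinical text; callers can
# override.
DEFAULT_WHITESPACE <- c(" ", "\t", "\r", "\n", "\u3000")

#' Construct a span-annotation table
#'
#' Spans are 0-based half-open character offsets into the document text.
#'
#' @param doc_id character vector of document ids
#' @param start,end integer vectors of 0-based half-open offsets
#' @param label character vector of entity labels
#' @param surface character vector of surface strings (the text slice)
#' @return data.frame with columns doc_id, start, end, label, surface
#' @export
span_annotations <- function(doc_id = character(), start = integer(),
                             end = integer(), label = character(),
                             surface = character()) {
  data.frame(doc_id = as.character(doc_id), start = as.integer(start),
             end = as.integer(end), label = as.character(label),
             surface = as.character(surface), stringsAsFactors = FALSE)
}

#' Construct a report document
#'
#' A report document is one examination-description text together with its
#' span annotations.
#'
#' @param doc_id string identifier
#' @param text the description text (UTF-8)
#' @param annotations annotation table from [span_annotations()]
#' @param validate check invariants (default TRUE)
#' @return object of class `report_document`
#' @export
report_document <- function(doc_id, text, annotations = span_annotations(),
                            validate = TRUE) {
  if (nrow(annotations) > 0L) {
    annotations$doc_id <- doc_id
    annotations <- annotations[order(annotations$start, annotations$end), ,
                               drop = FALSE]
    rownames(annotations) <- NULL
  }
  doc <- structure(list(doc_id = as.character(doc_id),
                        text = enc2utf8(as.character(text)),
                        annotations = annotations),
                   class = "report_document")
  if (validate) validate_report_document(doc)
  doc
}

#' Validate report-document invariants
#'
#' Checks that every annotation lies within the text, that annotations do
#' not overlap, and that each surface string equals its text slice.
#'
#' @param doc a `report_document`
#' @return the document, invisibly; errors otherwise
#' @export
validate_report_document <- function(doc) {
  stopifnot(inherits(doc, "report_document"))
  ann <- doc$annotations
  n <- nchar(doc$text)
  if (nrow(ann) == 0L) return(invisible(doc))
  if (any(ann$start < 0L) || any(ann$end > n) || any(ann$start >= ann$end))
    stop_dwispan("annotation offsets out of range", "dwispan_bad_offsets")
  if (!all(ann$label %in% c(PART_LABELS, "PART")))
    stop_dwispan("unknown entity label", "dwispan_unknown_label")
  o <- order(ann$start)
  s <- ann$start[o]; e <- ann$end[o]
  if (any(s[-1L] < e[-length(e)]))
    stop_dwispan("annotations overlap", "dwispan_overlap")
  slice <- substring(doc$text, ann$start + 1L, ann$end)
  if (!all(slice == ann$surface))
    stop_dwispan("offset/text disagreement", "dwispan_surface_mismatch")
  invisible(doc)
}

#' @export
print.report_document <- function(x, ...) {
  cat(sprintf("<report_document %s> %d chars, %d annotations\n",
              x$doc_id, nchar(x$text), nrow(x$annotations)))
  invisible(x)
}

#' @export
format.report_document <- function(x, ...) {
  sprintf("<report_document %s>", x$doc_id)
}

#' Compare two report documents for equality
#' @param a,b report documents
#' @return logical
#' @export
same_document <- function(a, b) {
  if (a$doc_id != b$doc_id || a$text != b$text) return(FALSE)
  aa <- a$annotations; bb <- b$annotations
  if (nrow(aa) != nrow(bb)) return(FALSE)
  if (nrow(aa) == 0L) return(TRUE)
  all(aa$start == bb$start) && all(aa$end == bb$end) &&
    all(aa$label == bb$label) && all(aa$surface == bb$surface)
}

#' Normalize report text with annotation offset remapping
#'
#' Removes whitespace (space, tab, CR, LF and full-width space by default)
#' and lower-cases ASCII letters, remapping annotation offsets so each
#' annotation still covers the same (case-folded, whitespace-stripped)
#' surface.
#'
#' @param text raw text
#' @param annotations annotation table valid against `text`
#' @param whitespace characters treated as removable whitespace
#' @return list with elements `text` and `annotations`
#' @export
normalize_text <- function(text, annotations = span_annotations(),
                           whitespace = DEFAULT_WHITESPACE) {
  ch <- chars(text)
  keep <- !(ch %in% whitespace)
  new_pos <- cumsum(keep)          # 1-based position of each kept char
  out_text <- ascii_tolower(paste(ch[keep], collapse = ""))
  if (nrow(annotations) == 0L)
    return(list(text = out_text, annotations = annotations))
  ann <- annotations
  for (i in seq_len(nrow(ann))) {
    idx <- (ann$start[i] + 1L):ann$end[i]      # 1-based old indices
    kept <- idx[keep[idx]]
    if (length(kept) == 0L)
      stop_dwispan("annotation destroyed by normalization",
                   "dwispan_annotation_destroyed")
    ann$start[i] <- new_pos[kept[1L]] - 1L
    ann$end[i] <- new_pos[kept[length(kept)]]
    ann$surface[i] <- ascii_tolower(paste(ch[kept], collapse = ""))
  }
  list(text = out_text, annotations = ann)
}

#' Normalize a report document in place
#' @param doc a `report_document`
#' @param whitespace see [normalize_text()]
#' @return normalized `report_document`
#' @export
normalize_document <- function(doc, whitespace = DEFAULT_WHITESPACE) {
  norm <- normalize_text(doc$text, doc$annotations, whitespace)
  report_document(doc$doc_id, norm$text, norm$annotations)
}

#' Read one document from BRAT standoff files
#'
#' Reads a `.txt`/`.ann` pair. Only text-bound (`T`) entries are read;
#' other line types are ignored with a warning. Offsets are character
#' offsets into the text file content.
#'
#' @param text_path path to the `.txt` file
#' @param ann_path path to the `.ann` file
#' @param doc_id document id; defaults to the file stem
#' @param label_set allowed entity labels
#' @return a `report_document`
#' @export
read_brat <- function(text_path, ann_path, doc_id = NULL,
                      label_set = c(PART_LABELS, "PART")) {
  doc_id <- doc_id %||% sub("\\.txt$", "", basename(text_path))
  text <- paste(readLines(text_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  lines <- if (file.exists(ann_path))
    readLines(ann_path, encoding = "UTF-8", warn = FALSE) else character(0)
  lines <- lines[nzchar(lines)]
  ann <- span_annotations()
  for (ln in lines) {
    if (!grepl("^T", ln)) {
      warning(sprintf("ignoring non-entity .ann line: %s",
                      substr(ln, 1L, 40L)), call. = FALSE)
      next
    }
    m <- regmatches(ln, regexec(
      "^T[0-9]+\t([^ \t]+) ([0-9]+) ([0-9]+)\t(.*)$", ln))[[1L]]
    if (length(m) != 5L)
      stop_dwispan(sprintf("malformed T entry: %s", ln), "dwispan_bad_brat")
    label <- m[2L]
    if (!label %in% label_set)
      stop_dwispan(sprintf("unknown entity label: %s", label),
                   "dwispan_unknown_label")
    start <- as.integer(m[3L]); end <- as.integer(m[4L])
    slice <- substring(text, start + 1L, end)
    if (slice != m[5L])
      stop_dwispan(sprintf("offset/text disagreement in %s at %d-%d",
                           doc_id, start, end), "dwispan_surface_mismatch")
    ann <- rbind(ann, span_annotations(doc_id, start, end, label, slice))
  }
  report_document(doc_id, text, ann)
}

#' Write one document as BRAT standoff files
#' @param doc a `report_document`
#' @param text_path,ann_path output paths
#' @return invisibly, the two paths
#' @export
write_brat <- function(doc, text_path, ann_path) {
  con <- file(text_path, open = "w", encoding = "UTF-8")
  writeLines(doc$text, con, useBytes = FALSE)
  close(con)
  ann <- doc$annotations
  lines <- character(0)
  if (nrow(ann) > 0L) {
    o <- order(ann$start, ann$end)
    ann <- ann[o, , drop = FALSE]
    lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(ann)),
                     ann$label, ann$start, ann$end, ann$surface)
  }
  con <- file(ann_path, open = "w", encoding = "UTF-8")
  writeLines(lines, con, useBytes = FALSE)
  close(con)
  invisible(c(text_path, ann_path))
}

#' Write a corpus of documents to a directory as BRAT files
#'
#' One `.txt`/`.ann` pair per document plus a plain-text `manifest.txt`
#' listing document stems in order.
#'
#' @param docs list of `report_document`s
#' @param dir output directory (created if missing)
#' @return invisibly, the directory
#' @export
write_corpus <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stems <- vapply(docs, function(d) d$doc_id, character(1))
  for (d in docs)
    write_brat(d, file.path(dir, paste0(d$doc_id, ".txt")),
               file.path(dir, paste0(d$doc_id, ".ann")))
  con <- file(file.path(dir, "manifest.txt"), open = "w", encoding = "UTF-8")
  writeLines(stems, con)
  close(con)
  invisible(dir)
}

#' Read a BRAT corpus directory written by [write_corpus()]
#' @param dir corpus directory containing `manifest.txt`
#' @return list of `report_document`s
#' @export
read_corpus <- function(dir) {
  manifest <- file.path(dir, "manifest.txt")
  stems <- if (file.exists(manifest))
    readLines(manifest, encoding = "UTF-8", warn = FALSE)
  else sort(sub("\\.txt$", "", basename(Sys.glob(file.path(dir, "*.txt")))))
  lapply(stems, function(s)
    read_brat(file.path(dir, paste0(s, ".txt")),
              file.path(dir, paste0(s, ".ann")), doc_id = s))
}

# ---- BIOES codec ----------------------------------------------------------

#' Convert a document's annotations to a BIOES tag sequence
#'
#' Length-1 spans become `S-<label>`; longer spans become
#' `B-<label>, I-<label>..., E-<label>`; all other positions are `O`.
#'
#' @param doc a `report_document` with non-overlapping annotations
#' @return character vector of tags, one per character of the text
#' @export
to_bioes <- function(doc) {
  validate_report_document(doc)
  n <- nchar(doc$text)
  tags <- rep("O", n)
  ann <- doc$annotations
  for (i in seq_len(nrow(ann))) {
    s <- ann$start[i] + 1L; e <- ann$end[i]; lab <- ann$label[i]
    if (any(tags[s:e] != "O"))
      stop_dwispan("overlap not representable in BIOES", "dwispan_overlap")
    if (s == e) {
      tags[s] <- paste0("S-", lab)
    } else {
      tags[s] <- paste0("B-", lab)
      if (e - s > 1L) tags[(s + 1L):(e - 1L)] <- paste0("I-", lab)
      tags[e] <- paste0("E-", lab)
    }
  }
  tags
}

#' Decode a BIOES tag sequence back into a document
#'
#' Tolerant inverse of [to_bioes()]: maximal legal BIOES segments become
#' annotations; illegal fragments (e.g. a dangling `I` with no opening `B`,
#' or a `B` run never closed by `E`) are dropped and counted. The number of
#' dropped fragments is attached as attribute `dropped`.
#'
#' @param tags character vector of tags
#' @param text the text the tags refer to (same length)
#' @param doc_id id for the resulting document
#' @return a `report_document` with attribute `dropped`
#' @export
from_bioes <- function(tags, text, doc_id = "doc") {
  n <- nchar(text)
  if (length(tags) != n)
    stop_dwispan("length mismatch between tags and text",
                 "dwispan_length_mismatch")
  ann <- span_annotations()
  dropped <- 0L
  i <- 1L
  tag_kind <- function(t) if (t == "O") "O" else substr(t, 1L, 1L)
  tag_label <- function(t) substring(t, 3L)
  while (i <= n) {
    t <- tags[i]; k <- tag_kind(t)
    if (k == "O") { i <- i + 1L; next }
    lab <- tag_label(t)
    if (k == "S") {
      ann <- rbind(ann, span_annotations(doc_id, i - 1L, i, lab,
                                         substring(text, i, i)))
      i <- i + 1L
    } else if (k == "B") {
      j <- i + 1L
      while (j <= n && tags[j] == paste0("I-", lab)) j <- j + 1L
      if (j <= n && tags[j] == paste0("E-", lab)) {
        ann <- rbind(ann, span_annotations(doc_id, i - 1L, j, lab,
                                           substring(text, i, j)))
        i <- j + 1L
      } else {
        dropped <- dropped + 1L   # B run never closed
        i <- j
      }
    } else {
      # orphan I/E run: consume contiguous I of this label plus one E
      dropped <- dropped + 1L
      if (k == "I") {
        while (i <= n && tags[i] == paste0("I-", lab)) i <- i + 1L
        if (i <= n && tags[i] == paste0("E-", lab)) i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  doc <- report_document(doc_id, text, ann)
  attr(doc, "dropped") <- dropped
  doc
}

#' Split a corpus into training and testing sets
#'
#' Deterministic for a fixed seed; the partition is exhaustive and disjoint
#' with `round(ratio * N)` training documents.
#'
#' @param docs list of documents (length at least 2)
#' @param ratio training fraction in (0, 1); default 0.8
#' @param seed integer seed
#' @return list with elements `train` and `test`
#' @export
split_corpus <- function(docs, ratio = 0.8, seed = 1L) {
  n <- length(docs)
  if (n < 2L) stop_dwispan("need at least 2 documents", "dwispan_too_few")
  if (!(ratio > 0 && ratio < 1)) stop_dwispan("ratio must be in (0,1)",
                                              "dwispan_bad_ratio")
  n_train <- as.integer(round(ratio * n))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  list(train = docs[sort(perm[seq_len(n_train)])],
       test = docs[sort(perm[(n_train + 1L):n])])
}
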