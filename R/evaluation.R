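# Strict span-triple evaluation. A prediction is correct only if its
# document id, start and end all equal those of a gold annotation: P is the
# matched fraction of predictions, R the matched fraction of gold, and
# F1 = 2PR/(P+R). Triples are compared in the package's 0-based half-open
# convention; converters to/from the 1-based inclusive convention of the
# decoding examples are provided.

#' Build a span-triple table from annotations
#'
#' @param annotations annotation data.frame (or list of
#'   `report_document`s)
#' @param label label(s) to keep (default "DWI_HIGH"); NULL keeps all
#' @return data.frame with columns `d`, `start`, `end` (0-based half-open)
#' @export
span_triples <- function(annotations, label = "DWI_HIGH") {
  if (is.list(annotations) && !is.data.frame(annotations))
    annotations <- do.call(rbind, c(list(span_annotations()),
                                    lapply(annotations, `[[`, "annotations")))
  ann <- annotations
  if (!is.null(label)) ann <- ann[ann$label %in% label, , drop = FALSE]
  data.frame(d = ann$doc_id, start = ann$start, end = ann$end,
             stringsAsFactors = FALSE)
}

#' Convert triples between paper-style and internal offset conventions
#'
#' Internal spans are 0-based half-open `[start, end)`; the 1-based
#' inclusive convention marks the same span as `(start + 1, end)`.
#'
#' @param triples data.frame with columns `d`, `start`, `end`
#' @return converted data.frame
#' @export
triples_to_inclusive <- function(triples) {
  transform(triples, start = start + 1L)
}

#' @rdname triples_to_inclusive
#' @export
triples_from_inclusive <- function(triples) {
  transform(triples, start = start - 1L)
}

triple_keys <- function(triples) {
  if (nrow(triples) == 0L) return(character(0))
  unique(paste(triples$d, triples$start, triples$end, sep = "\r"))
}

#' Strict span-triple precision, recall and F1
#'
#' Duplicate triples are deduplicated before counting. Conventions for
#' empty sets: if both sets are empty, P = R = F1 = 1 and `both_empty` is
#' flagged; an empty prediction (or gold) side otherwise scores 0 on the
#' undefined ratio. F1 is 0 when P + R = 0.
#'
#' @param pred,gold triple data.frames from [span_triples()]
#' @return object of class `metrics_report` with `precision`, `recall`,
#'   `f1`, `n_pred`, `n_gold`, `n_matched`, `both_empty`
#' @export
strict_match_metrics <- function(pred, gold) {
  pk <- triple_keys(pred)
  gk <- triple_keys(gold)
  n_pred <- length(pk); n_gold <- length(gk)
  n_matched <- length(intersect(pk, gk))
  both_empty <- n_pred == 0L && n_gold == 0L
  precision <- if (both_empty) 1 else if (n_pred == 0L) 0 else
    n_matched / n_pred
  recall <- if (both_empty) 1 else if (n_gold == 0L) 0 else
    n_matched / n_gold
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 n_pred = n_pred, n_gold = n_gold, n_matched = n_matched,
                 both_empty = both_empty),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("P %.4f  R %.4f  F1 %.4f  (pred %d, gold %d, matched %d)%s\n",
              x$precision, x$recall, x$f1, x$n_pred, x$n_gold, x$n_matched,
              if (x$both_empty) "  [both empty]" else ""))
  invisible(x)
}

#' Multi-seed evaluation with error bars
#'
#' Trains and evaluates once per seed and reports per-seed strict-match
#' metrics plus the mean and sample standard deviation of F1. A seed run
#' that errors or returns non-finite metrics is recorded as a failure and
#' excluded with a warning.
#'
#' @param train_fn function(seed) returning a predictor: a function taking
#'   a list of documents and returning an annotation data.frame
#' @param eval_docs held-out documents with gold annotations
#' @param seeds integer vector of at least 2 seeds
#' @param label positive label for evaluation (default "DWI_HIGH")
#' @return object of class `errorbar_report` with `runs` (list of
#'   seed/metrics), `mean_f1`, `sd_f1`
#' @export
multi_seed_eval <- function(train_fn, eval_docs, seeds, label = "DWI_HIGH") {
  if (length(seeds) < 2L)
    stop_dwispan("need at least 2 seeds", "dwispan_bad_config")
  gold <- span_triples(eval_docs, label)
  runs <- list()
  for (s in seeds) {
    res <- tryCatch({
      predictor <- train_fn(s)
      pred <- span_triples(predictor(eval_docs), label = NULL)
      m <- strict_match_metrics(pred, gold)
      if (!is.finite(m$f1)) stop("non-finite F1")
      m
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("seed %s run failed and was excluded: %s", s,
                      conditionMessage(res)), call. = FALSE)
    } else {
      runs[[length(runs) + 1L]] <- list(seed = s, metrics = res)
    }
  }
  f1s <- vapply(runs, function(r) r$metrics$f1, numeric(1))
  structure(list(runs = runs, mean_f1 = mean(f1s),
                 sd_f1 = if (length(f1s) > 1L) stats::sd(f1s) else NA_real_),
            class = "errorbar_report")
}

#' @export
print.errorbar_report <- function(x, ...) {
  cat(sprintf("F1 %.4f +/- %.4f over %d seeds\n", x$mean_f1, x$sd_f1,
              length(x$runs)))
  for (r in x$runs)
    cat(sprintf("  seed %s: F1 %.4f\n", r$seed, r$metrics$f1))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param metrics a `metrics_report`
#' @param path output path
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
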