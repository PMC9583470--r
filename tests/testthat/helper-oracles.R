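# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations: brute-force enumeration, direct-formula
# arithmetic, and character-walking remappers.

# Build a random report document: random lowercase text with random
# non-overlapping labeled spans.
random_doc <- function(seed, min_len = 5L, max_len = 60L,
                       labels = c("DWI_HIGH", "OTHER_PART")) {
  withr::with_seed(seed, {
    n <- sample(min_len:max_len, 1L)
    text <- paste(sample(letters[1:8], n, replace = TRUE), collapse = "")
    ann <- span_annotations()
    pos <- 0L
    while (pos < n - 1L && runif(1) < 0.7) {
      start <- pos + sample(0L:min(4L, n - 2L - pos), 1L)
      if (start >= n) break
      len <- sample(1L:min(5L, n - start), 1L)
      ann <- rbind(ann, span_annotations(
        "d", start, start + len, sample(labels, 1L),
        substring(text, start + 1L, start + len)))
      pos <- start + len
    }
    report_document(sprintf("doc%03d", seed), text, ann)
  })
}

# Exhaustive non-crossing pairing oracle for sequential start/end
# matching: enumerate every set of disjoint (start, end) interval pairs
# using each marker at most once, keep the maximum-cardinality ones, and
# return the lexicographically smallest by the flattened (s1, e1, s2, ...)
# key. Recursion over the sorted start list.
oracle_match <- function(i_start, i_end) {
  starts <- which(i_start == 1L)
  ends <- which(i_end == 1L)
  best_s <- integer(0); best_e <- integer(0)
  consider <- function(as_, ae_) {
    o <- order(as_)
    as_ <- as_[o]; ae_ <- ae_[o]
    if (length(as_) > length(best_s)) {
      best_s <<- as_; best_e <<- ae_
    } else if (length(as_) == length(best_s) && length(as_) > 0L) {
      key_new <- as.vector(rbind(as_, ae_))
      key_old <- as.vector(rbind(best_s, best_e))
      cmp <- key_new - key_old
      nz <- which(cmp != 0L)
      if (length(nz) > 0L && cmp[nz[1L]] < 0L) {
        best_s <<- as_; best_e <<- ae_
      }
    }
  }
  recurse <- function(s_idx, used_ends, as_, ae_) {
    if (s_idx > length(starts)) {
      consider(as_, ae_)
      return(invisible(NULL))
    }
    s <- starts[s_idx]
    # option 1: skip this start
    recurse(s_idx + 1L, used_ends, as_, ae_)
    # option 2: pair with any unused end >= s, keeping intervals disjoint
    for (e_idx in seq_along(ends)) {
      if (used_ends[e_idx]) next
      e <- ends[e_idx]
      if (e < s) next
      if (length(as_) > 0L && any(!(e < as_ | s > ae_))) next
      used2 <- used_ends; used2[e_idx] <- TRUE
      recurse(s_idx + 1L, used2, c(as_, s), c(ae_, e))
    }
  }
  recurse(1L, rep(FALSE, length(ends)), integer(0), integer(0))
  data.frame(start = best_s, end = best_e)
}

# Direct-summation CRF path score (independent of crf_score).
oracle_crf_score <- function(emissions, trans, bos, eos, idx) {
  s <- bos[idx[1]] + eos[idx[length(idx)]]
  for (t in seq_along(idx)) s <- s + emissions[t, idx[t]]
  if (length(idx) > 1L)
    for (t in 2:length(idx)) s <- s + trans[idx[t - 1], idx[t]]
  unname(s)
}

# Exhaustive enumeration of all T^n paths: best path (ties: first in
# lexicographic enumeration order with lower indices first) and logZ.
oracle_crf_enumerate <- function(emissions, trans, bos, eos) {
  n <- nrow(emissions); T_ <- ncol(emissions)
  grid <- do.call(expand.grid, rep(list(seq_len(T_)), n))
  # expand.grid varies the first column fastest; rebuild ordering so that
  # enumeration is lexicographic in path order with position 1 slowest
  scores <- apply(as.matrix(grid), 1L, function(p)
    oracle_crf_score(emissions, trans, bos, eos, as.integer(p)))
  best <- as.integer(grid[which.max(scores), ])
  m <- max(scores)
  list(best = best, best_score = max(scores),
       logZ = m + log(sum(exp(scores - m))))
}

# O(|pred| * |gold|) pairwise strict-matching oracle.
oracle_metrics <- function(pred, gold) {
  dedup <- function(x) x[!duplicated(paste(x$d, x$start, x$end)), ,
                         drop = FALSE]
  pred <- dedup(pred); gold <- dedup(gold)
  matched <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(gold))) {
      if (pred$d[i] == gold$d[j] && pred$start[i] == gold$start[j] &&
          pred$end[i] == gold$end[j]) {
        matched <- matched + 1L
        break
      }
    }
  }
  P <- if (nrow(pred) == 0L && nrow(gold) == 0L) 1
       else if (nrow(pred) == 0L) 0 else matched / nrow(pred)
  R <- if (nrow(pred) == 0L && nrow(gold) == 0L) 1
       else if (nrow(gold) == 0L) 0 else matched / nrow(gold)
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(precision = P, recall = R, f1 = F1, n_matched = matched)
}

# small encoder config for fast unit tests
tiny_encoder <- function(kind = "self_attention", seed = 1L) {
  encoder_config(kind = kind, hidden_dim = 16L, n_layers = 2L,
                 n_heads = if (kind == "self_attention") 4L else 8L,
                 max_length = 120L, seed = seed)
}

# tiny statement-like corpus for fast learning tests (fits the tiny
# encoder's length cap including the question overhead)
tiny_corpus <- function(n = 30L, seed = 1L) {
  generate_corpus(corpus_config(n_reports = n, seed = seed,
                                mean_dwi_mentions = 1.5,
                                mean_other_mentions = 3,
                                target_mean_length = 50L,
                                max_length = 100L))
}
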