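# Synthetic annotated MRI-report generator.
#
# Emulates the statistical profile of an annotated head-MRI description
# corpus (mention counts, text lengths) and its central linguistic
# difficulty: several imaging sequences (DWI, FLAIR, T2WI, T1WI) attributing
# signal findings to the same or nearby body parts, so that only context
# separates DWI high-signal parts from every other part mention.
#
# Templates are token patterns over pluggable vocabularies. The default pack
# uses romanized body-part/modality tokens (no CJK font handling needed in
# tests); a CJK pack mirrors real report phrasing. Mention counts are
# Poisson, target lengths truncated-normal -- modeling choices, documented
# in the vignette.

default_part_vocabulary <- function() {
  c("naoqiao", "dijie", "eye", "dingye", "nieye", "zhenye", "xiaonao",
    "naogan", "qiunao", "haima", "neinang", "daonao", "naoshi", "fangguan",
    "luanyuan", "jizhen", "jiaonao", "huiti", "ceqiao", "jizhi")
}

default_modifier_vocabulary <- function() {
  c("", "zuo", "you", "shuang")
}

default_filler_vocabulary <- function() {
  c("naoshixitongxingtaiweijianyichang.", "zhongxianjiegouwuyiwei.",
    "naogoufenmingqingxi.", "geshijieqingchuxianshi.",
    "saozhangweijianyichang.", "fujianjiegouxianshiqingxi.")
}

cjk_vocab_pack <- function() {
  list(parts = c("\u8111\u6865", "\u5e95\u8282", "\u653e\u5c04\u51a0",
                 "\u534a\u5375\u5706", "\u989d\u53f6", "\u9876\u53f6",
                 "\u9897\u53f6", "\u6795\u53f6", "\u5c0f\u8111",
                 "\u8111\u5e72", "\u4e18\u8111", "\u6d77\u9a6c"),
       modifiers = c("", "\u5de6\u4fa7", "\u53f3\u4fa7", "\u53cc\u4fa7"),
       modalities = c("dwi", "flair", "t2wi", "t1wi"),
       descriptors = c(high = "\u9ad8\u4fe1\u53f7",
                       slightly_high = "\u7a0d\u9ad8\u4fe1\u53f7",
                       long = "\u957f\u4fe1\u53f7",
                       equal = "\u7b49\u4fe1\u53f7"),
       sep = "\u3001", period = "\u3002", comma = "\uff0c",
       verb = "\u89c1",
       fillers = c("\u8111\u5ba4\u7cfb\u7edf\u5f62\u6001\u672a\u89c1\u5f02\u5e38\u3002",
                   "\u4e2d\u7ebf\u7ed3\u6784\u65e0\u79fb\u4f4d\u3002",
                   "\u8111\u6c9f\u5206\u660e\u6e05\u6670\u3002"))
}

romanized_vocab_pack <- function() {
  list(parts = default_part_vocabulary(),
       modifiers = default_modifier_vocabulary(),
       modalities = c("dwi", "flair", "t2wi", "t1wi"),
       descriptors = c(high = "gaoxinhao", slightly_high = "shaogaoxinhao",
                       long = "changxinhao", equal = "dengxinhao"),
       sep = ",", period = ".", comma = ",", verb = "jian",
       fillers = default_filler_vocabulary())
}

#' Configuration for the synthetic report generator
#'
#' Defaults reproduce the corpus statistics the generator targets: on
#' average 2 DWI high-signal mentions and 8 other part mentions per
#' annotated description, mean description length about 170 characters with
#' a hard maximum of 525.
#'
#' @param n_reports number of reports to generate
#' @param empty_fraction proportion of descriptions carrying no annotated
#'   parts (default 0: the modeled corpus is the annotated one)
#' @param mean_dwi_mentions expected DWI high-signal mentions per non-empty
#'   report (default 2)
#' @param mean_other_mentions expected other part mentions per non-empty
#'   report (default 8)
#' @param target_mean_length target mean description length in characters
#'   (default 170)
#' @param max_length hard length cap in characters (default 525)
#' @param shared_part_rate probability that a statement attributes multiple
#'   modalities to the same parts, or that a distractor reuses parts already
#'   reported DWI-high (default 0.3)
#' @param broken_writing_rate probability a multi-part statement omits the
#'   part delimiter ("broken writing", a real report error mode)
#' @param language_pack "romanized" (default) or "cjk"
#' @param part_vocabulary,modality_vocabulary,descriptor_vocabulary optional
#'   vocabulary overrides
#' @param seed integer seed; the whole corpus is reproducible from it
#' @return object of class `corpus_config`
#' @export
corpus_config <- function(n_reports = 100L, empty_fraction = 0,
                          mean_dwi_mentions = 2, mean_other_mentions = 8,
                          target_mean_length = 170L, max_length = 525L,
                          shared_part_rate = 0.3, broken_writing_rate = 0.05,
                          language_pack = c("romanized", "cjk"),
                          part_vocabulary = NULL, modality_vocabulary = NULL,
                          descriptor_vocabulary = NULL, seed = 1L) {
  language_pack <- match.arg(language_pack)
  pack <- if (language_pack == "cjk") cjk_vocab_pack() else
    romanized_vocab_pack()
  if (!is.null(part_vocabulary)) pack$parts <- part_vocabulary
  if (!is.null(modality_vocabulary)) pack$modalities <- modality_vocabulary
  if (!is.null(descriptor_vocabulary)) pack$descriptors <- descriptor_vocabulary
  cfg <- structure(list(n_reports = as.integer(n_reports),
                        empty_fraction = empty_fraction,
                        mean_dwi_mentions = mean_dwi_mentions,
                        mean_other_mentions = mean_other_mentions,
                        target_mean_length = as.integer(target_mean_length),
                        max_length = as.integer(max_length),
                        shared_part_rate = shared_part_rate,
                        broken_writing_rate = broken_writing_rate,
                        language_pack = language_pack,
                        pack = pack, seed = as.integer(seed)),
                   class = "corpus_config")
  validate_corpus_config(cfg)
  cfg
}

validate_corpus_config <- function(cfg) {
  probs <- c(cfg$empty_fraction, cfg$shared_part_rate, cfg$broken_writing_rate)
  if (any(probs < 0 | probs > 1))
    stop_dwispan("proportions must lie in [0,1]", "dwispan_bad_config")
  if (cfg$mean_dwi_mentions <= 0 || cfg$mean_other_mentions <= 0)
    stop_dwispan("mention means must be positive", "dwispan_bad_config")
  if (cfg$max_length < cfg$target_mean_length)
    stop_dwispan("max_length must be >= target_mean_length",
                 "dwispan_bad_config")
  if (length(cfg$pack$parts) == 0L || length(cfg$pack$modalities) == 0L ||
      length(cfg$pack$descriptors) == 0L)
    stop_dwispan("empty vocabulary", "dwispan_empty_vocab")
  invisible(cfg)
}

# A (modality, descriptor) attribution counts as DWI-high when the modality
# is DWI and the descriptor is a high or slightly-high signal phrase.
is_dwi_high <- function(pack, modality, descriptor) {
  modality == pack$modalities[1L] &&
    descriptor %in% pack$descriptors[c("high", "slightly_high")]
}

draw_parts <- function(pack, k) {
  base <- sample(pack$parts, k, replace = k > length(pack$parts))
  mods <- sample(pack$modifiers, k, replace = TRUE)
  paste0(mods, base)
}

# Draw a non-DWI-high (modality, descriptor) attribution, including the
# "DWI equal-signal" near-miss.
draw_distractor_attribution <- function(pack) {
  repeat {
    modality <- sample(pack$modalities, 1L)
    descriptor <- if (modality == pack$modalities[1L])
      pack$descriptors[["equal"]]           # DWI-equal near-miss
    else sample(pack$descriptors, 1L)
    if (!is_dwi_high(pack, modality, descriptor))
      return(c(modality, descriptor))
  }
}

#' Generate one report statement
#'
#' Builds a single sentence-like fragment attributing one or more modality
#' signals to a list of body parts, with annotations for each part mention.
#'
#' @param config a `corpus_config`
#' @param kind "dwi_high" (DWI-high attribution), "distractor" (non-DWI-high
#'   attribution only) or "multi_modality" (two or more modalities over the
#'   same parts; parts are labeled by whether a DWI-high attribution
#'   applies)
#' @param parts optional character vector of part surfaces to use
#' @param n_parts number of parts to draw when `parts` is NULL
#' @param broken force/suppress broken writing (delimiter omitted); default
#'   draws from `config$broken_writing_rate`
#' @return list with `text` (fragment) and `annotations` (offsets relative
#'   to the fragment; doc_id empty)
#' @export
generate_statement <- function(config,
                               kind = c("dwi_high", "distractor",
                                        "multi_modality"),
                               parts = NULL, n_parts = NULL, broken = NULL) {
  kind <- match.arg(kind)
  pack <- config$pack
  if (length(pack$parts) == 0L)
    stop_dwispan("empty vocabulary", "dwispan_empty_vocab")
  if (is.null(n_parts)) n_parts <- sample(1:3, 1L, prob = c(0.5, 0.3, 0.2))
  if (is.null(parts)) parts <- draw_parts(pack, n_parts)
  if (is.null(broken))
    broken <- length(parts) > 1L && runif(1) < config$broken_writing_rate

  attributions <- switch(kind,
    dwi_high = list(c(pack$modalities[1L],
                      sample(pack$descriptors[c("high", "slightly_high")],
                             1L, prob = c(0.8, 0.2)))),
    distractor = list(draw_distractor_attribution(pack)),
    multi_modality = {
      atts <- list(c(pack$modalities[1L],
                     pack$descriptors[[sample(c("high", "slightly_high"),
                                              1L, prob = c(0.8, 0.2))]]))
      if (runif(1) < 0.5) atts[[1L]] <- draw_distractor_attribution(pack)
      extra <- draw_distractor_attribution(pack)
      # avoid repeating the same modality twice in one statement
      while (extra[1L] == atts[[1L]][1L]) extra <- draw_distractor_attribution(pack)
      c(atts, list(extra))
    })

  dwi_high_here <- any(vapply(attributions, function(a)
    is_dwi_high(pack, a[1L], a[2L]), logical(1)))
  label <- if (dwi_high_here) "DWI_HIGH" else "OTHER_PART"

  sep <- if (broken) "" else pack$sep
  frag <- ""
  ann <- span_annotations()
  for (i in seq_along(parts)) {
    if (i > 1L) frag <- paste0(frag, sep)
    start <- nchar(frag)
    frag <- paste0(frag, parts[i])
    ann <- rbind(ann, span_annotations("", start, nchar(frag), label,
                                       parts[i]))
  }
  use_verb <- runif(1) < 0.5
  if (use_verb) frag <- paste0(frag, pack$verb)
  att_text <- paste(vapply(attributions, function(a) paste0(a[1L], a[2L]),
                           character(1)), collapse = pack$comma)
  frag <- paste0(frag, att_text, pack$period)
  list(text = frag, annotations = ann)
}

# Partition k parts into statement groups of size 1-3.
group_sizes <- function(k) {
  sizes <- integer(0)
  while (k > 0L) {
    s <- min(k, sample(1:3, 1L, prob = c(0.3, 0.4, 0.3)))
    sizes <- c(sizes, s)
    k <- k - s
  }
  sizes
}

#' Generate one synthetic report document
#'
#' @param config a `corpus_config`
#' @param index report counter; the report seed is derived from
#'   `config$seed` and `index`, so reports can be generated independently
#' @return a `report_document` (already in normalized form: no whitespace,
#'   lower-case ASCII)
#' @export
generate_report <- function(config, index = 1L) {
  with_seed(derive_seed(config$seed, index), {
    doc_id <- sprintf("doc%05d", index)
    pack <- config$pack
    statements <- list()

    if (runif(1) >= config$empty_fraction) {
      # annotated report: draw mention counts conditioned on being non-empty
      repeat {
        n_dwi <- stats::rpois(1L, config$mean_dwi_mentions)
        n_other <- stats::rpois(1L, config$mean_other_mentions)
        if (n_dwi + n_other > 0L) break
      }
      dwi_parts_used <- character(0)
      for (s in group_sizes(n_dwi)) {
        kind <- if (runif(1) < config$shared_part_rate) "multi_modality"
                else "dwi_high"
        st <- generate_statement(config, kind, n_parts = s)
        # multi_modality may come out non-DWI; force the DWI-high label set
        if (kind == "multi_modality" &&
            !any(st$annotations$label == "DWI_HIGH"))
          st <- generate_statement(config, "dwi_high", n_parts = s)
        dwi_parts_used <- c(dwi_parts_used, st$annotations$surface)
        statements <- c(statements, list(st))
      }
      for (s in group_sizes(n_other)) {
        reuse <- length(dwi_parts_used) > 0L &&
          runif(1) < config$shared_part_rate
        parts <- if (reuse) {
          p <- sample(dwi_parts_used, min(s, length(dwi_parts_used)))
          if (length(p) < s) p <- c(p, draw_parts(pack, s - length(p)))
          p
        } else draw_parts(pack, s)
        kind <- if (runif(1) < config$shared_part_rate) "multi_modality"
                else "distractor"
        st <- generate_statement(config, kind, parts = parts)
        # keep OTHER_PART statements truly non-DWI-high
        if (any(st$annotations$label == "DWI_HIGH"))
          st <- generate_statement(config, "distractor", parts = parts)
        statements <- c(statements, list(st))
      }
      statements <- statements[sample.int(length(statements))]
    }

    # assemble under the length cap
    text <- ""
    ann <- span_annotations()
    for (st in statements) {
      if (nchar(text) + nchar(st$text) > config$max_length) break
      offset <- nchar(text)
      text <- paste0(text, st$text)
      if (nrow(st$annotations) > 0L) {
        a <- st$annotations
        a$start <- a$start + offset
        a$end <- a$end + offset
        ann <- rbind(ann, a)
      }
    }

    # pad with unannotated filler sentences toward the drawn target length
    target <- round(stats::rnorm(1L, config$target_mean_length,
                                 0.2 * config$target_mean_length))
    target <- max(10L, min(config$max_length, target))
    while (nchar(text) < target) {
      filler <- sample(pack$fillers, 1L)
      if (nchar(text) + nchar(filler) > config$max_length) break
      text <- paste0(text, filler)
    }

    report_document(doc_id, text, ann)
  })
}

#' Generate a synthetic corpus
#' @param config a `corpus_config`
#' @return list of `report_document`s of length `config$n_reports`
#' @export
generate_corpus <- function(config) {
  validate_corpus_config(config)
  lapply(seq_len(config$n_reports), function(i) generate_report(config, i))
}

#' Empirical summary statistics of a corpus
#'
#' Mention means are computed over non-empty (annotated) reports, matching
#' how the generator's configured means are defined.
#'
#' @param corpus nonempty list of `report_document`s
#' @return object of class `corpus_summary` with fields
#'   `mean_dwi_mentions`, `mean_other_mentions`, `mean_length`,
#'   `max_length`, `empty_fraction`, `n_reports`
#' @export
corpus_stats <- function(corpus) {
  if (length(corpus) == 0L)
    stop_dwispan("empty corpus", "dwispan_empty_corpus")
  n_dwi <- vapply(corpus, function(d) sum(d$annotations$label == "DWI_HIGH"),
                  numeric(1))
  n_other <- vapply(corpus,
                    function(d) sum(d$annotations$label == "OTHER_PART"),
                    numeric(1))
  lens <- vapply(corpus, function(d) nchar(d$text), numeric(1))
  nonempty <- (n_dwi + n_other) > 0
  structure(list(
    mean_dwi_mentions = if (any(nonempty)) mean(n_dwi[nonempty]) else 0,
    mean_other_mentions = if (any(nonempty)) mean(n_other[nonempty]) else 0,
    mean_length = mean(lens),
    max_length = max(lens),
    empty_fraction = mean(!nonempty),
    n_reports = length(corpus)), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf(paste0("corpus of %d reports: %.2f DWI-high / %.2f other ",
                     "mentions per annotated report, mean length %.1f ",
                     "(max %d), %.1f%% empty\n"),
              x$n_reports, x$mean_dwi_mentions, x$mean_other_mentions,
              x$mean_length, x$max_length, 100 * x$empty_fraction))
  invisible(x)
}
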