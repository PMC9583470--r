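# Linear-chain CRF: path scoring, log-partition (forward algorithm),
# marginals (forward-backward), negative log-likelihood and Viterbi
# decoding. Tag-set agnostic; BIOES legality masking for decoding lives in
# two_step.R. All recursions are in log space with log-sum-exp guards.

#' Construct linear-chain CRF parameters
#'
#' Transition scores over an ordered tag vocabulary plus BOS/EOS boundary
#' scores, all initialized to zero.
#'
#' @param tag_vocab ordered character vector of tags
#' @return object of class `crf_params` with fields `tag_vocab`,
#'   `trans` (T x T, from-row to-column), `bos` (T), `eos` (T)
#' @export
crf_params <- function(tag_vocab) {
  T_ <- length(tag_vocab)
  structure(list(tag_vocab = tag_vocab,
                 trans = matrix(0, T_, T_,
                                dimnames = list(tag_vocab, tag_vocab)),
                 bos = stats::setNames(numeric(T_), tag_vocab),
                 eos = stats::setNames(numeric(T_), tag_vocab)),
            class = "crf_params")
}

tag_index <- function(params, path) {
  idx <- match(path, params$tag_vocab)
  if (anyNA(idx)) stop_dwispan("tag not in vocabulary", "dwispan_bad_tag")
  idx
}

#' Score a tag path under a linear-chain CRF
#'
#' Sum of per-position emission scores along the path plus transition
#' scores, including the BOS->first and last->EOS boundary transitions.
#'
#' @param emissions n x T matrix of per-position tag scores
#' @param params a `crf_params`
#' @param path character (or integer index) vector of length n
#' @return numeric score
#' @export
crf_score <- function(emissions, params, path) {
  n <- nrow(emissions)
  T_ <- length(params$tag_vocab)
  if (ncol(emissions) != T_)
    stop_dwispan("emission/tag dimension mismatch", "dwispan_dim_mismatch")
  idx <- if (is.numeric(path)) as.integer(path) else tag_index(params, path)
  if (length(idx) != n)
    stop_dwispan("path length mismatch", "dwispan_length_mismatch")
  s <- sum(emissions[cbind(seq_len(n), idx)]) +
    params$bos[idx[1L]] + params$eos[idx[n]]
  if (n > 1L)
    s <- s + sum(params$trans[cbind(idx[-n], idx[-1L])])
  unname(s)
}

# forward algorithm: returns list(logZ, alpha) with alpha[t, j] the
# log-sum over paths ending in tag j at position t (inclusive of
# emissions and BOS).
crf_forward <- function(emissions, params) {
  n <- nrow(emissions)
  T_ <- ncol(emissions)
  alpha <- matrix(0, n, T_)
  alpha[1L, ] <- params$bos + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      prev <- alpha[t - 1L, ]
      off <- max(prev)
      # column-wise log-sum-exp of (prev + trans), vectorized
      alpha[t, ] <- emissions[t, ] + off +
        log(colSums(exp(prev - off + params$trans)))
    }
  }
  list(logZ = logsumexp(alpha[n, ] + params$eos), alpha = alpha)
}

# backward recursion: beta[t, i] = log-sum over path suffixes after
# position t given tag i at t (exclusive of emission at t, inclusive of
# EOS).
crf_backward <- function(emissions, params) {
  n <- nrow(emissions)
  T_ <- ncol(emissions)
  beta <- matrix(0, n, T_)
  beta[n, ] <- params$eos
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      nxt <- emissions[t + 1L, ] + beta[t + 1L, ]
      off <- max(nxt)
      beta[t, ] <- off +
        log(rowSums(exp(params$trans + rep(nxt - off, each = T_))))
    }
  }
  beta
}

#' CRF log-partition function
#' @param emissions n x T emission matrix
#' @param params a `crf_params`
#' @return log of the sum of exp-scores over all T^n paths
#' @export
crf_logZ <- function(emissions, params) {
  crf_forward(emissions, params)$logZ
}

#' CRF negative log-likelihood of a gold path
#'
#' `logZ - score(gold)`; non-negative up to floating-point tolerance.
#'
#' @inheritParams crf_score
#' @return numeric NLL
#' @export
crf_nll <- function(emissions, params, path) {
  crf_logZ(emissions, params) - crf_score(emissions, params, path)
}

# node marginals (n x T), pairwise transition expectations (T x T summed
# over positions), used for NLL gradients.
crf_marginals <- function(emissions, params) {
  fw <- crf_forward(emissions, params)
  beta <- crf_backward(emissions, params)
  n <- nrow(emissions)
  logZ <- fw$logZ
  node <- exp(fw$alpha + beta - logZ)
  pair <- matrix(0, ncol(emissions), ncol(emissions))
  if (n > 1L) {
    for (t in 2:n) {
      lp <- outer(fw$alpha[t - 1L, ], emissions[t, ] + beta[t, ], "+") +
        params$trans - logZ
      pair <- pair + exp(lp)
    }
  }
  list(node = node, pair = pair, logZ = logZ)
}

#' Viterbi decoding
#'
#' Returns an argmax-scoring tag path; score ties resolve deterministically
#' to the lower tag index.
#'
#' @param emissions n x T emission matrix
#' @param params a `crf_params`
#' @return character vector of tags (length n)
#' @export
crf_viterbi <- function(emissions, params) {
  n <- nrow(emissions)
  T_ <- ncol(emissions)
  delta <- matrix(-Inf, n, T_)
  back <- matrix(0L, n, T_)
  delta[1L, ] <- params$bos + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      m <- delta[t - 1L, ] + params$trans
      back[t, ] <- max.col(t(m), ties.method = "first")
      delta[t, ] <- emissions[t, ] + m[cbind(back[t, ], seq_len(T_))]
    }
  }
  final <- delta[n, ] + params$eos
  idx <- integer(n)
  idx[n] <- which.max(final)
  if (n > 1L)
    for (t in n:2) idx[t - 1L] <- back[t, idx[t]]
  params$tag_vocab[idx]
}
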