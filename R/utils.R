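# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a string into single characters
#' @param x a length-1 character string (UTF-8)
#' @return character vector of single characters
#' @keywords internal
chars <- function(x) {
  if (length(x) != 1L || !is.character(x)) stop("`x` must be a single string")
  if (nchar(x) == 0L) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1L]]
}

#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Row-wise softmax of a matrix
#' @param x numeric matrix of logits
#' @return matrix of the same shape; rows sum to 1
#' @keywords internal
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a per-item 32-bit seed from a base seed and a counter.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483647)
}

# ASCII-only lower-casing (leaves non-ASCII untouched, unlike tolower()
# under some locales).
ascii_tolower <- function(x) {
  chartr(paste(LETTERS, collapse = ""), paste(letters, collapse = ""), x)
}

# Tiny FNV-1a hash for run logs (no digest dependency). State is kept in
# doubles (exact below 2^53); xor touches only the low byte.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n"))) %% 256
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_dwispan <- function(msg, class) {
  stop(structure(class = c(class, "dwispan_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
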