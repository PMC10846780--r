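# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates `expr`, and restores the
#' state on exit, so library functions never perturb user-level streams.
#'
#' @param seed integer seed (< 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit substream seed from a base seed; keeps results for unit i
# independent of how many units precede it. Stays below 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 1000003) %% 2147483629L + 1)
}

# Deterministic 31-bit polynomial hash of a character vector, returned as
# 8 hex digits. Used only as a provenance stamp in output file headers.
# Exact in double arithmetic: intermediates stay below 2^53.
stamp_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)

is_prob <- function(x) is_scalar_num(x) && x >= 0 && x <= 1
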