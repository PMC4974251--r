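#' @keywords internal
"_PACKAGE"

# Deterministic seed splitting: every stochastic stage derives its own seed
# from the master seed plus integer keys (subject, session, channel, ...), so
# runs are reproducible and sub-streams are decoupled. Kept below 2^31 - 1.
#' Derive a child seed from a master seed and integer keys
#'
#' All randomness in the package flows from one explicit master seed via this
#' splitting scheme (per subject, session, trial, channel...). The mixing is a
#' small multiplicative-congruential hash; child seeds are valid R seeds.
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647
  s <- 11
  for (k in keys) {
    k <- as.numeric(k) %% m
    # 48271 is a classic MINSTD multiplier; arithmetic stays exact in doubles
    s <- (s * 48271 + k * 16807 + 12345) %% m
  }
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# `seed` is forced first: a caller may compute it from the ambient RNG, and
# that draw must not be rolled back by the restore.
with_seed <- function(seed, code) {
  force(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ms -> 0-based sample index under the package-wide convention
# sample = round(onset_ms * fs / 1000)
ms_to_sample <- function(ms, fs) as.integer(round(ms * fs / 1000))

sample_to_ms <- function(idx, fs) idx / fs * 1000

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Tiny FNV-1a hash of a deparsed object, for run manifests / cache keys.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 69069 + 1) %% 2^31  # products stay < 2^53, exact in doubles
  }
  sprintf("%08x", as.integer(h))
}
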