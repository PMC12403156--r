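# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. `seed = NULL` uses the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character string, returned as a non-negative double
# below 2^31. Used to derive per-stage seeds and to fingerprint configs.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 2^32
  }
  h %% 2^31
}

#' Derive a stage-specific random seed from a global seed
#'
#' A single pipeline seed is folded with the stage name so that stages draw
#' from independent, reproducible streams and can be rerun in isolation.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"hmm"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  as.integer((as.numeric(seed) * 2654435761 + fnv1a32(stage)) %% (2^31 - 1))
}

# Deterministic fingerprint of an R object (configs); stable across sessions.
config_hash <- function(x) {
  sprintf("%08x", fnv1a32(paste(deparse(x), collapse = "\n")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
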