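#' Derive a stage seed from a master seed
#'
#' Every randomised step of the pipeline draws from its own named stream so
#' that adding or reordering steps never perturbs the draws of another step.
#' The stream seed is a deterministic hash of `(seed, stream, index)` kept
#' below 2^31 so it is a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param stream character stream name (e.g. `"annotations"`, `"shadow"`).
#' @param index optional integer sub-index (e.g. dataset id or iteration).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  mod <- 2147483647
  h <- as.double(seed) %% mod
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% mod
  h <- (h * 31 + as.double(index) %% mod) %% mod
  as.integer(h)
}

# canonical key for an unordered pair, used for dedup / disjointness checks
pair_keys <- function(p1, p2) {
  paste(pmin(p1, p2), pmax(p1, p2), sep = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
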