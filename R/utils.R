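#' Derive a child seed from a master seed
#'
#' All stochastic operations in the package draw their randomness from a
#' single master seed through this counter-based derivation, so that adding
#' trials or conditions to an experiment never perturbs the random streams of
#' earlier ones. Children are kept below 2^31 - 1 so they are always valid R
#' integer seeds.
#'
#' @param seed Master seed (single integer).
#' @param counter Non-negative integer counter (vectorised).
#' @return Integer vector of derived seeds.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  x <- (as.double(seed) %% m) + 1
  # two rounds of a Lehmer-style mix keep distinct counters well separated
  x <- (x * 48271) %% m
  out <- (x + (as.double(counter) + 1) * 2654435) %% m
  as.integer((out * 16807) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

#' @keywords internal
hash_of <- function(x) {
  # small content hash for run manifests (stable across sessions; not crypto)
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)), collapse = "\n")
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
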