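#' Derive independent sub-seeds from a master seed
#'
#' Every stochastic pipeline stage takes its own integer seed; this helper
#' expands one user-facing seed into reproducible per-stage seeds (all
#' below 2^31).
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}
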