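#' Derive a step-specific seed from a global seed
#'
#' Every randomized step in the pipeline draws its own seed deterministically
#' from one global seed so that a whole run is reproducible from a single
#' integer. The derivation hashes the step name into an integer and combines
#' it with the global seed by a multiplicative congruential step modulo
#' 2^31 - 1 (all arithmetic exact in doubles).
#'
#' @param seed Integer global seed.
#' @param step Character step name, e.g. `"replicate-noise"`.
#' @return An integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(1, "split")
#' @export
derive_seed <- function(seed, step) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.character(step), length(step) == 1)
  codes <- utf8ToInt(step)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer(1 + (abs(seed) * 48271 + h * 69621) %% 2147483645)
}

# Run code with a temporary RNG state seeded from (seed, step).
with_step_seed <- function(seed, step, code) {
  withr::with_seed(derive_seed(seed, step), code)
}
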