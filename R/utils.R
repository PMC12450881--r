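# Seeding helpers: all randomness flows from one user seed through
# derived stream seeds, and never disturbs the caller's RNG state.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's `.Random.seed`
#' so package functions never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream seed from a base seed and a counter
#'
#' Deterministic splitting so that independent generator calls (traits,
#' genotypes, EM replicates, ...) draw from distinct streams of one base
#' seed. Result stays within the 32-bit integer range.
#'
#' @param seed base integer seed.
#' @param counter non-negative integer stream index.
#' @return derived integer seed.
#' @keywords internal
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 100003 + as.numeric(counter) * 7919) %% 2147483629) + 1L
}
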