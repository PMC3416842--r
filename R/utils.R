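# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards.  All user-facing randomness in the
# package flows through this helper so runs are reproducible from recorded
# seeds alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive independent child seeds from a master seed
#'
#' Draws `n` distinct integer seeds (all below 2^31) from a stream seeded by
#' `seed`, without disturbing the caller's RNG state.  Used to give each
#' protocol component (pattern draw, corruption, dilution mask, thermal
#' noise) its own reproducible stream.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
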