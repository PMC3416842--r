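#' Symmetric (associative-memory) Hebbian coupling matrix
#'
#' Builds the symmetric outer-product part of the synaptic matrix,
#' `Xi^s_ij = (1/N) sum_mu xi^mu_i xi^mu_j` with zero diagonal.  Patterns
#' stored this way become independent fixed-point attractors of the
#' zero-temperature dynamics at low load.
#'
#' @param pats a [pattern_set()] (`P x N`).
#' @return A dense `N x N` numeric matrix (one "part"; combine with
#'   [mix_parts()]).
#' @export
build_symmetric <- function(pats) {
  w <- crossprod(pats) / ncol(pats)   # (1/N) sum_mu xi_i xi_j
  diag(w) <- 0
  unclass(w)
}

#' Asymmetric (sequence) Hebbian coupling matrix
#'
#' Builds the sequence part `Xi^a_ij = (1/N) sum_mu xi^(mu+1)_i xi^mu_j`,
#' where the pattern index is taken modulo `P` (the successor of the last
#' pattern is the first).  Applied to pattern `mu`, this matrix produces a
#' field aligned with pattern `mu + 1`, so the whole set is stored as one
#' cyclic attractor of period `P` traversed one pattern per synchronous
#' update.
#'
#' @inheritParams build_symmetric
#' @return A dense `N x N` numeric matrix with zero diagonal.
#' @export
build_asymmetric <- function(pats) {
  p <- nrow(pats)
  succ <- pats[c(seq_len(p)[-1], 1L), , drop = FALSE]  # row mu -> pattern mu+1 (mod P)
  w <- crossprod(succ, pats) / ncol(pats)              # (1/N) sum_mu xi^{mu+1}_i xi^mu_j
  diag(w) <- 0
  unclass(w)
}

#' Mix the symmetric and asymmetric parts into one synaptic matrix
#'
#' The full coupling matrix is the weighted combination
#' `J = nu * sym + (1 - nu) * asym`.  `nu = 1` leaves only the symmetric
#' part (the classical Hopfield model, pure associative memory); `nu = 0`
#' leaves only the asymmetric part (the asymmetric Hopfield model, pure
#' sequence retrieval); intermediate values put the two dynamics in
#' competition.
#'
#' @param sym_part,asym_part `N x N` matrices from [build_symmetric()] and
#'   [build_asymmetric()].
#' @param nu mixture parameter in `[0, 1]`.
#' @param variant `"one_set"` if both parts were built from the same pattern
#'   set, `"two_set"` if from independent sets (bookkeeping only; the
#'   algebra is identical).
#' @return An object of class `synaptic_matrix`: a list with elements
#'   `weights` (`N x N`), `mask` (`NULL` until [dilute()]d), `nu`,
#'   `variant`, `in_degree` (`"full"` or an integer).
#' @export
mix_parts <- function(sym_part, asym_part, nu, variant = c("one_set", "two_set")) {
  variant <- match.arg(variant)
  if (nu < 0 || nu > 1) stop("nu must lie in [0, 1]")
  if (!all(dim(sym_part) == dim(asym_part)))
    stop("symmetric and asymmetric parts have different shapes")
  structure(list(weights = nu * sym_part + (1 - nu) * asym_part,
                 mask = NULL, nu = nu, variant = variant, in_degree = "full"),
            class = "synaptic_matrix")
}

#' @export
print.synaptic_matrix <- function(x, ...) {
  cat(sprintf("<synaptic_matrix> %d x %d, nu = %g, variant = %s, in-degree = %s\n",
              nrow(x$weights), ncol(x$weights), x$nu, x$variant,
              format(x$in_degree)))
  invisible(x)
}

#' Build the full network coupling matrix from pattern sets
#'
#' Convenience wrapper: `build_network(am, nu = ...)` builds the one-set
#' model (the same patterns feed both parts); supplying an independent
#' `spr_set` builds the two-set model in which the symmetric part stores
#' `am_set` and the asymmetric part stores `spr_set`.
#'
#' @param am_set pattern set feeding the symmetric part.
#' @param spr_set optional independent pattern set feeding the asymmetric
#'   part; `NULL` (default) reuses `am_set` (one-set model).
#' @param nu mixture parameter in `[0, 1]`.
#' @return A `synaptic_matrix` (see [mix_parts()]).
#' @export
build_network <- function(am_set, spr_set = NULL, nu = 0.5) {
  if (is.null(spr_set)) {
    mix_parts(build_symmetric(am_set), build_asymmetric(am_set), nu, "one_set")
  } else {
    if (ncol(am_set) != ncol(spr_set))
      stop("the two pattern sets must have the same number of neurons")
    mix_parts(build_symmetric(am_set), build_asymmetric(spr_set), nu, "two_set")
  }
}

#' Randomly dilute the coupling matrix to a fixed in-degree
#'
#' Each neuron keeps exactly `in_degree` incoming connections, chosen
#' uniformly at random from the other `N - 1` neurons; all other incoming
#' weights are zeroed.  The connectivity mask is drawn once and fixed
#' thereafter.  Kept weights are rescaled by `N / in_degree` so the local
#' fields keep their fully connected magnitude in expectation, which also
#' means the effective load of a diluted network is `P / in_degree` rather
#' than `P / N`.
#'
#' @param J a `synaptic_matrix`.
#' @param in_degree number of incoming connections per neuron,
#'   `1 <= in_degree < N`.
#' @param seed integer seed for the mask draw.
#' @param rescale rescale kept weights by `N / in_degree` (default `TRUE`).
#' @return The diluted `synaptic_matrix`, with `mask` set.
#' @export
dilute <- function(J, in_degree, seed = 1L, rescale = TRUE) {
  n <- nrow(J$weights)
  if (in_degree < 1 || in_degree >= n)
    stop("in_degree must satisfy 1 <= in_degree < N")
  mask <- with_seed(seed, {
    m <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      keep <- sample(seq_len(n)[-i], in_degree)
      m[i, keep] <- TRUE
    }
    m
  })
  w <- J$weights
  w[!mask] <- 0
  if (rescale) w <- w * (n / in_degree)
  J$weights <- w
  J$mask <- mask
  J$in_degree <- as.integer(in_degree)
  J
}
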