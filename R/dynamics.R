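#' Configuration of the parallel stochastic dynamics
#'
#' @param temperature statistical temperature `T >= 0`; `beta = 1/T`.  At
#'   `T = 0` the update is the deterministic map
#'   `sigma_i(t+1) = sign(h_i(t))`, with the tie-break `sign(0) = +1`.
#' @param external_field length-`N` vector of external fields `theta_i`, or
#'   `NULL` for none (the default; external fields are a formal device and
#'   all protocols run without them).
#' @param seed integer master seed for the thermal noise.
#' @return An object of class `dynamics_config`.
#' @export
dynamics_config <- function(temperature = 0, external_field = NULL, seed = 1L) {
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(temperature = temperature, external_field = external_field,
                 seed = as.integer(seed)),
            class = "dynamics_config")
}

#' Local fields of a network state
#'
#' Computes `h_i = sum_j J_ij sigma_j + theta_i`, the field each neuron
#' feels given the current state.
#'
#' @param J a `synaptic_matrix` (or a plain `N x N` matrix).
#' @param state length-`N` spin vector.
#' @param external_field optional length-`N` vector of `theta_i`.
#' @return Length-`N` numeric vector of fields.
#' @export
local_fields <- function(J, state, external_field = NULL) {
  w <- if (inherits(J, "synaptic_matrix")) J$weights else J
  if (ncol(w) != length(state)) stop("state length does not match J")
  h <- as.numeric(w %*% state)
  if (!is.null(external_field)) {
    if (length(external_field) != length(h))
      stop("external_field length does not match J")
    h <- h + external_field
  }
  h
}

#' One synchronous update of all spins
#'
#' All neurons are updated simultaneously from the same previous state
#' (parallel Glauber / Little-model updating): each new spin is `+1` with
#' probability `exp(beta h_i) / (2 cosh(beta h_i))`, i.e.
#' `(1 + tanh(beta h_i)) / 2`, independently across neurons.  At
#' `temperature = 0` this degenerates to the deterministic map
#' `sign(h_i)` with `sign(0) = +1`.
#'
#' @param state length-`N` spin vector.
#' @param J a `synaptic_matrix`.
#' @param config a [dynamics_config()]; thermal randomness uses the current
#'   RNG stream (seed it once per trajectory, e.g. via [run_trajectory()]).
#' @return The next state (length-`N` spin vector).
#' @export
net_step <- function(state, J, config) {
  h <- local_fields(J, state, config$external_field)
  if (config$temperature == 0) {
    s <- ifelse(h >= 0, 1, -1)          # sign(0) = +1, documented tie-break
  } else {
    p_up <- 0.5 * (1 + tanh(h / config$temperature))
    s <- ifelse(stats::runif(length(h)) < p_up, 1, -1)
  }
  as.numeric(s)
}

#' Run a trajectory of the parallel dynamics
#'
#' Iterates [net_step()] `n_steps` times from `init`, seeding the thermal
#' noise from `config$seed` so trajectories are reproducible.
#'
#' @param J a `synaptic_matrix`.
#' @param init initial spin vector.
#' @param n_steps number of synchronous updates.
#' @param config a [dynamics_config()].
#' @param keep_path if `TRUE` return all intermediate states.
#' @return If `keep_path`, a `(n_steps + 1) x N` matrix of states (row 1 is
#'   `init`); otherwise the final state vector.
#' @export
run_trajectory <- function(J, init, n_steps, config, keep_path = FALSE) {
  init <- as.numeric(init)
  with_seed(config$seed, {
    if (keep_path) {
      path <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(init))
      path[1L, ] <- init
      s <- init
      for (t in seq_len(n_steps)) {
        s <- net_step(s, J, config)
        path[t + 1L, ] <- s
      }
      path
    } else {
      s <- init
      for (t in seq_len(n_steps)) s <- net_step(s, J, config)
      s
    }
  })
}

#' Associative-memory retrieval protocol
#'
#' For each tested pattern: corrupt it by `flip_fraction`, evolve the
#' network `transient` synchronous steps, and measure the overlap with the
#' original pattern.  The protocol score is the average overlap over the
#' tested patterns.
#'
#' @param J a `synaptic_matrix`.
#' @param pattern_set the AM [pattern_set()] whose rows are tested.
#' @param flip_fraction initial corruption (default 0.1: the state starts
#'   90% correct).
#' @param transient number of update steps before measuring (default 35).
#' @param config a [dynamics_config()]; its seed spawns independent
#'   per-pattern streams.
#' @param patterns indices of the patterns to test (default: all rows).
#' @return Mean overlap, with the per-pattern overlaps in attribute
#'   `per_pattern`.
#' @export
run_am_protocol <- function(J, pattern_set, flip_fraction = 0.1,
                            transient = 35L, config = dynamics_config(),
                            patterns = seq_len(nrow(pattern_set))) {
  if (nrow(pattern_set) == 0L) stop("empty pattern set")
  seeds <- derive_seeds(config$seed, 2L * length(patterns))
  ms <- vapply(seq_along(patterns), function(k) {
    mu <- patterns[k]
    init <- corrupt(pattern_set[mu, ], flip_fraction, seed = seeds[2L * k - 1L])
    cfg <- config
    cfg$seed <- seeds[2L * k]
    fin <- run_trajectory(J, init, transient, cfg)
    overlap(fin, pattern_set[mu, ])
  }, numeric(1))
  structure(mean(ms), per_pattern = ms)
}

#' Sequential-pattern-recognition retrieval protocol
#'
#' Corrupts one sequence pattern by `flip_fraction`, evolves the network for
#' `transient` steps (by default three periods of the supposed cycle), then
#' follows the dynamics for one further period of `P` steps, comparing the
#' state at each step with the stored sequence advanced in order.  The cycle
#' phase is aligned at the first post-transient step to the pattern with the
#' maximum (signed) overlap.  The score is the average of the `P` overlaps
#' around the cycle.
#'
#' @param J a `synaptic_matrix`.
#' @param sequence_set the SPR [pattern_set()] storing the cycle, in order.
#' @param flip_fraction initial corruption (default 0.1).
#' @param transient steps before the measured period (default `3 * P`).
#' @param config a [dynamics_config()].
#' @param start_index which sequence pattern the initial state is a
#'   corrupted copy of.
#' @return Mean cyclic overlap, with the per-step overlaps in attribute
#'   `per_step` and the aligned phase in attribute `phase`.
#' @export
run_spr_protocol <- function(J, sequence_set, flip_fraction = 0.1,
                             transient = NULL, config = dynamics_config(),
                             start_index = 1L) {
  p <- nrow(sequence_set)
  if (p == 0L) stop("empty sequence set")
  if (is.null(transient)) transient <- 3L * p
  seeds <- derive_seeds(config$seed, 2L)
  init <- corrupt(sequence_set[start_index, ], flip_fraction, seed = seeds[1])
  cfg <- config
  cfg$seed <- seeds[2]
  state <- run_trajectory(J, init, transient, cfg)
  # Phase alignment: the sequence index best matching the first
  # post-transient state.
  m0 <- as.numeric(sequence_set %*% state) / ncol(sequence_set)
  phase <- which.max(m0)
  ms <- numeric(p)
  with_seed(seeds[2] + 1L, {
    for (k in seq_len(p)) {
      state <- net_step(state, J, cfg)
      expected <- ((phase + k - 1L) %% p) + 1L
      ms[k] <- overlap(state, sequence_set[expected, ])
    }
  })
  structure(mean(ms), per_step = ms, phase = phase)
}

#' Detect the attractor of the zero-temperature map
#'
#' At `T = 0` the synchronous dynamics are a deterministic map on a finite
#' state space, so every trajectory is eventually periodic.  Iterates from
#' `state` until a previously visited state recurs (or `horizon` steps have
#' been taken) and reports what was found.
#'
#' @param J a `synaptic_matrix`.
#' @param state initial spin vector.
#' @param config a [dynamics_config()] with `temperature = 0` (nonzero
#'   temperature is rejected: stochastic trajectories have no exact
#'   recurrences).
#' @param horizon maximum number of steps to try.
#' @return A list of class `attractor_report`: `kind` (`"fixed_point"`,
#'   `"cycle"`, or `"none"`), `period` (1 for a fixed point), `entry_time`
#'   (first step at which the recurring state was visited).
#' @export
detect_attractor <- function(J, state, config = dynamics_config(), horizon = 1000L) {
  if (config$temperature != 0)
    stop("detect_attractor requires temperature = 0 (deterministic map)")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(s) rawToChar(as.raw(44L + s))  # +1 -> '-', -1 -> '+'; bijective
  s <- as.numeric(state)
  assign(key(s), 0L, envir = seen)
  t <- 0L
  while (t < horizon) {
    s <- net_step(s, J, config)
    t <- t + 1L
    k <- key(s)
    if (!is.null(first <- seen[[k]])) {
      period <- t - first
      return(structure(list(kind = if (period == 1L) "fixed_point" else "cycle",
                            period = period, entry_time = first),
                       class = "attractor_report"))
    }
    assign(k, t, envir = seen)
  }
  structure(list(kind = "none", period = NA_integer_, entry_time = NA_integer_),
            class = "attractor_report")
}

#' @export
print.attractor_report <- function(x, ...) {
  cat(sprintf("<attractor_report> kind = %s, period = %s, entry_time = %s\n",
              x$kind, format(x$period), format(x$entry_time)))
  invisible(x)
}

#' Sweep the mixture parameter and score both retrieval protocols
#'
#' For each value of `nu`, builds the network (one-set: a single pattern set
#' feeds both parts; two-set: two independent sets), optionally dilutes it,
#' runs the AM protocol on the fixed-point set and the SPR protocol on the
#' sequence set, and records the two mean overlaps.  In the two-set model
#' there is an interval of `nu` where both overlaps are high (the two kinds
#' of retrieval coexist); in the one-set model there is none.
#'
#' @param variant `"one_set"` or `"two_set"`.
#' @param nu_grid numeric vector of mixture values to sweep.
#' @param n_neurons network size `N`.
#' @param p_am,p_spr number of fixed-point and sequence patterns (one-set
#'   uses `p_am` for both roles).
#' @param in_degree in-degree `K` for [dilute()], or `NULL` for full
#'   connectivity.
#' @param flip_fraction,transient_am protocol parameters (see
#'   [run_am_protocol()]); the SPR transient is `3 * p_spr`.
#' @param temperature dynamics temperature.
#' @param seed master seed (patterns, dilution and thermal noise all derive
#'   from it).
#' @param out optional CSV path, written via [write_results()].
#' @return A `data.frame` with columns `nu`, `overlap_am`, `overlap_spr`,
#'   `seed`.
#' @export
sweep_nu <- function(variant = c("two_set", "one_set"),
                     nu_grid = seq(0, 1, by = 0.1),
                     n_neurons = 2000L, p_am = 10L, p_spr = 10L,
                     in_degree = 500L, flip_fraction = 0.1,
                     transient_am = 35L, temperature = 0, seed = 1L,
                     out = NULL) {
  variant <- match.arg(variant)
  seeds <- derive_seeds(seed, 4L)
  am <- generate_random_patterns(n_neurons, p_am, role = "AM", seed = seeds[1])
  spr <- if (variant == "two_set")
    generate_random_patterns(n_neurons, p_spr, role = "SPR", seed = seeds[2])
  else pattern_set(unclass(am)[seq_len(p_am), , drop = FALSE], role = "SPR")
  sym <- build_symmetric(am)
  asym <- build_asymmetric(spr)
  res <- lapply(nu_grid, function(nu) {
    J <- mix_parts(sym, asym, nu, variant)
    if (!is.null(in_degree)) J <- dilute(J, in_degree, seed = seeds[3])
    cfg <- dynamics_config(temperature = temperature, seed = seeds[4])
    m_am <- run_am_protocol(J, am, flip_fraction, transient_am, cfg)
    m_spr <- run_spr_protocol(J, spr, flip_fraction, config = cfg)
    data.frame(nu = nu, overlap_am = as.numeric(m_am),
               overlap_spr = as.numeric(m_spr), seed = seed)
  })
  res <- do.call(rbind, res)
  if (!is.null(out))
    write_results(res, out, metadata = list(command = "sweep_nu",
                                            variant = variant, seed = seed))
  res
}
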