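# Mean-field stationary theory of the mixed-synapse network.
#
# Four stationary order-parameter systems are implemented, one per
# (dynamics, variant) combination.  Unknowns: the condensed overlap m, the
# interference variance r (variance of the non-condensed overlaps, scaled
# so the condensed field noise is sqrt(alpha * r) * z with z standard
# normal), and the persistent state correlation C.  The single-site
# susceptibility is chi = beta * (1 - C).
#
# Structure of the systems (derived by a signal-to-noise / linear-response
# analysis of the synchronous dynamics; see the methods vignette):
#
#   m = << tanh(beta * h) >>,   C = << tanh^2(beta * h) >>,
#   h = sig * m + s * drag * m + z * sqrt(alpha * r),  s = +/-1 equiprobable
#
# with signal weight sig = nu (AM) or 1 - nu (SPR), and a macroscopic
# "drag" field of weight drag = 1 - nu (one-set AM: the asymmetric part
# pushes a fixed point toward its successor pattern) or nu (one-set SPR:
# the symmetric part drags the cycle back toward the current pattern);
# drag = 0 in the two-set model, whose sets are independent.
#
# The interference variance closes as r = C * S(chi) with
#   one-set AM :  S = 1 / [(1 - nu chi)^2 - (1 - nu)^2 chi^2]
#   one-set SPR:  S = 1 / [1 - (nu^2 + (1 - nu)^2) chi^2]
#   two-set AM :  S = nu^2/(1 - nu chi)^2 + (1-nu)^2/(1 - (1-nu)^2 chi^2)
#   two-set SPR:  S = nu^2/(1 - nu^2 chi^2) + (1-nu)^2/(1 - (1-nu)^2 chi^2)
# Frozen (fixed-point) states accumulate own-set interference coherently,
# giving (1 - g chi)^-2 factors; cycling states accumulate it with fresh
# signs each step, giving (1 - g^2 chi^2)^-1 factors.

.mf_cache <- new.env(parent = emptyenv())

.gh_rule <- function(order) {
  key <- paste0("gh", order)
  if (is.null(.mf_cache[[key]])) {
    gh <- pracma::gaussHermite(order)
    .mf_cache[[key]] <- list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
  }
  .mf_cache[[key]]
}

.gl_rule <- function(order = 200, half_width = 25) {
  key <- paste0("gl", order, "_", half_width)
  if (is.null(.mf_cache[[key]])) {
    gl <- pracma::gaussLegendre(order, -half_width, half_width)
    .mf_cache[[key]] <- list(t = gl$x, w = gl$w)
  }
  .mf_cache[[key]]
}

#' Expectation against the standard Gaussian measure
#'
#' Computes `E[f(z)] = integral f(z) exp(-z^2/2)/sqrt(2*pi) dz` by
#' fixed-order Gauss--Hermite quadrature.  The order is fixed (not
#' adaptive) so downstream root searches see a value that is smooth in any
#' parameters of `f`; order 120 gives relative accuracy better than 1e-10
#' for smooth integrands.
#'
#' @param f vectorized function of one argument.
#' @param order quadrature order (>= 80 recommended).
#' @return The scalar expectation.
#' @export
gauss_expectation <- function(f, order = 120L) {
  rule <- .gh_rule(order)
  sum(rule$w * f(rule$z))
}

# E[tanh(beta*(a + b z))] and E[tanh^2(beta*(a + b z))] for scalar a, b >= 0.
# Two regimes: for beta*b <= 1 the integrand is smooth on the Gauss-Hermite
# node spacing; for beta*b > 1 it is kink-like and is computed exactly as a
# sign/erf part plus a correction integral localized at the kink
# (z0 = -a/b, width delta = 1/(beta*b)), evaluated by fixed Gauss-Legendre:
#   E tanh   = erf(a / (sqrt(2) b)) + delta * Int phi(z0 + delta t) (tanh t - sign t) dt
#   E tanh^2 = 1 - delta * Int phi(z0 + delta t) sech^2(t) dt
# Both regimes agree to ~1e-12 at beta*b = 1, so the right-hand sides stay
# continuous in (alpha, T, nu) as required by the bisection solvers.
.tanh_moments <- function(a, b, beta) {
  if (!is.finite(beta)) stop("finite beta required (zero temperature has its own path)")
  if (b < 1e-14) {
    th <- tanh(beta * a)
    return(list(m1 = th, m2 = th^2))
  }
  if (beta * b <= 1) {
    rule <- .gh_rule(120L)
    th <- tanh(beta * (a + b * rule$z))
    list(m1 = sum(rule$w * th), m2 = sum(rule$w * th^2))
  } else {
    delta <- 1 / (beta * b)
    z0 <- -a / b
    rule <- .gl_rule()
    phi <- stats::dnorm(z0 + delta * rule$t)
    m1 <- .erf(a / (sqrt(2) * b)) +
      delta * sum(rule$w * phi * (tanh(rule$t) - sign(rule$t)))
    m2 <- 1 - delta * sum(rule$w * phi * (1 / cosh(rule$t))^2)
    list(m1 = m1, m2 = m2)
  }
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Mean-field context
#'
#' Bundles the control parameters of one stationary system: the load
#' `alpha = P/N`, the mixture `nu`, the temperature, and which of the four
#' systems (AM or SPR dynamics; one-set or two-set synaptic construction)
#' applies.
#'
#' @param alpha load parameter `>= 0`.
#' @param nu mixture parameter in `[0, 1]`.
#' @param temperature `T >= 0`; `T = 0` selects the zero-temperature
#'   saddle-point equations.
#' @param dynamics `"AM"` or `"SPR"`.
#' @param variant `"one_set"` or `"two_set"`.
#' @return Object of class `mf_context`.
#' @export
mf_context <- function(alpha, nu, temperature,
                       dynamics = c("AM", "SPR"),
                       variant = c("two_set", "one_set")) {
  dynamics <- match.arg(dynamics)
  variant <- match.arg(variant)
  if (alpha < 0) stop("alpha must be >= 0")
  if (nu < 0 || nu > 1) stop("nu must lie in [0, 1]")
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(alpha = alpha, nu = nu, temperature = temperature,
                 beta = if (temperature == 0) Inf else 1 / temperature,
                 dynamics = dynamics, variant = variant),
            class = "mf_context")
}

#' @export
print.mf_context <- function(x, ...) {
  cat(sprintf("<mf_context> %s / %s, alpha = %g, nu = %g, T = %g\n",
              x$dynamics, x$variant, x$alpha, x$nu, x$temperature))
  invisible(x)
}

# Signal and drag weights of the condensed field.
.mf_weights <- function(ctx) {
  if (ctx$dynamics == "AM") {
    list(sig = ctx$nu, drag = if (ctx$variant == "one_set") 1 - ctx$nu else 0)
  } else {
    list(sig = 1 - ctx$nu, drag = if (ctx$variant == "one_set") ctx$nu else 0)
  }
}

# Interference amplification factor S(chi); NA when chi is outside the
# validity domain (a denominator hit zero or went negative).
.mf_noise_factor <- function(ctx, chi) {
  nu <- ctx$nu
  if (ctx$variant == "one_set") {
    d <- if (ctx$dynamics == "AM") {
      (1 - nu * chi)^2 - (1 - nu)^2 * chi^2
    } else {
      1 - (nu^2 + (1 - nu)^2) * chi^2
    }
    if (!is.finite(d) || d <= 0) return(NA_real_)
    1 / d
  } else {
    d1 <- if (ctx$dynamics == "AM") (1 - nu * chi)^2 else 1 - nu^2 * chi^2
    d2 <- 1 - (1 - nu)^2 * chi^2
    if (!is.finite(d1) || !is.finite(d2)) return(NA_real_)
    if ((nu > 0 && d1 <= 0) || (nu < 1 && d2 <= 0)) return(NA_real_)
    (if (nu > 0) nu^2 / d1 else 0) + (if (nu < 1) (1 - nu)^2 / d2 else 0)
  }
}

# Upper end of the chi validity interval (first singularity of S).
.chi_limit <- function(ctx) {
  nu <- ctx$nu
  if (ctx$variant == "one_set") {
    if (ctx$dynamics == "AM") 1 else 1 / sqrt(nu^2 + (1 - nu)^2)
  } else {
    lims <- c(if (nu > 0) 1 / nu else Inf, if (nu < 1) 1 / (1 - nu) else Inf)
    min(lims)
  }
}

#' Order-parameter container
#'
#' @param m condensed overlap in `[-1, 1]`.
#' @param r interference (overlap) variance `>= 0`.
#' @param C persistent correlation between network states, in `[0, 1]`.
#' @return A named list of class `order_parameters`.
#' @export
order_parameters <- function(m = 0, r = 0, C = 0) {
  structure(list(m = m, r = r, C = C), class = "order_parameters")
}

#' @export
print.order_parameters <- function(x, ...) {
  cat(sprintf("<order_parameters> m = %.6g, r = %.6g, C = %.6g\n", x$m, x$r, x$C))
  invisible(x)
}

#' One evaluation of the stationary self-consistency map
#'
#' Evaluates the right-hand side of the selected stationary system once:
#' `m' = <<tanh(beta h)>>`, `C' = <<tanh^2(beta h)>>` with
#' `h = sig*m + s*drag*m + z*sqrt(alpha*r)`, and `r' = C * S(chi)` with
#' `chi = beta (1 - C)` (see the file header for the four `S` forms).  A
#' pure function of its inputs; the all-zero point is an exact fixed point
#' of every system.  Requires `temperature > 0` (the zero-temperature limit
#' is handled by its own reduced equations inside [solve_branch()]).
#'
#' @param ctx an [mf_context()] with `temperature > 0`.
#' @param op an [order_parameters()] value.
#' @return The mapped [order_parameters()]; `r` is `NA` if `chi` left the
#'   validity domain of the noise closure.
#' @export
mf_rhs <- function(ctx, op) {
  if (ctx$temperature == 0)
    stop("mf_rhs is the finite-temperature map; use solve_branch for T = 0")
  w <- .mf_weights(ctx)
  b <- sqrt(max(ctx$alpha * op$r, 0))
  signs <- if (w$drag > 0) c(1, -1) else 0
  m1 <- 0; m2 <- 0
  for (s in signs) {
    a <- w$sig * op$m + s * w$drag * op$m
    mm <- .tanh_moments(a, b, ctx$beta)
    m1 <- m1 + mm$m1 / length(signs)
    m2 <- m2 + mm$m2 / length(signs)
  }
  chi <- ctx$beta * (1 - op$C)
  S <- .mf_noise_factor(ctx, chi)
  # C = 0 carries no interference regardless of the amplification factor,
  # so the all-zero point is an exact fixed point even where S is singular.
  order_parameters(m = m1, r = if (op$C == 0) 0 else op$C * S, C = m2)
}

# --- zero-temperature reduced equations --------------------------------

# Zero-T spin-glass susceptibility chi0: solves chi * sqrt(alpha * S(chi))
# = sqrt(2/pi) on (0, chi_limit).  In the T -> 0 limit C -> 1 and
# chi = beta (1 - C) stays finite at this value.
.solve_sg_chi0 <- function(ctx) {
  if (ctx$alpha <= 0) return(NA_real_)
  hi <- min(.chi_limit(ctx) * (1 - 1e-10), 1e6)
  g <- function(chi) {
    S <- .mf_noise_factor(ctx, chi)
    if (is.na(S)) return(Inf)
    chi * sqrt(ctx$alpha * S) - sqrt(2 / pi)
  }
  lo <- 1e-12
  if (g(lo) > 0) return(NA_real_)
  stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
}

# Zero-T iteration on (m, chi): m = E_s erf(h_s / sqrt(2 alpha r)),
# chi = E_s sqrt(2/(pi alpha r)) exp(-h_s^2 / (2 alpha r)), r = S(chi)
# (C = 1 at T = 0).
.solve_zero_t <- function(ctx, branch, tol = 1e-12, max_iter = 10000L,
                          damping = 0.5, m_min = 0.01) {
  w <- .mf_weights(ctx)
  fail <- function(status) list(op = order_parameters(), status = status,
                                branch = branch, iterations = 0L, residual = NA_real_)
  if (branch == "trivial")
    return(list(op = order_parameters(), status = "converged", branch = branch,
                iterations = 0L, residual = 0))
  if (branch == "spin_glass") {
    chi0 <- .solve_sg_chi0(ctx)
    if (is.na(chi0)) return(fail("no_solution"))
    S <- .mf_noise_factor(ctx, chi0)
    return(list(op = order_parameters(m = 0, r = S, C = 1), chi = chi0,
                status = "converged", branch = branch, iterations = 1L,
                residual = 0))
  }
  # retrieval branch
  signs <- if (w$drag > 0) c(1, -1) else 0
  if (ctx$alpha < 1e-12) {
    # noiseless limit: m = E_s sign((sig + s drag) m)
    m <- mean(sign(w$sig + signs * w$drag))
    st <- if (m > m_min) "converged" else "no_solution"
    return(list(op = order_parameters(m = m, r = .mf_noise_factor(ctx, 0), C = 1),
                chi = 0, status = st, branch = branch, iterations = 1L,
                residual = 0))
  }
  m <- 1; chi <- 0
  for (it in seq_len(max_iter)) {
    S <- .mf_noise_factor(ctx, chi)
    if (is.na(S)) return(fail("no_solution"))
    ar <- ctx$alpha * S
    h <- (w$sig + signs * w$drag) * m
    m_new <- mean(.erf(h / sqrt(2 * ar)))
    chi_new <- mean(sqrt(2 / (pi * ar)) * exp(-h^2 / (2 * ar)))
    if (!is.finite(m_new) || !is.finite(chi_new)) return(fail("diverged"))
    res <- max(abs(m_new - m), abs(chi_new - chi))
    m <- (1 - damping) * m + damping * m_new
    chi <- (1 - damping) * chi + damping * chi_new
    if (res < tol) {
      S <- .mf_noise_factor(ctx, chi)
      if (is.na(S)) return(fail("no_solution"))
      status <- if (m > m_min) "converged" else "no_solution"
      return(list(op = order_parameters(m = m, r = S, C = 1), chi = chi,
                  status = status, branch = branch, iterations = it,
                  residual = res))
    }
  }
  fail("no_solution")
}

#' Solve one branch of the stationary equations
#'
#' The `retrieval` branch is solved by damped fixed-point iteration of
#' [mf_rhs()] from the perfectly condensed point (`m = 1, C = 1`); the
#' `spin_glass` branch (where `m = 0` closes the system into one scalar
#' equation in `C`) by bracketed root-finding, which remains stable at low
#' temperature where plain iteration flip-flops; `trivial` returns the
#' all-zero solution immediately.  At `temperature = 0` the
#' saddle-point-reduced equations in `(m, chi)` are iterated instead (the
#' finite-temperature integrands degenerate there).
#'
#' A branch "exists" when the iteration converges to a solution that did
#' not collapse: `m > m_min` for retrieval, `C > 1e-6` for spin-glass.
#' Collapse is reported as status `"no_solution"`; a non-finite iterate as
#' `"diverged"`.
#'
#' @param ctx an [mf_context()].
#' @param branch `"retrieval"`, `"spin_glass"`, or `"trivial"`.
#' @param tol convergence tolerance on the max-norm of successive iterates.
#' @param max_iter iteration cap.
#' @param damping fraction of the new iterate mixed in each step.
#' @param m_min overlap threshold defining retrieval-branch existence.
#' @return A list: `op` (the [order_parameters()]), `status`
#'   (`"converged"`, `"no_solution"`, `"diverged"`), `branch`,
#'   `iterations`, `residual`.
#' @export
solve_branch <- function(ctx, branch = c("retrieval", "spin_glass", "trivial"),
                         tol = 1e-10, max_iter = 10000L, damping = 0.5,
                         m_min = 0.01) {
  branch <- match.arg(branch)
  if (tol <= 0) stop("tol must be > 0")
  if (ctx$temperature == 0)
    return(.solve_zero_t(ctx, branch, tol = min(tol, 1e-12),
                         max_iter = max_iter, damping = damping, m_min = m_min))
  fail <- function(status) list(op = order_parameters(), status = status,
                                branch = branch, iterations = 0L,
                                residual = NA_real_)
  if (branch == "trivial")
    return(list(op = order_parameters(), status = "converged", branch = branch,
                iterations = 0L, residual = 0))
  if (branch == "spin_glass") return(.solve_sg_finite_t(ctx, branch))
  op <- order_parameters(m = 1, r = .mf_noise_factor(ctx, 0), C = 1)
  # keep iterates inside the validity domain of the noise closure: C may
  # not drop so low that chi = beta (1 - C) crosses the first singularity
  # of S.  Below the spin-glass temperature this floor is inactive at the
  # solution itself; above it the floor is negative and never engages, so
  # collapse to the trivial solution is still detected.
  c_floor <- 1 - 0.999 * .chi_limit(ctx) / ctx$beta
  for (it in seq_len(max_iter)) {
    new <- mf_rhs(ctx, op)
    if (branch == "spin_glass") new$m <- 0
    vals <- unlist(new)
    if (any(!is.finite(vals))) return(fail("diverged"))
    res <- max(abs(vals - unlist(op)))
    op <- order_parameters(m = (1 - damping) * op$m + damping * new$m,
                           r = (1 - damping) * op$r + damping * new$r,
                           C = (1 - damping) * op$C + damping * new$C)
    if (op$C < c_floor) op$C <- c_floor
    if (res < tol) {
      collapsed <- if (branch == "retrieval") op$m <= m_min else op$C <= 1e-6
      return(list(op = op, status = if (collapsed) "no_solution" else "converged",
                  branch = branch, iterations = it, residual = res))
    }
  }
  fail("no_solution")
}

#' Spin-glass transition temperature
#'
#' Temperature at which the trivial solution loses stability against
#' spin-glass order: the linearization of the stationary map around the
#' all-zero solution has unit spectral radius when
#' `alpha * beta^2 * S(beta) = 1` (with `S` the interference amplification
#' factor of the selected system).  For the one-set systems this condition
#' is closed-form:
#' `T_sg = nu + sqrt(alpha + (1 - nu)^2)` (AM) and
#' `T_sg = sqrt(alpha + nu^2 + (1 - nu)^2)` (SPR); for the two-set systems
#' the condition is solved by bracketed root-finding.  The result is finite
#' and positive for every `alpha > 0` and `nu` in `[0, 1]`.
#'
#' @param ctx an [mf_context()] (its temperature is ignored).
#' @return The transition temperature `T_sg`.
#' @export
spin_glass_temperature <- function(ctx) {
  alpha <- ctx$alpha; nu <- ctx$nu
  if (alpha <= 0) stop("alpha must be > 0")
  if (ctx$variant == "one_set") {
    if (ctx$dynamics == "AM") nu + sqrt(alpha + (1 - nu)^2)
    else sqrt(alpha + nu^2 + (1 - nu)^2)
  } else {
    f <- if (ctx$dynamics == "AM") {
      function(T) alpha * ((if (nu > 0) nu^2 / (T - nu)^2 else 0) +
                           (if (nu < 1) (1 - nu)^2 / (T^2 - (1 - nu)^2) else 0)) - 1
    } else {
      function(T) alpha * ((if (nu > 0) nu^2 / (T^2 - nu^2) else 0) +
                           (if (nu < 1) (1 - nu)^2 / (T^2 - (1 - nu)^2) else 0)) - 1
    }
    lo <- max(nu, 1 - nu) * (1 + 1e-12) + 1e-12
    hi <- max(nu, 1 - nu) + sqrt(alpha) + 2
    stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  }
}

# Finite-temperature spin-glass branch.  With m = 0 the system closes as a
# single scalar equation in C,
#   G(C) = E[tanh^2(beta z sqrt(alpha C S(beta(1 - C))))] - C = 0 ,
# which is solved by bracketed root-finding on the validity interval of S
# (the damped iteration used for the retrieval branch develops a stable
# flip-flop around this solution at low temperature, where the map slope in
# C passes below -1).  G is positive just above C = 0 exactly when the
# trivial solution is unstable, i.e. below the spin-glass temperature, and
# negative at C -> 1, so a root exists iff spin-glass order does.
.solve_sg_finite_t <- function(ctx, branch) {
  G <- function(C) {
    S <- .mf_noise_factor(ctx, ctx$beta * (1 - C))
    if (is.na(S)) return(1 - C)   # beyond the singularity: huge noise, C' -> 1
    b <- sqrt(max(ctx$alpha * C * S, 0))
    .tanh_moments(0, b, ctx$beta)$m2 - C
  }
  lo <- max(1e-8, 1 - (1 - 1e-9) * .chi_limit(ctx) / ctx$beta)
  no_sol <- list(op = order_parameters(), status = "no_solution",
                 branch = branch, iterations = 0L, residual = NA_real_)
  if (ctx$alpha <= 0 || G(lo) <= 0) return(no_sol)
  root <- stats::uniroot(G, c(lo, 1 - 1e-12), tol = 1e-14)
  C <- root$root
  S <- .mf_noise_factor(ctx, ctx$beta * (1 - C))
  list(op = order_parameters(m = 0, r = C * S, C = C), status = "converged",
       branch = branch, iterations = root$iter, residual = abs(root$f.root))
}

# --- zero-temperature storage capacity ---------------------------------

#' Family of zero-temperature load curves
#'
#' At `T = 0` the stationary system reduces to a one-parameter family: for
#' each value of the reduced variable `x = m / sqrt(2 alpha r)` there is at
#' most one load `alpha(x)` at which a nontrivial root sits at `x`.  The
#' susceptibility is explicit along the family,
#' `chi(x) = E_s (2/sqrt(pi)) exp(-h_s^2 x^2 / m^2) * x / m` with
#' `h_s = (sig + s drag) m`, and
#' `alpha(x) = m(x)^2 / (2 x^2 S(chi(x)))`.  Nontrivial solutions exist at
#' load `alpha` iff `alpha <= max_x alpha(x)`; the maximum is the storage
#' capacity (returns `NA` where the curve is undefined, e.g. beyond the
#' validity domain of `S`).
#'
#' @param x positive reduced variable (vectorized).
#' @param dynamics,variant,nu system selectors as in [mf_context()].
#' @return `alpha(x)`, same length as `x`.
#' @export
zero_t_load_family <- function(x, dynamics, variant, nu) {
  ctx <- mf_context(0, nu, 0, dynamics, variant)
  w <- .mf_weights(ctx)
  signs <- if (w$drag > 0) c(1, -1) else 0
  vapply(x, function(xi) {
    hw <- w$sig + signs * w$drag         # field weights per sign branch
    m <- mean(.erf(hw * xi))
    if (m <= 0) return(NA_real_)
    chi <- mean((2 / sqrt(pi)) * exp(-(hw * xi)^2)) * xi / m
    S <- .mf_noise_factor(ctx, chi)
    if (is.na(S)) return(NA_real_)
    m^2 / (2 * xi^2 * S)
  }, numeric(1))
}

#' Zero-temperature storage capacity
#'
#' The largest load `alpha` for which the zero-temperature stationary
#' equations retain a nontrivial retrieval root, located by scanning the
#' load family of [zero_t_load_family()] and refining its maximum by
#' golden-section search.  Benchmarks: AM/two-set at `nu = 1` gives the
#' classical result `alpha_c ~= 0.138`; SPR at `nu = 0` gives
#' `alpha_c ~= 0.269`.
#'
#' @inheritParams zero_t_load_family
#' @return The capacity `alpha_c` (0 when no retrieval solution exists at
#'   any positive load, e.g. when the signal weight vanishes).
#' @export
capacity_zero_temperature <- function(dynamics, variant, nu) {
  xs <- exp(seq(log(0.01), log(10), length.out = 1200L))
  vals <- zero_t_load_family(xs, dynamics, variant, nu)
  if (all(!is.finite(vals) | vals <= 0)) return(0)
  i <- which.max(ifelse(is.finite(vals), vals, -Inf))
  lo <- xs[max(i - 1L, 1L)]; hi <- xs[min(i + 1L, length(xs))]
  opt <- stats::optimize(function(x) zero_t_load_family(x, dynamics, variant, nu),
                         c(lo, hi), maximum = TRUE, tol = 1e-10)
  max(opt$objective, vals[i])
}

#' Critical load at finite temperature
#'
#' Largest `alpha` at which the retrieval branch still exists at the
#' context's `(temperature, nu)`, found by bisection on the existence of a
#' converged [solve_branch()] retrieval solution, to absolute tolerance
#' `tol_alpha`.  Errors if retrieval does not exist even at the smallest
#' probed load (no bracket).
#'
#' @param ctx an [mf_context()] with `temperature > 0` (at `T = 0` use
#'   [capacity_zero_temperature()]).
#' @param tol_alpha absolute bisection tolerance on `alpha`.
#' @param alpha_min,alpha_max probed load range.
#' @param ... passed on to [solve_branch()].
#' @return The critical load `alpha_c(T, nu)`.
#' @export
critical_alpha <- function(ctx, tol_alpha = 1e-4, alpha_min = 1e-4,
                           alpha_max = 1, ...) {
  if (ctx$temperature <= 0)
    stop("critical_alpha requires finite temperature > 0")
  exists_at <- function(a) {
    c2 <- mf_context(a, ctx$nu, ctx$temperature, ctx$dynamics, ctx$variant)
    solve_branch(c2, "retrieval", ...)$status == "converged"
  }
  if (!exists_at(alpha_min))
    stop("bracket failure: no retrieval solution at alpha = ", alpha_min,
         " (T = ", ctx$temperature, ", nu = ", ctx$nu, ")")
  lo <- alpha_min
  hi <- min(2 * alpha_min, alpha_max)
  while (exists_at(hi)) {
    lo <- hi
    if (hi >= alpha_max)
      stop("bracket failure: retrieval still exists at alpha_max = ", alpha_max)
    hi <- min(hi * 2, alpha_max)
  }
  while (hi - lo > tol_alpha) {
    mid <- (lo + hi) / 2
    if (exists_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
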