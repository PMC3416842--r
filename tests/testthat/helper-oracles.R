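# Independent oracles and shared scaffolding for the test suite.

# Element-wise double-loop Hebbian builders (deliberately naive; these are
# the reference implementations the vectorized builders are checked
# against).
brute_force_symmetric <- function(pats) {
  p <- nrow(pats); n <- ncol(pats)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (mu in seq_len(p)) w[i, j] <- w[i, j] + pats[mu, i] * pats[mu, j] / n
  }
  w
}

brute_force_asymmetric <- function(pats) {
  p <- nrow(pats); n <- ncol(pats)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (mu in seq_len(p)) {
      succ <- if (mu == p) 1L else mu + 1L
      w[i, j] <- w[i, j] + pats[succ, i] * pats[mu, j] / n
    }
  }
  w
}

brute_force_fields <- function(w, state) {
  n <- length(state)
  h <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) h[i] <- h[i] + w[i, j] * state[j]
  h
}

# Rows of the order-8 Hadamard matrix: mutually orthogonal +/-1 vectors.
hadamard8 <- function() {
  h2 <- matrix(c(1, 1, 1, -1), 2, 2)
  kronecker(kronecker(h2, h2), h2)
}

# Trace the retrieval overlap m(T) along a temperature grid by
# continuation: each solve starts from the previous converged solution, so
# a branch is followed until it genuinely disappears.  NA marks grid points
# where the branch no longer exists.
trace_retrieval_overlap <- function(dynamics, variant, nu, alpha, t_grid,
                                    max_iter = 30000L) {
  op <- NULL
  out <- rep(NA_real_, length(t_grid))
  for (i in seq_along(t_grid)) {
    ctx <- mf_context(alpha, nu, t_grid[i], dynamics, variant)
    cur <- if (is.null(op)) order_parameters(1, 1, 1) else op
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      new <- mf_rhs(ctx, cur)
      if (any(!is.finite(unlist(new)))) { ok <- FALSE; break }
      res <- max(abs(unlist(new) - unlist(cur)))
      cur <- order_parameters(0.5 * cur$m + 0.5 * new$m,
                              0.5 * cur$r + 0.5 * new$r,
                              0.5 * cur$C + 0.5 * new$C)
      if (res < 1e-11) break
    }
    if (ok && cur$m > 0.01) { out[i] <- cur$m; op <- cur } else op <- NULL
  }
  out
}

# Numerical Jacobian of the stationary map at the trivial solution, by
# second-order forward (Richardson) differences; valid because the map
# sends the origin exactly to the origin.
trivial_jacobian <- function(ctx, h = 1e-6) {
  f <- function(v) {
    out <- mf_rhs(ctx, order_parameters(v[1], v[2], v[3]))
    c(out$m, out$r, out$C)
  }
  jac <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- 1
    jac[, j] <- (4 * f(h * e) - f(2 * h * e)) / (2 * h)
  }
  jac
}

spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))
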