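test_that("Gaussian expectations are exact for moments and accurate for tanh", {
  expect_equal(gauss_expectation(function(z) rep(1, length(z))), 1)
  expect_equal(gauss_expectation(function(z) z^2), 1)
  oracle <- stats::integrate(function(z) tanh(2 + z) * stats::dnorm(z),
                             -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(gauss_expectation(function(z) tanh(2 + z)), oracle,
               tolerance = 1e-10)
})

test_that("the all-zero point is an exact fixed point of every system", {
  for (dyn in c("AM", "SPR")) for (var in c("one_set", "two_set")) {
    ctx <- mf_context(0.15, 0.6, 0.7, dyn, var)
    out <- mf_rhs(ctx, order_parameters(0, 0, 0))
    expect_identical(c(out$m, out$r, out$C), c(0, 0, 0))
  }
})

test_that("the map is pure and reduces to the noiseless mean-field at alpha = 0", {
  ctx <- mf_context(0.1, 0.5, 0.4, "AM", "two_set")
  op <- order_parameters(0.3, 0.8, 0.6)
  expect_identical(unlist(mf_rhs(ctx, op)), unlist(mf_rhs(ctx, op)))
  # alpha = 0, nu = 1, AM: m' = tanh(beta m)
  for (Tv in c(0.5, 0.9, 1.5)) for (mv in c(0.05, 0.4, 0.9)) {
    ctx0 <- mf_context(0, 1, Tv, "AM", "two_set")
    out <- mf_rhs(ctx0, order_parameters(mv, 0, 0.5))
    expect_equal(out$m, tanh(mv / Tv), tolerance = 1e-12)
  }
})

test_that("one-set and two-set systems coincide at their pure limits", {
  ops <- list(order_parameters(0.2, 0.5, 0.3), order_parameters(0.8, 1.2, 0.9),
              order_parameters(0.05, 0.1, 0.99))
  for (op in ops) {
    a <- mf_rhs(mf_context(0.12, 1, 0.6, "AM", "one_set"), op)
    b <- mf_rhs(mf_context(0.12, 1, 0.6, "AM", "two_set"), op)
    expect_equal(unlist(a), unlist(b), tolerance = 1e-12)
    a <- mf_rhs(mf_context(0.12, 0, 0.6, "SPR", "one_set"), op)
    b <- mf_rhs(mf_context(0.12, 0, 0.6, "SPR", "two_set"), op)
    expect_equal(unlist(a), unlist(b), tolerance = 1e-12)
  }
})

test_that("the retrieval branch exists below capacity and collapses above", {
  s <- solve_branch(mf_context(0.05, 1, 0.1, "AM", "two_set"), "retrieval")
  expect_identical(s$status, "converged")
  expect_gt(s$op$m, 0.9)
  s2 <- solve_branch(mf_context(0.5, 1, 0.1, "AM", "two_set"), "retrieval")
  expect_identical(s2$status, "no_solution")
  tr <- solve_branch(mf_context(0.5, 1, 0.1, "AM", "two_set"), "trivial")
  expect_identical(unlist(tr$op), c(m = 0, r = 0, C = 0))
})

test_that("spin-glass order appears exactly below its transition temperature", {
  for (dyn in c("AM", "SPR")) for (var in c("one_set", "two_set")) {
    ctx <- mf_context(0.1, 0.7, 1, dyn, var)
    tsg <- spin_glass_temperature(ctx)
    expect_true(is.finite(tsg) && tsg > 0)
    below <- solve_branch(mf_context(0.1, 0.7, tsg - 0.01, dyn, var), "spin_glass")
    above <- solve_branch(mf_context(0.1, 0.7, tsg + 0.01, dyn, var), "spin_glass")
    expect_identical(below$status, "converged")
    expect_gt(below$op$C, 0)
    expect_identical(above$status, "no_solution")
  }
  # continuity along a load grid (closed form / smooth root)
  tsg <- vapply(seq(0.02, 0.4, by = 0.02), function(a)
    spin_glass_temperature(mf_context(a, 0.3, 1, "AM", "one_set")), numeric(1))
  expect_true(all(abs(diff(tsg)) < 0.05))
  expect_error(spin_glass_temperature(mf_context(0, 0.5, 1, "AM", "one_set")),
               "alpha")
})

test_that("zero-temperature capacities match independent root-scan oracles", {
  # classical fixed-point capacity: erf(x) = x (sqrt(2a) + 2/sqrt(pi) e^-x^2)
  hopfield_family <- function(x)
    0.5 * (pracma::erf(x) / x - (2 / sqrt(pi)) * exp(-x^2))^2
  # sequence capacity: 2a = (erf(x)/x)^2 - (4/pi) e^-2x^2
  sequence_family <- function(x)
    0.5 * ((pracma::erf(x) / x)^2 - (4 / pi) * exp(-2 * x^2))
  o_hop <- stats::optimize(hopfield_family, c(0.5, 3), maximum = TRUE)$objective
  o_seq <- stats::optimize(sequence_family, c(0.5, 3), maximum = TRUE)$objective
  expect_equal(capacity_zero_temperature("AM", "two_set", 1), o_hop,
               tolerance = 1e-6)
  expect_equal(capacity_zero_temperature("SPR", "two_set", 0), o_seq,
               tolerance = 1e-6)
  # the two variants agree where they describe the same model
  expect_equal(capacity_zero_temperature("SPR", "one_set", 0),
               capacity_zero_temperature("SPR", "two_set", 0), tolerance = 1e-9)
  # AM capacity shrinks as the symmetric weight shrinks
  caps <- vapply(c(1, 0.8, 0.6, 0.4), function(nu)
    capacity_zero_temperature("AM", "two_set", nu), numeric(1))
  expect_true(all(diff(caps) < 0))
  # no retrieval without signal
  expect_identical(capacity_zero_temperature("AM", "two_set", 0), 0)
})

test_that("finite-temperature critical load is consistent and monotone", {
  cap0 <- capacity_zero_temperature("AM", "two_set", 1)
  ca <- critical_alpha(mf_context(0, 1, 1e-3, "AM", "two_set"))
  expect_lt(abs(ca - cap0), 1e-2)
  cas <- vapply(c(0.05, 0.2, 0.4), function(T)
    critical_alpha(mf_context(0, 1, T, "AM", "two_set")), numeric(1))
  expect_true(all(diff(cas) <= 0))
  # far above every retrieval region the bracket fails loudly
  expect_error(critical_alpha(mf_context(0, 1, 3, "AM", "two_set")),
               "bracket failure")
})
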