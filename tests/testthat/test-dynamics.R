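test_that("local fields follow h = J sigma + theta", {
  pats <- generate_random_patterns(6, 2, seed = 1)
  J <- build_network(pats, nu = 0.7)
  st <- generate_random_patterns(6, 1, seed = 2)[1, ]
  expect_equal(local_fields(J, st), brute_force_fields(J$weights, st))
  expect_equal(local_fields(J, rep(0, 6)), rep(0, 6))
  theta <- rnorm(6)
  expect_equal(local_fields(J, st, theta),
               brute_force_fields(J$weights, st) + theta)
  # a single stored pattern produces a field aligned with itself
  p1 <- generate_random_patterns(100, 1, seed = 3)
  J1 <- build_network(p1, nu = 1)
  expect_identical(sign(local_fields(J1, p1[1, ])), p1[1, ])
  expect_error(local_fields(J, c(1, -1)), "match")
})

test_that("synchronous update has the stated thermal and deterministic limits", {
  p1 <- generate_random_patterns(100, 1, seed = 4)
  J1 <- build_network(p1, nu = 1)
  cfg0 <- dynamics_config(0, seed = 1)
  # T = 0: a stored pattern is a fixed point
  expect_identical(net_step(p1[1, ], J1, cfg0), p1[1, ])
  # T = 0 with positive fields: all-plus state
  ones <- structure(list(weights = matrix(1 / 100, 100, 100), mask = NULL,
                         nu = 1, variant = "one_set", in_degree = "full"),
                    class = "synaptic_matrix")
  expect_identical(net_step(rep(1, 100), ones, cfg0), rep(1, 100))
  # T -> infinity: each spin is +1 with probability 1/2 regardless of h
  big <- generate_random_patterns(10000, 1, seed = 5)
  Jb <- build_network(big, nu = 1)
  cfg_inf <- dynamics_config(Inf, seed = 2)
  s <- run_trajectory(Jb, big[1, ], 1, cfg_inf)
  expect_lt(abs(mean(s == 1) - 0.5), 5 * 0.5 / sqrt(10000))
  expect_error(dynamics_config(-1), ">= 0")
})

test_that("updates are synchronous: relabeling neurons commutes with a step", {
  pats <- generate_random_patterns(60, 3, seed = 6)
  J <- build_network(pats, nu = 0.4)
  st <- corrupt(pats[1, ], 0.2, seed = 7)
  cfg <- dynamics_config(0, seed = 1)
  perm <- sample(60)
  Jp <- J; Jp$weights <- J$weights[perm, perm]
  expect_identical(net_step(as.numeric(st)[perm], Jp, cfg),
                   net_step(as.numeric(st), J, cfg)[perm])
})

test_that("the AM protocol retrieves a single stored pattern from 10% noise", {
  p1 <- generate_random_patterns(2000, 1, seed = 8)
  J <- build_network(p1, nu = 1)
  cfg <- dynamics_config(0, seed = 3)
  expect_equal(as.numeric(run_am_protocol(J, p1, 0.1, 35, cfg)), 1)
  # zero corruption at a fixed point needs no steps at all
  expect_equal(as.numeric(run_am_protocol(J, p1, 0, 0L, cfg)), 1)
  # determinism under a fixed seed (nonzero temperature)
  cfgT <- dynamics_config(0.3, seed = 11)
  expect_identical(as.numeric(run_am_protocol(J, p1, 0.1, 10, cfgT)),
                   as.numeric(run_am_protocol(J, p1, 0.1, 10, cfgT)))
  expect_error(run_am_protocol(J, p1[0, , drop = FALSE]), "empty")
})

test_that("the SPR protocol follows the cycle where sequence retrieval is stable", {
  spr <- generate_random_patterns(2000, 5, role = "SPR", seed = 9)
  J <- build_network(spr, nu = 0)          # pure asymmetric, small load
  cfg <- dynamics_config(0, seed = 4)
  m <- run_spr_protocol(J, spr, 0.1, config = cfg)
  expect_gt(as.numeric(m), 0.99)
  expect_identical(as.numeric(run_spr_protocol(J, spr, 0.1, config = cfg)),
                   as.numeric(m))
  # nu = 1 leaves no asymmetric part: an independent sequence is not followed
  am <- generate_random_patterns(2000, 5, seed = 10)
  J1 <- build_network(am, spr, nu = 1)
  m1 <- run_spr_protocol(J1, spr, 0.1, config = cfg)
  expect_lt(abs(as.numeric(m1)), 0.2)
  expect_error(run_spr_protocol(J, spr[0, , drop = FALSE]), "empty")
})

test_that("attractor detection reports fixed points, cycles, and horizon misses", {
  am <- generate_random_patterns(800, 3, seed = 11)
  J <- build_network(am, nu = 1)
  cfg <- dynamics_config(0, seed = 5)
  rep_fp <- detect_attractor(J, am[1, ], cfg)
  expect_identical(rep_fp$kind, "fixed_point")
  expect_identical(rep_fp$period, 1L)
  spr <- generate_random_patterns(800, 5, role = "SPR", seed = 12)
  Ja <- build_network(spr, nu = 0)
  start <- corrupt(spr[1, ], 0.1, seed = 13)
  rep_cy <- detect_attractor(Ja, start, cfg, horizon = 200)
  expect_identical(rep_cy$kind, "cycle")
  expect_identical(rep_cy$period, 5L)
  expect_identical(detect_attractor(J, am[1, ], cfg, horizon = 0)$kind, "none")
  expect_error(detect_attractor(J, am[1, ], dynamics_config(0.5)), "temperature")
})

test_that("retrieval quality does not improve with temperature", {
  pats <- generate_random_patterns(500, 3, seed = 14)
  J <- build_network(pats, nu = 1)
  temps <- c(0, 0.2, 0.5, 2.0)
  m <- vapply(temps, function(T) {
    mean(vapply(1:10, function(s)
      as.numeric(run_am_protocol(J, pats, 0.1, 20, dynamics_config(T, seed = s))),
      numeric(1)))
  }, numeric(1))
  # non-increasing within simulation error
  expect_true(all(diff(m) < 0.05))
  expect_gt(m[1], 0.99)
  expect_lt(m[4], 0.2)
})

test_that("the mixture sweep exposes two-set coexistence and one-set frustration", {
  grid <- c(0, 0.35, 0.5, 0.65, 1)
  two <- sweep_nu("two_set", grid, n_neurons = 1200, p_am = 8, p_spr = 8,
                  in_degree = 300, seed = 21)
  expect_identical(names(two), c("nu", "overlap_am", "overlap_spr", "seed"))
  both_high <- two$overlap_am > 0.9 & two$overlap_spr > 0.9
  expect_true(any(both_high[two$nu > 0 & two$nu < 1]))
  one <- sweep_nu("one_set", grid, n_neurons = 1200, p_am = 8, p_spr = 8,
                  in_degree = 300, seed = 22)
  expect_false(any(one$overlap_am > 0.9 & one$overlap_spr > 0.9))
  # intermediate nu in the one-set model: frustrated superpositions keep a
  # non-negligible but far-from-perfect overlap with the stored patterns
  mid <- one$nu == 0.5
  expect_true(abs(one$overlap_am[mid]) < 0.9)
})
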