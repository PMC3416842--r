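test_that("random pattern generation is reproducible and validated", {
  a <- generate_random_patterns(4, 1, seed = 99)
  b <- generate_random_patterns(4, 1, seed = 99)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(a == 1 | a == -1))
  expect_error(generate_random_patterns(0, 1), "positive")
  expect_error(generate_random_patterns(10, 0), "positive")
  expect_error(pattern_set(matrix(c(1, 0, -1, 1), 2, 2)), "exactly \\+1 or -1")
})

test_that("random patterns are balanced and mutually near-orthogonal", {
  # each pattern's mean and any cross-overlap are O(1/sqrt(N)); 5 sigma bounds
  p1 <- generate_random_patterns(10000, 1, seed = 5)
  expect_lt(abs(mean(p1[1, ])), 5 / sqrt(10000))
  p2 <- generate_random_patterns(1000, 2, seed = 6)
  expect_lt(abs(overlap(p2[1, ], p2[2, ])), 5 / sqrt(1000))
})

test_that("overlap satisfies its identities and bounds", {
  pat <- generate_random_patterns(1000, 1, seed = 3)[1, ]
  expect_identical(overlap(pat, pat), 1)
  expect_identical(overlap(-pat, pat), -1)
  flipped <- pat
  flipped[1:100] <- -flipped[1:100]          # exactly 10% flipped
  expect_equal(overlap(flipped, pat), 0.8)
  # symmetry, boundedness, sign flip, over random cases
  for (seed in 1:5) {
    s <- generate_random_patterns(200, 2, seed = seed)
    m <- overlap(s[1, ], s[2, ])
    expect_identical(m, overlap(s[2, ], s[1, ]))
    expect_identical(overlap(-s[1, ], s[2, ]), -m)
    expect_true(m >= -1 && m <= 1)
    # fraction of matching entries is (1 + m) / 2
    expect_equal(mean(s[1, ] == s[2, ]), (1 + m) / 2)
  }
  expect_error(overlap(c(1, -1), c(1, -1, 1)), "lengths")
})

test_that("corrupt flips an exact count of spins", {
  pat <- generate_random_patterns(1000, 1, seed = 8)[1, ]
  expect_equal(overlap(corrupt(pat, 0, seed = 1), pat), 1)
  expect_equal(overlap(corrupt(pat, 1, seed = 1), pat), -1)
  st <- corrupt(pat, 0.1, seed = 2)
  expect_identical(attr(st, "n_flipped"), 100)
  expect_equal(overlap(st, pat), 0.8)        # deterministic, not approximate
  expect_identical(as.numeric(corrupt(pat, 0.1, seed = 7)),
                   as.numeric(corrupt(pat, 0.1, seed = 7)))
  # rounding is half-up: 0.15 * 10 = 1.5 -> 2 flips
  st2 <- corrupt(pat[1:10], 0.15, seed = 1)
  expect_identical(attr(st2, "n_flipped"), 2)
  expect_error(corrupt(pat, 1.2), "\\[0, 1\\]")
})

test_that("glyph fixture round-trips and yields near-orthogonal patterns", {
  g <- glyph_fixture(20, width = 16, height = 10, bit_depth = 8, seed = 42)
  expect_identical(ncol(g), 16L * 10L * 8L)   # N = width * height * bit_depth
  expect_identical(nrow(g), 20L)
  # decoding the spins reproduces each drawn bitmap exactly
  for (p in c(1L, 7L, 20L)) {
    img <- attr(g, "bitmaps")[[p]]
    expect_identical(decode_intensities(g[p, ], 8L), as.integer(img))
  }
  # pairwise overlaps all well below 1
  ov <- tcrossprod(unclass(g)) / ncol(g)
  expect_lt(max(abs(ov[upper.tri(ov)])), 0.5)
  expect_error(glyph_fixture(2, width = 2, height = 3), "pixels")
  # bit conventions: MSB first, bit 1 -> +1
  expect_identical(encode_intensities(5L, 3L), c(1, -1, 1))
  expect_identical(decode_intensities(c(1, -1, 1), 3L), 5L)
})

test_that("pattern files round-trip bit-exactly", {
  pats <- generate_random_patterns(37, 5, role = "SPR", seed = 13)
  path <- withr::local_tempfile(fileext = ".txt")
  write_patterns(pats, path)
  back <- read_patterns(path)
  expect_identical(unclass(back)[, ], unclass(pats)[, ])
  expect_identical(attr(back, "role"), "SPR")
  expect_identical(readLines(path)[1], "37 5 SPR")
})
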