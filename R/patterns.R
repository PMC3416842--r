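#' Construct a pattern set
#'
#' A pattern set is a `P x N` matrix of binary spins (every entry exactly
#' `+1` or `-1`), tagged with the role it plays in the network: `"AM"` for
#' patterns stored as independent fixed-point attractors through the
#' symmetric part of the synaptic matrix, or `"SPR"` for an ordered sequence
#' stored as a single cyclic attractor through the asymmetric part.
#'
#' @param entries numeric matrix with `P` rows (patterns) and `N` columns
#'   (neurons); all entries must be `+1` or `-1`.
#' @param role `"AM"` or `"SPR"`.
#' @param seed integer seed the set was generated from, or `NA` if not
#'   applicable (kept for reproducibility bookkeeping only).
#' @return An object of class `pattern_set`: the entry matrix with `role`
#'   and `seed` attributes.
#' @seealso [generate_random_patterns()], [glyph_fixture()], [overlap()]
#' @export
pattern_set <- function(entries, role = c("AM", "SPR"), seed = NA_integer_) {
  role <- match.arg(role)
  entries <- as.matrix(entries)
  if (nrow(entries) < 1L || ncol(entries) < 1L)
    stop("a pattern set needs at least one pattern and one neuron")
  if (!all(entries == 1 | entries == -1))
    stop("pattern entries must be exactly +1 or -1")
  storage.mode(entries) <- "double"
  structure(entries, role = role, seed = seed, class = c("pattern_set", "matrix"))
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d patterns x %d neurons, role = %s, seed = %s\n",
              nrow(x), ncol(x), attr(x, "role"),
              format(attr(x, "seed"))))
  invisible(x)
}

#' Number of patterns / neurons in a pattern set
#'
#' @param pats a [pattern_set()].
#' @return Integer count.
#' @export
n_patterns <- function(pats) nrow(pats)

#' @rdname n_patterns
#' @export
n_neurons <- function(pats) ncol(pats)

#' Generate equiprobable random binary patterns
#'
#' Each entry is drawn independently and uniformly from \{-1, +1\}.  Random
#' patterns of this kind are asymptotically orthogonal: the overlap between
#' two of them, and the mean of a single one, are O(1/sqrt(N)).
#'
#' @param n_neurons number of neurons `N` (>= 1).
#' @param n_patterns number of patterns `P` (>= 1).
#' @param role `"AM"` or `"SPR"` (see [pattern_set()]).
#' @param seed integer seed; the same seed always yields the same set.
#' @return A [pattern_set()].
#' @export
generate_random_patterns <- function(n_neurons, n_patterns,
                                     role = c("AM", "SPR"), seed = 1L) {
  if (n_neurons < 1 || n_patterns < 1)
    stop("n_neurons and n_patterns must be positive")
  role <- match.arg(role)
  entries <- with_seed(seed, {
    matrix(sample(c(-1, 1), n_neurons * n_patterns, replace = TRUE),
           nrow = n_patterns, ncol = n_neurons)
  })
  pattern_set(entries, role = role, seed = as.integer(seed))
}

#' Overlap between a network state and a stored pattern
#'
#' The overlap `m = (1/N) sum_i state_i * pattern_i` measures retrieval
#' quality: `m = 1` means perfect recall, `m = -1` the specular copy
#' (anti-pattern), and `m = O(1/sqrt(N))` an uncorrelated state.  A state
#' with overlap `m` has a fraction `(1 + m)/2` of its neurons equal to the
#' pattern.
#'
#' @param state length-`N` spin vector.
#' @param pattern length-`N` spin vector (usually one row of a
#'   [pattern_set()]).
#' @return The overlap, a number in `[-1, 1]`.
#' @export
overlap <- function(state, pattern) {
  state <- as.numeric(state)
  pattern <- as.numeric(pattern)
  if (length(state) != length(pattern))
    stop("state and pattern have different lengths (",
         length(state), " vs ", length(pattern), ")")
  sum(state * pattern) / length(state)
}

#' Corrupt a pattern by flipping an exact number of spins
#'
#' Flips exactly `round(flip_fraction * N)` spins (round half up) at
#' uniformly chosen distinct positions, so the overlap between the corrupted
#' state and the original pattern is deterministic:
#' `1 - 2 * n_flipped / N`.
#'
#' @param pattern length-`N` spin vector.
#' @param flip_fraction fraction of spins to flip, in `[0, 1]`.
#' @param seed integer seed selecting the flipped positions.
#' @return A length-`N` spin vector with attributes `n_flipped` (the exact
#'   flip count) and `time_index = 0`.
#' @export
corrupt <- function(pattern, flip_fraction, seed = 1L) {
  if (flip_fraction < 0 || flip_fraction > 1)
    stop("flip_fraction must lie in [0, 1]")
  pattern <- as.numeric(pattern)
  n <- length(pattern)
  n_flip <- floor(flip_fraction * n + 0.5)  # round half up
  idx <- with_seed(seed, sample.int(n, n_flip))
  state <- pattern
  state[idx] <- -state[idx]
  structure(state, n_flipped = n_flip, time_index = 0L)
}

# ---------------------------------------------------------------------------
# Glyph fixture: procedurally drawn grayscale bitmaps encoded as spins.
# ---------------------------------------------------------------------------

# Seven-segment layout used to rasterize a digit onto a w x h pixel grid.
# Segments: 1 top, 2 upper-right, 3 lower-right, 4 bottom, 5 lower-left,
# 6 upper-left, 7 middle.
.seg_map <- list(
  `0` = c(1, 2, 3, 4, 5, 6),
  `1` = c(2, 3),
  `2` = c(1, 2, 7, 5, 4),
  `3` = c(1, 2, 7, 3, 4),
  `4` = c(6, 7, 2, 3),
  `5` = c(1, 6, 7, 3, 4),
  `6` = c(1, 6, 5, 4, 3, 7),
  `7` = c(1, 2, 3),
  `8` = 1:7,
  `9` = c(1, 2, 3, 4, 6, 7)
)

# Rasterize digit d (0-9) as a logical w x h mask (TRUE = glyph stroke).
.draw_digit <- function(d, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  top <- 1L; mid <- as.integer(ceiling(height / 2)); bot <- height
  left <- 1L; right <- width
  segs <- .seg_map[[as.character(d)]]
  for (s in segs) {
    switch(s,
      `1` = { mask[top, left:right] <- TRUE },
      `2` = { mask[top:mid, right] <- TRUE },
      `3` = { mask[mid:bot, right] <- TRUE },
      `4` = { mask[bot, left:right] <- TRUE },
      `5` = { mask[mid:bot, left] <- TRUE },
      `6` = { mask[top:mid, left] <- TRUE },
      `7` = { mask[mid, left:right] <- TRUE })
  }
  mask
}

#' Encode pixel intensities as spins
#'
#' Each intensity (an integer in `[0, 2^bit_depth - 1]`) is written as
#' `bit_depth` spins, most-significant bit first; bit value 1 maps to `+1`
#' and bit value 0 to `-1`.
#'
#' @param intensities integer vector of pixel intensities.
#' @param bit_depth bits per pixel (>= 1).
#' @return Spin vector of length `length(intensities) * bit_depth`.
#' @seealso [decode_intensities()] for the exact inverse.
#' @export
encode_intensities <- function(intensities, bit_depth = 8L) {
  if (bit_depth < 1) stop("bit_depth must be >= 1")
  intensities <- as.integer(intensities)
  if (any(intensities < 0 | intensities >= 2^bit_depth))
    stop("intensities out of range for the given bit depth")
  bits <- vapply(seq.int(bit_depth - 1L, 0L), # MSB first
                 function(b) bitwAnd(intensities %/% 2L^b, 1L),
                 integer(length(intensities)))
  as.numeric(t(bits)) * 2 - 1
}

#' Decode spins back to pixel intensities
#'
#' Exact inverse of [encode_intensities()].
#'
#' @param spins spin vector whose length is a multiple of `bit_depth`.
#' @param bit_depth bits per pixel.
#' @return Integer vector of intensities.
#' @export
decode_intensities <- function(spins, bit_depth = 8L) {
  if (length(spins) %% bit_depth != 0)
    stop("spin vector length is not a multiple of bit_depth")
  bits <- matrix((as.numeric(spins) + 1) / 2, nrow = bit_depth)
  as.integer(colSums(bits * 2^seq.int(bit_depth - 1L, 0L)))
}

#' Procedural grayscale glyph patterns
#'
#' Builds a pattern set that emulates storing digitized grayscale glyph
#' images: each pattern is a `width x height` bitmap of a seven-segment
#' digit drawn over a noisy gray background, and every pixel's intensity is
#' encoded as `bit_depth` spins (see [encode_intensities()]), giving
#' `N = width * height * bit_depth` spins per pattern.  Background pixels
#' take random dark intensities and stroke pixels random bright ones, so
#' distinct glyphs are close to orthogonal (all pairwise overlaps well below
#' 0.5) while each decoded bitmap still shows its glyph.
#'
#' @param n_patterns number of glyph patterns.
#' @param width,height bitmap size in pixels (at least 3 x 5 to fit a
#'   glyph).
#' @param bit_depth bits of gray depth per pixel.
#' @param role pattern role, as in [pattern_set()].
#' @param seed integer seed; drives both which intensities are drawn and the
#'   background texture.
#' @return A [pattern_set()] with `P = n_patterns` and
#'   `N = width * height * bit_depth`, carrying the drawn bitmaps in the
#'   `bitmaps` attribute (a list of `height x width` integer matrices).
#' @export
glyph_fixture <- function(n_patterns, width, height, bit_depth = 8L,
                          role = c("AM", "SPR"), seed = 1L) {
  role <- match.arg(role)
  if (width < 3 || height < 5)
    stop("glyph bitmaps need at least 3 x 5 pixels")
  if (bit_depth < 1) stop("bit_depth must be >= 1")
  hi <- 2L^bit_depth - 1L
  lo_top <- max(0L, hi %/% 2L - 1L)      # background band: [0, lo_top]
  fg_lo  <- min(hi, hi %/% 2L + 1L)      # stroke band: [fg_lo, hi]
  out <- with_seed(seed, {
    bitmaps <- vector("list", n_patterns)
    rows <- matrix(0, nrow = n_patterns, ncol = width * height * bit_depth)
    for (p in seq_len(n_patterns)) {
      mask <- .draw_digit((p - 1) %% 10L, width, height)
      img <- matrix(sample.int(lo_top + 1L, height * width, replace = TRUE) - 1L,
                    nrow = height, ncol = width)
      img[mask] <- fg_lo + sample.int(hi - fg_lo + 1L, sum(mask),
                                      replace = TRUE) - 1L
      bitmaps[[p]] <- img
      rows[p, ] <- encode_intensities(as.integer(img), bit_depth)
    }
    list(rows = rows, bitmaps = bitmaps)
  })
  pats <- pattern_set(out$rows, role = role, seed = as.integer(seed))
  attr(pats, "bitmaps") <- out$bitmaps
  attr(pats, "bit_depth") <- as.integer(bit_depth)
  attr(pats, "width") <- as.integer(width)
  attr(pats, "height") <- as.integer(height)
  pats
}

# ---------------------------------------------------------------------------
# Plain-text pattern file format: header "N P role", then P lines of N
# space-separated +1/-1 tokens.
# ---------------------------------------------------------------------------

#' Write a pattern set to a plain-text file
#'
#' Format: a header line `"N P role"`, then `P` lines of `N` space-separated
#' `+1`/`-1` tokens.  [read_patterns()] round-trips the file bit-exactly.
#'
#' @param pats a [pattern_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(pats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %s", ncol(pats), nrow(pats), attr(pats, "role")), con)
  apply(pats, 1L, function(row)
    writeLines(paste(ifelse(row > 0, "+1", "-1"), collapse = " "), con))
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(hdr[1]); p <- as.integer(hdr[2]); role <- hdr[3]
  entries <- t(vapply(lines[1 + seq_len(p)],
                      function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                      numeric(n)))
  dimnames(entries) <- NULL
  pattern_set(entries, role = role)
}
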