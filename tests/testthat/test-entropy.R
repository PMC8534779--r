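# Entropy primitives: closed forms, the local transform, and its invariants.

test_that("tsallis_entropy matches closed forms and rejects bad input", {
  # degenerate distribution has zero entropy for any q
  for (q in c(0.3, 0.5, 2, 3.7))
    expect_equal(tsallis_entropy(c(1, 0, 0), q), 0)
  # uniform over B bins: k * (1 - B^(1-q)) / (q - 1)
  for (B in c(2, 4, 8)) for (q in c(0.5, 1.5, 2)) {
    expect_equal(tsallis_entropy(rep(1 / B, B), q),
                 (1 - B^(1 - q)) / (q - 1), tolerance = 1e-12)
  }
  expect_equal(tsallis_entropy(c(0.5, 0.5), q = 2), 0.5)
  expect_equal(tsallis_entropy(rep(0.5, 2), q = 2, k = 3), 1.5)
  expect_error(tsallis_entropy(c(0.5, 0.5), q = 1), "q = 1|indeterminate")
  expect_error(tsallis_entropy(c(0.7, -0.2, 0.5), q = 2), "non-negative")
  expect_error(tsallis_entropy(c(0.4, 0.4), q = 2), "sum to 1")
})

test_that("bgs_entropy matches closed forms with 0 log 0 = 0", {
  expect_equal(bgs_entropy(c(1, 0)), 0)
  expect_equal(bgs_entropy(c(0.5, 0.5)), log(2))
  expect_equal(bgs_entropy(rep(1 / 8, 8)), log(8))
  expect_equal(bgs_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_equal(bgs_entropy(c(0.5, 0.5), k = 2), 2 * log(2))
  expect_error(bgs_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("tsallis entropy converges to the BGS entropy as q -> 1", {
  for (i in 1:100) {
    p <- random_probs(sample(2:12, 1), seed = i)
    s_bgs <- bgs_entropy(p)
    for (q in c(1 - 1e-6, 1 + 1e-6)) {
      expect_lt(abs(tsallis_entropy(p, q) - s_bgs), 1e-5 * abs(s_bgs))
    }
  }
})

test_that("reduced_entropy evaluates sum of powered masses with q = 1 handling", {
  one_bin <- c(1, 0, 0, 0)
  expect_equal(reduced_entropy(one_bin, entropy_spec(q = 2)), 1)
  expect_equal(reduced_entropy(rep(0.25, 4), entropy_spec(q = 2)), 0.25)
  for (B in c(2, 4, 8)) for (q in c(0.25, 0.5, 1.5, 2))
    expect_equal(reduced_entropy(rep(1 / B, B), entropy_spec(q = q)),
                 B^(1 - q), tolerance = 1e-12)
  expect_equal(reduced_entropy(c(0.5, 0.5), entropy_spec(q = 0.5)), sqrt(2))
  # q = 1: BGS limit by default, literal constant sum in raw mode
  expect_equal(reduced_entropy(c(0.5, 0.25, 0.25), entropy_spec(q = 1)),
               1.5 * log(2))
  expect_equal(reduced_entropy(one_bin, entropy_spec(q = 1)), 0)
  expect_equal(reduced_entropy(c(0.5, 0.25, 0.25),
                               entropy_spec(q = 1, q1 = "raw")), 1)
})

test_that("reduced_entropy is permutation invariant and extremal at uniform", {
  set.seed(7)
  for (i in 1:20) {
    mass <- random_probs(6)
    for (q in c(0.5, 1, 1.5, 2)) {
      spec <- entropy_spec(q = q)
      expect_equal(reduced_entropy(sample(mass), spec),
                   reduced_entropy(mass, spec))
    }
  }
  # among histograms on B occupied bins the uniform one maximizes S'q for
  # q < 1 and minimizes it for q > 1
  B <- 5
  uniform_low <- B^(1 - 0.5)
  uniform_high <- B^(1 - 2)
  for (i in 1:50) {
    mass <- random_probs(B)
    expect_lte(reduced_entropy(mass, entropy_spec(0.5)), uniform_low + 1e-12)
    expect_gte(reduced_entropy(mass, entropy_spec(2)), uniform_high - 1e-12)
  }
})

test_that("reduced_entropy is non-increasing in q for a fixed distribution", {
  qs <- c(0.25, 0.5, 0.75, 1.2, 1.5, 2, 3)
  set.seed(11)
  for (i in 1:20) {
    mass <- random_probs(8)
    vals <- vapply(qs, function(q) reduced_entropy(mass, entropy_spec(q)), 0)
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("histogram_spec enforces the bin partition contract", {
  h <- histogram_spec(bin_width = 32)
  expect_equal(h$n_bins, 8)
  expect_error(histogram_spec(bin_width = 48), "divide")
  expect_error(window_spec(0), "positive")
})

test_that("local histograms bin with half-open edges and normalize to 1", {
  # all nine pixels equal: mass concentrated in a single bin
  img <- matrix(10L, 3, 3)
  h <- local_histogram(img, 2, 2, window_spec(1), histogram_spec(64))
  expect_equal(h$mass, c(1, 0, 0, 0))
  expect_equal(h$count_total, 9)
  # half-open edges: 0 and 63 share bin 1, 64 opens bin 2, 255 ends bin 4
  counts <- entropytex:::bin_counts(c(0, 63, 64, 255), histogram_spec(64))
  expect_equal(counts, c(2L, 1L, 0L, 1L))
  # unnormalized masses sum to the window pixel count
  hr <- local_histogram(random_gray(9, seed = 3), 5, 5, window_spec(2),
                        histogram_spec(32, normalize = FALSE))
  expect_equal(sum(hr$mass), 25)
  # normalized masses sum to 1 for any window
  hn <- local_histogram(random_gray(9, seed = 4), 1, 9, window_spec(2),
                        histogram_spec(16))
  expect_equal(sum(hn$mass), 1, tolerance = 1e-12)
  expect_error(local_histogram(img, 5, 1, window_spec(1), histogram_spec(64)),
               "outside")
})

test_that("entropy transform equals the per-pixel oracle engine everywhere", {
  img <- random_gray(24, seed = 42)
  for (q in c(0.5, 1, 2)) for (r in c(1, 3)) for (hb in c(16, 64)) {
    fast <- entropy_transform(img, window_spec(r), histogram_spec(hb),
                              entropy_spec(q))
    naive <- entropy_transform(img, window_spec(r), histogram_spec(hb),
                               entropy_spec(q), engine = "naive")
    expect_lt(max(abs(fast - naive)), 1e-12)
  }
  # clamp border agrees too
  fast <- entropy_transform(img, window_spec(2, "clamp"), histogram_spec(32),
                            entropy_spec(1.5))
  naive <- entropy_transform(img, window_spec(2, "clamp"), histogram_spec(32),
                             entropy_spec(1.5), engine = "naive")
  expect_lt(max(abs(fast - naive)), 1e-12)
})

test_that("entropy transform handles known images and range invariants", {
  # constant image: single-bin windows everywhere, S'q = 1 for q != 1
  cmap <- entropy_transform(matrix(7L, 10, 12), spec = entropy_spec(1.5))
  expect_true(all(cmap == 1))
  expect_equal(dim(cmap), c(10L, 12L))
  # checkerboard interior: 3x3 windows hold masses (5/9, 4/9); q = 2
  emap <- entropy_transform(checkerboard(8), window_spec(1),
                            histogram_spec(64), entropy_spec(2))
  expect_equal(emap[4, 4], 41 / 81, tolerance = 1e-12)
  expect_equal(emap[5, 5], 41 / 81, tolerance = 1e-12)
  # normalized-histogram bounds: (0, 1] for q > 1, [1, B^(1-q)] for q < 1
  img <- random_gray(20, seed = 9)
  hi <- entropy_transform(img, window_spec(2), histogram_spec(32),
                          entropy_spec(2))
  expect_true(all(hi > 0 & hi <= 1))
  lo <- entropy_transform(img, window_spec(2), histogram_spec(32),
                          entropy_spec(0.5))
  expect_true(all(lo >= 1 & lo <= 8^0.5 + 1e-12))
  expect_true(all(is.finite(hi)) && all(is.finite(lo)))
})

test_that("entropy maps round-trip through delimited text losslessly", {
  map <- entropy_transform(random_gray(12, seed = 5), spec = entropy_spec(0.75))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_entropy_map(map, path)
  back <- read_entropy_map(path)
  expect_equal(matrix(as.numeric(map), nrow(map)),
               matrix(as.numeric(back), nrow(back)), tolerance = 0)
})
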