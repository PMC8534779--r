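# Backbone feature extraction, stream plumbing and fusion.

test_that("grayscale conversion uses BT.601 luma weights", {
  expect_equal(to_grayscale(array(255L, c(2, 2, 3))), matrix(255L, 2, 2))
  expect_equal(to_grayscale(array(0L, c(2, 2, 3))), matrix(0L, 2, 2))
  red <- array(rep(c(255L, 0L, 0L), each = 4), c(2, 2, 3))
  expect_equal(to_grayscale(red), matrix(76L, 2, 2))
  gray <- matrix(5L, 3, 3)
  expect_identical(to_grayscale(gray), gray)
})

test_that("entropy maps are adapted to backbone input deterministically", {
  spec <- backbone_spec("pooled-stats")
  # constant map maps to mid-gray 128 in all three channels
  const <- entropy_to_input(matrix(0.37, 8, 8), spec)
  expect_equal(dim(const), c(spec$input_side, spec$input_side, 3L))
  expect_true(all(const == 128L))
  # min-max midpoint uses round-half-even (map already at native size, so
  # no interpolation intervenes)
  m <- matrix(0.45, 32, 32)
  m[1, 1] <- 0.2
  m[32, 32] <- 0.7
  out <- entropy_to_input(m, spec)
  expect_equal(out[1, 1, 1], 0L)
  expect_equal(out[32, 32, 3], 255L)
  expect_equal(out[16, 16, 2], 128L)  # (0.45-0.2)/0.5*255 = 127.5 -> even
  # any map yields the contracted shape and integer range
  m2 <- matrix(runif(100), 10, 10)
  out2 <- entropy_to_input(m2, spec)
  expect_equal(dim(out2), c(32L, 32L, 3L))
  expect_true(all(out2 >= 0 & out2 <= 255))
})

test_that("the stand-in extractor is deterministic with analytic constant-image stats", {
  spec <- backbone_spec("pooled-stats")
  img <- random_color(16, seed = 2)
  f1 <- extract_features(img, spec)
  f2 <- extract_features(img, spec)
  expect_identical(unclass(f1), unclass(f2))
  expect_length(f1, spec$output_dim)
  # constant image: channel means are the constant, variances exactly 0
  const <- array(200L, c(8, 8, 3))
  fc <- extract_features(const, spec)
  expect_equal(fc[1:3], rep(200 / 255, 3), tolerance = 1e-12)
  expect_equal(fc[4:6], rep(0, 3))
})

test_that("the backbone registry exposes the VGG19 contract without weights", {
  expect_true(all(c("pooled-stats", "vgg19-penultimate") %in% list_backbones()))
  vgg <- backbone_spec("vgg19-penultimate")
  expect_equal(vgg$output_dim, 4096L)
  expect_equal(vgg$input_side, 224L)
  expect_error(extract_features(random_color(8), vgg),
               "pretrained weights.*pooled-stats")
  expect_error(backbone_spec("resnet-999"), "unknown backbone")
})

test_that("fusion concatenates original-first and enforces provenance", {
  spec <- backbone_spec("pooled-stats")
  img <- random_color(16, seed = 3)
  fo <- extract_features(img, spec, stream = "original")
  fe <- extract_features(entropy_to_input(
    entropy_transform(to_grayscale(img)), spec), spec,
    stream = "entropy", q = 1.5)
  fv <- fuse(fo, fe)
  expect_length(fv, 32)
  expect_equal(as.numeric(fv)[1:16], as.numeric(fo))
  expect_equal(as.numeric(fv)[17:32], as.numeric(fe))
  expect_equal(attr(fv, "stream"), "fused")
  expect_error(fuse(fe, fo), "original-stream")
  expect_error(fuse(fo, fo), "original-stream|entropy-stream")
  empty <- structure(numeric(0), class = "feature_vector",
                     stream = "entropy", backbone = "pooled-stats")
  expect_error(fuse(fo, empty), "empty")
})

test_that("the entropy stream reacts to disorder but not to bin-preserving shifts", {
  set.seed(21)
  base <- matrix(64L + sample(0:20, 900, TRUE), 30, 30)
  win <- window_spec(2); hs <- histogram_spec(32); es <- entropy_spec(1.5)
  e_base <- entropy_transform(base, win, hs, es)
  # high-frequency noise measurably changes the entropy map
  noisy <- base
  idx <- sample(length(noisy), 200)
  noisy[idx] <- sample(0:255, 200, TRUE)
  expect_gt(mean(abs(entropy_transform(noisy, win, hs, es) - e_base)), 0)
  # a global shift by a whole bin width crosses no bin boundary: the
  # normalized-histogram entropy map is unchanged
  shifted <- base + 32L
  expect_equal(unclass(entropy_transform(shifted, win, hs, es)),
               unclass(e_base))
})

test_that("image descriptors are a pure function of image and config", {
  cfg <- pipeline_config(q = 0.75, stream = "fused")
  img <- random_color(20, seed = 5)
  v1 <- entropytex:::sample_features(img, cfg)
  v2 <- entropytex:::sample_features(img, cfg)
  expect_identical(unclass(v1), unclass(v2))
})
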