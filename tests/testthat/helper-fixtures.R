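# Shared helpers: all fixtures are generated in code at test time.

random_gray <- function(side = 32, seed = 1, levels = 256) {
  set.seed(seed)
  matrix(sample(0:(levels - 1), side * side, replace = TRUE), side, side)
}

random_color <- function(side = 16, seed = 1) {
  set.seed(seed)
  array(sample(0:255, side * side * 3, replace = TRUE), c(side, side, 3))
}

# 0/255 checkerboard whose interior 3x3 windows hold 5 pixels of one value
# and 4 of the other.
checkerboard <- function(side = 8) {
  m <- matrix(0L, side, side)
  m[(row(m) + col(m)) %% 2 == 0] <- 255L
  m
}

random_probs <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(n)
  p / sum(p)
}

# Small on-disk dataset in the class-per-directory layout; returns its root.
write_tiny_dataset <- function(classes = c("bark", "leaf"), n = 3, side = 12,
                               seed = 1, tag_letters = NULL) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  set.seed(seed)
  for (cl in classes) {
    dir.create(file.path(root, cl))
    for (i in seq_len(n)) {
      img <- matrix(runif(side * side), side, side)
      tag <- if (is.null(tag_letters)) "" else
        paste0("_sample_", tag_letters[(i - 1) %% length(tag_letters) + 1])
      png::writePNG(img, file.path(root, cl, sprintf("%s_%02d%s.png", cl, i, tag)))
    }
  }
  root
}
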