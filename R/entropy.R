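#' Window, histogram and entropy specifications
#'
#' Small spec objects parameterising the local entropy transform. The window
#' is the square neighbourhood of radius `r` (side `2r + 1`) centred on each
#' pixel; the histogram partitions the `levels` gray levels into bins of width
#' `bin_width`; the entropy spec carries the entropic index `q`.
#'
#' Bins are half-open: bin `k` collects intensities `j` with
#' `(k - 1) * bin_width <= j < k * bin_width`, so the bins partition
#' `[0, levels - 1]` with no double counting and the top intensity falls in
#' the last bin. `bin_width` must divide `levels` exactly.
#'
#' At `q = 1` the reduced entropy `sum(p^q)` is identically 1 for any
#' probability histogram, which carries no information. The default
#' `q1 = "bgs"` therefore substitutes the Boltzmann–Gibbs–Shannon limit
#' (Shannon entropy) at `q = 1`; `q1 = "raw"` keeps the literal constant sum
#' for strict-letter comparison.
#'
#' @param r window radius in pixels (positive integer). Default 2 (5x5
#'   window), the smallest window giving at least 25 samples per histogram.
#' @param border how windows overhanging the image edge are filled:
#'   `"reflect"` mirrors the image about its edge (edge pixel repeated),
#'   `"clamp"` repeats the edge pixel.
#' @param bin_width intensity span of one histogram bin (positive integer
#'   dividing `levels`). Default 32, i.e. 8 bins for 256 gray levels, so a
#'   5x5 window does not yield trivially sparse histograms.
#' @param levels number of gray levels (default 256 for 8-bit images).
#' @param normalize if `TRUE` (default) window histograms are normalised to
#'   probabilities before the entropy is computed; if `FALSE` raw counts are
#'   used.
#' @param q entropic index, a positive real. `q < 1` amplifies rare bins,
#'   `q > 1` emphasises dominant bins.
#' @param k entropy prefactor (default 1; a global constant adds no
#'   discriminative information to the transform).
#' @param q1 behaviour at exactly `q = 1`: `"bgs"` (Shannon limit, default)
#'   or `"raw"` (literal constant sum).
#' @return an object of class `"window_spec"`, `"histogram_spec"` or
#'   `"entropy_spec"` respectively.
#' @seealso [entropy_transform()]
#' @export
window_spec <- function(r = 2L, border = c("reflect", "clamp")) {
  border <- match.arg(border)
  if (length(r) != 1L || is.na(r) || r < 1 || r != as.integer(r))
    stop("`r` must be a single positive integer window radius")
  r <- as.integer(r)
  structure(list(r = r, border = border, side = 2L * r + 1L),
            class = "window_spec")
}

#' @rdname window_spec
#' @export
histogram_spec <- function(bin_width = 32L, levels = 256L, normalize = TRUE) {
  bin_width <- as.integer(bin_width)
  levels <- as.integer(levels)
  if (is.na(bin_width) || bin_width < 1L) stop("`bin_width` must be a positive integer")
  if (is.na(levels) || levels < 2L) stop("`levels` must be an integer >= 2")
  if (levels %% bin_width != 0L)
    stop("`bin_width` (", bin_width, ") must divide the number of gray levels (",
         levels, ")")
  structure(list(bin_width = bin_width, levels = levels,
                 n_bins = levels %/% bin_width, normalize = isTRUE(normalize)),
            class = "histogram_spec")
}

#' @rdname window_spec
#' @export
entropy_spec <- function(q = 1.5, k = 1, q1 = c("bgs", "raw")) {
  q1 <- match.arg(q1)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0)
    stop("`q` must be a single positive finite real")
  structure(list(q = as.numeric(q), k = as.numeric(k), q1 = q1),
            class = "entropy_spec")
}

check_gray <- function(image, levels = 256L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix of integer intensities")
  if (anyNA(image)) stop("`image` contains missing values")
  if (any(image != floor(image)))
    stop("`image` intensities must be integers")
  if (min(image) < 0 || max(image) > levels - 1L)
    stop("`image` intensities must lie in [0, ", levels - 1L, "]")
  invisible(image)
}

check_prob <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) == 0L) stop("`p` must be a numeric vector")
  if (anyNA(p)) stop("`p` contains missing values")
  if (any(p < 0)) stop("`p` must be non-negative")
  if (abs(sum(p) - 1) > tol) stop("`p` must sum to 1 (tolerance 1e-9)")
  invisible(p)
}

#' Tsallis and Boltzmann-Gibbs-Shannon entropies
#'
#' `tsallis_entropy()` computes the non-additive entropy
#' `S_q(p) = k / (q - 1) * (1 - sum(p_i^q))` of a probability distribution.
#' `bgs_entropy()` computes its `q -> 1` limit, the classical
#' Boltzmann–Gibbs–Shannon entropy `-k * sum(p_i * log(p_i))` (natural
#' logarithm, with `0 * log 0 = 0`). These are the reference forms the local
#' transform is validated against.
#'
#' @param p numeric vector of probabilities (non-negative, summing to 1
#'   within 1e-9).
#' @param q entropic index, positive and different from 1 (at `q = 1` the
#'   Tsallis form is an indeterminate 0/0; call `bgs_entropy()` instead).
#' @param k entropy prefactor (default 1).
#' @return a single numeric entropy value.
#' @examples
#' tsallis_entropy(c(0.5, 0.5), q = 2)   # 0.5
#' bgs_entropy(c(0.5, 0.5))              # log(2)
#' @export
tsallis_entropy <- function(p, q, k = 1) {
  check_prob(p)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0)
    stop("`q` must be a single positive real")
  if (q == 1)
    stop("Tsallis entropy is indeterminate at q = 1; use bgs_entropy() for the limit")
  k / (q - 1) * (1 - sum(p^q))
}

#' @rdname tsallis_entropy
#' @export
bgs_entropy <- function(p, k = 1) {
  check_prob(p)
  pp <- p[p > 0]
  -k * sum(pp * log(pp))
}

#' Local window histogram
#'
#' Histogram of the intensities inside the square window of radius `win$r`
#' centred on pixel `(row, col)`, with the image extended past its borders
#' according to `win$border`. Bin `k` covers intensities
#' `[(k - 1) * bin_width, k * bin_width)`.
#'
#' @param image integer intensity matrix (values in `[0, levels - 1]`).
#' @param row,col centre pixel coordinates (1-based).
#' @param win a [window_spec()].
#' @param hist a [histogram_spec()].
#' @return an object of class `"local_histogram"`: a list with `mass`
#'   (normalised or raw bin masses, length `hist$n_bins`), `counts` (integer
#'   bin counts) and `count_total` (window pixel count, `(2r + 1)^2`).
#' @export
local_histogram <- function(image, row, col, win = window_spec(),
                            hist = histogram_spec()) {
  check_gray(image, hist$levels)
  if (row < 1 || row > nrow(image) || col < 1 || col > ncol(image))
    stop("window centre (", row, ", ", col, ") is outside the image bounds")
  r <- win$r
  pad <- pad_image(image, r, win$border)
  w <- pad[row:(row + 2L * r), col:(col + 2L * r)]
  counts <- bin_counts(w, hist)
  mass <- if (hist$normalize) counts / win$side^2 else as.numeric(counts)
  structure(list(mass = mass, counts = counts, count_total = win$side^2),
            class = "local_histogram")
}

# Half-open binning of intensities into hist$n_bins bins of width
# hist$bin_width; returns integer counts.
bin_counts <- function(values, hist) {
  tabulate(as.integer(values) %/% hist$bin_width + 1L, nbins = hist$n_bins)
}

#' Reduced local entropy of a histogram
#'
#' The per-pixel statistic of the entropy transform: for `q != 1`,
#' `S'_q = sum_k mass(k)^q` over all bins (with `0^q = 0`), i.e. the Tsallis
#' entropy stripped of the constant offset and prefactor, which are global
#' constants that add nothing to an image representation. For `q > 1` on a
#' probability histogram this lies in `(0, 1]` and is minimised by the
#' uniform histogram; for `0 < q < 1` it lies in `[1, n_bins^(1 - q)]` and is
#' maximised by the uniform histogram. At `q = 1` the sum is identically 1,
#' so the default `q1 = "bgs"` substitutes the Shannon entropy
#' `-sum(mass * log(mass))`; `q1 = "raw"` returns the literal constant sum.
#'
#' @param h a [local_histogram()] or a numeric vector of bin masses.
#' @param spec an [entropy_spec()].
#' @return a single numeric value.
#' @examples
#' reduced_entropy(rep(1 / 4, 4), entropy_spec(q = 2))   # 4^(1 - 2) = 0.25
#' @export
reduced_entropy <- function(h, spec = entropy_spec()) {
  mass <- if (inherits(h, "local_histogram")) h$mass else h
  if (!is.numeric(mass) || anyNA(mass) || any(mass < 0))
    stop("histogram masses must be non-negative numbers")
  reduced_entropy_mass(mass, spec$q, spec$q1)
}

# Internal fast path: no validation, `mass` a plain numeric vector.
reduced_entropy_mass <- function(mass, q, q1) {
  if (q != 1) return(sum(mass^q))
  if (q1 == "raw") return(sum(mass))
  m <- mass[mass > 0]
  -sum(m * log(m))
}

# Extend `image` by `r` pixels on each side. "reflect" mirrors about the
# image edge with the edge pixel repeated; "clamp" replicates the edge pixel.
# Both are well defined for any r (indices fold repeatedly on tiny images).
pad_image <- function(image, r, border) {
  nH <- nrow(image)
  nW <- ncol(image)
  rows <- border_index((1L - r):(nH + r), nH, border)
  cols <- border_index((1L - r):(nW + r), nW, border)
  image[rows, cols, drop = FALSE]
}

border_index <- function(t, n, border) {
  if (border == "clamp") return(pmin(pmax(t, 1L), n))
  if (n == 1L) return(rep(1L, length(t)))
  m <- (t - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

#' Local entropy transform of a grayscale image
#'
#' Produces the alternative representation `Iq`: every pixel of `image` is
#' replaced by the reduced entropy ([reduced_entropy()]) of the local window
#' histogram ([local_histogram()]) centred on it. Border pixels use windows
#' filled according to `win$border`.
#'
#' The `"fast"` engine computes, for each histogram bin, the window counts of
#' the whole image at once via two-dimensional cumulative sums of bin
#' indicators (an integral-image box filter), and accumulates the entropy
#' bin by bin in the same order as the `"naive"` reference engine, which
#' loops over pixels building each window histogram explicitly. The two
#' engines agree to floating-point accumulation error (< 1e-12).
#'
#' @inheritParams local_histogram
#' @param spec an [entropy_spec()].
#' @param engine `"fast"` (default, integral-image) or `"naive"`
#'   (per-pixel reference implementation).
#' @return a numeric matrix of class `"entropy_map"` with the same shape as
#'   `image`; the parameters `q`, `r`, `bin_width`, `normalize`, `border` and
#'   `q1` are recorded as attributes.
#' @examples
#' img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
#' emap <- entropy_transform(img, window_spec(2), histogram_spec(32),
#'                           entropy_spec(q = 1.5))
#' range(emap)
#' @export
entropy_transform <- function(image, win = window_spec(),
                              hist = histogram_spec(),
                              spec = entropy_spec(),
                              engine = c("fast", "naive")) {
  engine <- match.arg(engine)
  check_gray(image, hist$levels)
  map <- if (engine == "fast") {
    transform_fast(image, win, hist, spec)
  } else {
    transform_naive(image, win, hist, spec)
  }
  structure(map, class = c("entropy_map", class(map)),
            q = spec$q, r = win$r, bin_width = hist$bin_width,
            normalize = hist$normalize, border = win$border, q1 = spec$q1)
}

transform_fast <- function(image, win, hist, spec) {
  r <- win$r
  side <- win$side
  npix <- side^2
  pad <- pad_image(image, r, win$border)
  bins <- as.integer(pad) %/% hist$bin_width + 1L
  dim(bins) <- dim(pad)
  q <- spec$q
  acc <- matrix(0, nrow(image), ncol(image))
  for (k in seq_len(hist$n_bins)) {
    cnt <- box_sum(bins == k, side)
    p <- if (hist$normalize) cnt / npix else cnt
    acc <- acc + if (q != 1) {
      p^q
    } else if (spec$q1 == "raw") {
      p
    } else {
      out <- -p * log(p)
      out[p == 0] <- 0
      out
    }
  }
  acc
}

# Window sums of M (numeric/logical matrix) over all side x side windows,
# via padded 2-D cumulative sums; counts are exact (integers < 2^53).
box_sum <- function(M, side) {
  nr <- nrow(M)
  nc <- ncol(M)
  Z <- matrix(0, nr + 1L, nc + 1L)
  Z[-1L, -1L] <- apply(apply(M, 2L, cumsum), 1L, cumsum) |> t()
  lo_r <- 1L:(nr - side + 1L)
  lo_c <- 1L:(nc - side + 1L)
  hi_r <- lo_r + side
  hi_c <- lo_c + side
  Z[hi_r, hi_c] - Z[lo_r, hi_c] - Z[hi_r, lo_c] + Z[lo_r, lo_c]
}

transform_naive <- function(image, win, hist, spec) {
  r <- win$r
  pad <- pad_image(image, r, win$border)
  bins <- as.integer(pad) %/% hist$bin_width + 1L
  dim(bins) <- dim(pad)
  npix <- win$side^2
  kmax <- hist$n_bins
  norm <- hist$normalize
  out <- matrix(NA_real_, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      cnt <- tabulate(bins[i:(i + 2L * r), j:(j + 2L * r)], nbins = kmax)
      mass <- if (norm) cnt / npix else as.numeric(cnt)
      out[i, j] <- reduced_entropy_mass(mass, spec$q, spec$q1)
    }
  }
  out
}

#' @export
print.entropy_map <- function(x, ...) {
  cat(sprintf("<entropy_map %d x %d>  q = %g, r = %d, bin_width = %d, %s, border = %s\n",
              nrow(x), ncol(x), attr(x, "q"), attr(x, "r"),
              attr(x, "bin_width"),
              if (attr(x, "normalize")) "normalized" else "raw counts",
              attr(x, "border")))
  cat(sprintf("  values in [%.6g, %.6g]\n", min(x), max(x)))
  invisible(x)
}

#' Write or read an entropy map as a lossless delimited text matrix
#'
#' @param map an `"entropy_map"` (or any numeric matrix).
#' @param path file path.
#' @return `write_entropy_map()` returns `path` invisibly;
#'   `read_entropy_map()` returns a numeric matrix.
#' @export
write_entropy_map <- function(map, path) {
  utils::write.table(format(unclass(map), digits = 17, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_entropy_map
#' @export
read_entropy_map <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
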