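#' Backbone feature extractors
#'
#' A backbone turns a color image into a fixed-length real descriptor — the
#' role played by the penultimate fully connected layer of a pretrained CNN.
#' Backbones are looked up by name in a registry; any deterministic
#' image-to-vector function satisfying the contract can be registered, so the
#' whole pipeline runs and is testable without pretrained weights.
#'
#' Two backbones ship with the package:
#'
#' * `"pooled-stats"` (default): a lightweight deterministic stand-in.
#'   The image is bilinearly resized to `input_side` (32), scaled to
#'   `[0, 1]`; the descriptor is the per-channel mean (3), per-channel
#'   population variance (3), and `output_dim - 6` fixed-seed Gaussian random
#'   projections of the flattened pixels (scaled by `1/sqrt(n_pixels)`).
#'   `output_dim` is 16.
#' * `"vgg19-penultimate"`: the VGG19 (VGG-VD) penultimate 4096-unit fully
#'   connected layer on 224 x 224 input. No pretrained weights are bundled;
#'   requesting extraction raises a configuration error directing the user to
#'   the stand-in (or to registering an extractor backed by a local deep
#'   learning runtime with downloaded weights).
#'
#' @param name backbone identifier.
#' @return `backbone_spec()` returns an object of class `"backbone_spec"`
#'   with fields `name`, `input_side`, `output_dim`; `list_backbones()`
#'   returns the registered names.
#' @export
backbone_spec <- function(name = "pooled-stats") {
  reg <- .etx$backbones
  if (is.null(reg[[name]]))
    stop("unknown backbone '", name, "'; registered: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]$spec
}

#' @rdname backbone_spec
#' @export
list_backbones <- function() names(.etx$backbones)

#' @rdname backbone_spec
#' @param input_side square input size in pixels the extractor expects.
#' @param output_dim descriptor length.
#' @param extract function `(color_array, spec) -> numeric(output_dim)`;
#'   must be deterministic.
#' @export
register_backbone <- function(name, input_side, output_dim, extract) {
  stopifnot(is.function(extract), input_side >= 1, output_dim >= 1)
  spec <- structure(list(name = name, input_side = as.integer(input_side),
                         output_dim = as.integer(output_dim)),
                    class = "backbone_spec")
  .etx$backbones[[name]] <- list(spec = spec, extract = extract)
  invisible(spec)
}

pooled_stats_extract <- function(arr, spec) {
  x <- resize_color(arr, spec$input_side) / 255
  mu <- apply(x, 3L, mean)
  va <- apply(x, 3L, function(ch) mean((ch - mean(ch))^2))
  d <- spec$output_dim - 6L
  if (d <= 0L) return(c(mu, va)[seq_len(spec$output_dim)])
  P <- projection_matrix(spec$input_side, d)
  c(mu, va, as.numeric(P %*% as.vector(x)) / sqrt(length(x)))
}

# Memoised fixed-seed Gaussian projection matrix (d x 3*side^2). The seed is
# a package constant, independent of user RNG, so extraction is a pure
# function of the image.
projection_matrix <- function(side, d) {
  key <- paste0("proj_", side, "_", d)
  if (is.null(.etx$cache[[key]])) {
    n <- 3L * side^2
    .etx$cache[[key]] <- with_seed(760301L, matrix(stats::rnorm(d * n), d, n))
  }
  .etx$cache[[key]]
}

vgg19_unavailable <- function(arr, spec) {
  stop("backbone 'vgg19-penultimate' has no pretrained weights available in ",
       "this installation; use the stand-in backbone 'pooled-stats', or ",
       "register_backbone() an extractor backed by a deep-learning runtime ",
       "with locally downloaded VGG19 weights", call. = FALSE)
}

#' Convert an entropy map to backbone input
#'
#' Entropy maps are real-valued with a q-dependent range; backbones expect
#' 8-bit, 3-channel, fixed-size input. The map is min-max rescaled to
#' `[0, 255]` (preserving relative local-entropy contrast, which is the
#' signal; a constant map becomes mid-gray 128), quantised with banker's
#' (round-half-even) rounding, replicated to 3 identical channels and
#' bilinearly resized to the backbone's native square input.
#'
#' @param map an `"entropy_map"` (any finite numeric matrix).
#' @param spec a [backbone_spec()].
#' @return an `input_side x input_side x 3` integer array.
#' @export
entropy_to_input <- function(map, spec = backbone_spec()) {
  m <- unclass(map)
  if (!all(is.finite(m))) stop("entropy map contains non-finite values")
  rng <- range(m)
  v <- if (rng[2] > rng[1]) {
    round((m - rng[1]) / (rng[2] - rng[1]) * 255)
  } else {
    matrix(128, nrow(m), ncol(m))
  }
  resize_color(matrix(as.integer(v), nrow(m), ncol(m)), spec$input_side)
}

#' Extract a backbone feature vector from an image
#'
#' Applies the named backbone to a color image (grayscale input is
#' channel-replicated) and tags the resulting descriptor with its stream of
#' origin, so that fusion can verify provenance.
#'
#' @param img H x W x 3 integer array or integer matrix.
#' @param spec a [backbone_spec()].
#' @param stream provenance tag: `"original"` or `"entropy"`.
#' @param q entropic index used to produce `img` (entropy stream only).
#' @return numeric vector of class `"feature_vector"` of length
#'   `spec$output_dim`, with attributes `stream`, `backbone`, `q`.
#' @export
extract_features <- function(img, spec = backbone_spec(),
                             stream = c("original", "entropy"), q = NA_real_) {
  stream <- match.arg(stream)
  entry <- .etx$backbones[[spec$name]]
  if (is.null(entry)) stop("unknown backbone '", spec$name, "'")
  v <- entry$extract(as_color(img), spec)
  if (length(v) != spec$output_dim || !all(is.finite(v)))
    stop("backbone '", spec$name, "' returned an invalid descriptor")
  structure(as.numeric(v), class = "feature_vector",
            stream = stream, backbone = spec$name, q = q)
}

#' Fuse the original-image and entropy-stream descriptors
#'
#' Concatenates the two penultimate-layer descriptors of the same image,
#' original stream first, to form the final texture descriptor.
#'
#' @param original_fv `"feature_vector"` with stream tag `"original"`.
#' @param entropy_fv `"feature_vector"` with stream tag `"entropy"`, from the
#'   same backbone.
#' @return `"feature_vector"` of length `length(original_fv) +
#'   length(entropy_fv)` with stream tag `"fused"`.
#' @export
fuse <- function(original_fv, entropy_fv) {
  if (!inherits(original_fv, "feature_vector") ||
      !inherits(entropy_fv, "feature_vector"))
    stop("fuse() expects two feature_vector objects")
  if (length(original_fv) == 0L || length(entropy_fv) == 0L)
    stop("cannot fuse empty feature vectors")
  if (!identical(attr(original_fv, "stream"), "original") ||
      !identical(attr(entropy_fv, "stream"), "entropy"))
    stop("fuse() expects an original-stream and an entropy-stream vector, ",
         "in that order")
  if (!identical(attr(original_fv, "backbone"), attr(entropy_fv, "backbone")))
    stop("cannot fuse descriptors from different backbones")
  structure(c(unclass(original_fv), unclass(entropy_fv)),
            class = "feature_vector", stream = "fused",
            backbone = attr(original_fv, "backbone"),
            q = attr(entropy_fv, "q"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector length %d>  stream = %s, backbone = %s, q = %s\n",
              length(x), attr(x, "stream"), attr(x, "backbone"),
              format(attr(x, "q"))))
  invisible(x)
}
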