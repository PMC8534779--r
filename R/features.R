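#' Pipeline configuration
#'
#' Bundles every knob of the descriptor pipeline: the entropic index and its
#' window/histogram parameters, the backbone, and which stream(s) feed the
#' classifier.
#'
#' @param q entropic index for the entropy stream.
#' @param window a [window_spec()].
#' @param histogram a [histogram_spec()].
#' @param backbone backbone name (see [list_backbones()]).
#' @param stream which descriptor feeds the classifier: `"fused"`
#'   (concatenated original + entropy, the method's default), `"original"`,
#'   or `"entropy"`.
#' @param reducer a [reducer_spec()].
#' @param q1 behaviour of the reduced entropy at `q = 1` (see
#'   [entropy_spec()]).
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(q = 1.5, window = window_spec(),
                            histogram = histogram_spec(),
                            backbone = "pooled-stats",
                            stream = c("fused", "original", "entropy"),
                            reducer = reducer_spec(),
                            q1 = c("bgs", "raw")) {
  stream <- match.arg(stream)
  q1 <- match.arg(q1)
  structure(list(q = q, window = window, histogram = histogram,
                 backbone = backbone, stream = stream, reducer = reducer,
                 entropy = entropy_spec(q = q, q1 = q1)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config: q = %g, r = %d, bin_width = %d (%s), backbone = %s, stream = %s>\n",
    x$q, x$window$r, x$histogram$bin_width,
    if (x$histogram$normalize) "normalized" else "raw", x$backbone, x$stream))
  invisible(x)
}

#' Feature cache
#'
#' Descriptors are expensive relative to everything downstream, so they are
#' memoised per (image content, stream, backbone, entropy parameters). The
#' original-image stream's key does not involve `q`, so a sweep over many
#' `q` values computes that stream exactly once per image; changing `q`
#' invalidates only entropy-stream entries. With `dir` set, entries are also
#' persisted on disk and survive the session.
#'
#' @param dir optional directory for on-disk persistence.
#' @return an object of class `"feature_cache"` with counters `hits` and
#'   `misses` (misses equal extractor invocations made through the cache).
#' @export
feature_cache <- function(dir = NULL) {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  e$dir <- dir
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  class(e) <- "feature_cache"
  e
}

#' @export
print.feature_cache <- function(x, ...) {
  cat(sprintf("<feature_cache: %d entries, %d hits, %d misses%s>\n",
              length(ls(x$store)), x$hits, x$misses,
              if (is.null(x$dir)) "" else paste0(", dir = ", x$dir)))
  invisible(x)
}

cache_fetch <- function(cache, key, compute) {
  if (is.null(cache)) return(compute())
  hit <- cache$store[[key]]
  if (is.null(hit) && !is.null(cache$dir)) {
    f <- file.path(cache$dir, paste0(key, ".rds"))
    if (file.exists(f)) {
      hit <- tryCatch(readRDS(f), error = function(e) {
        warning("corrupt cache entry ", key, "; recomputing")
        NULL
      })
      if (!is.null(hit)) cache$store[[key]] <- hit
    }
  }
  if (!is.null(hit)) {
    cache$hits <- cache$hits + 1L
    return(hit)
  }
  cache$misses <- cache$misses + 1L
  val <- compute()
  cache$store[[key]] <- val
  if (!is.null(cache$dir))
    saveRDS(val, file.path(cache$dir, paste0(key, ".rds")))
  val
}

# Content-addressed cache keys. The original stream is independent of the
# entropy parameters by construction.
feature_key <- function(img, stream, config) {
  params <- if (stream == "entropy") {
    list(q = config$q, q1 = config$entropy$q1, r = config$window$r,
         border = config$window$border, bin_width = config$histogram$bin_width,
         normalize = config$histogram$normalize)
  } else NULL
  digest::digest(list(img = img, stream = stream,
                      backbone = config$backbone, params = params))
}

# Descriptor of one image under `config`. Color goes to the original stream;
# the entropy stream always works on the grayscale version.
sample_features <- function(img, config, cache = NULL) {
  bspec <- backbone_spec(config$backbone)
  need_orig <- config$stream %in% c("fused", "original")
  need_ent <- config$stream %in% c("fused", "entropy")
  fo <- if (need_orig) {
    cache_fetch(cache, feature_key(img, "original", config),
                function() extract_features(img, bspec, stream = "original"))
  }
  fe <- if (need_ent) {
    cache_fetch(cache, feature_key(img, "entropy", config), function() {
      emap <- entropy_transform(to_grayscale(img), config$window,
                                config$histogram, config$entropy)
      extract_features(entropy_to_input(emap, bspec), bspec,
                       stream = "entropy", q = config$q)
    })
  }
  switch(config$stream,
         fused = fuse(fo, fe),
         original = fo,
         entropy = fe)
}

#' Compute the descriptor matrix of a dataset
#'
#' Applies the configured descriptor pipeline (original stream, entropy
#' stream, or their fusion) to every sample.
#'
#' @param ds a [texture_dataset()].
#' @param config a [pipeline_config()].
#' @param cache optional [feature_cache()].
#' @return numeric matrix, one row per sample (rownames = sample ids).
#' @export
compute_features <- function(ds, config = pipeline_config(), cache = NULL) {
  rows <- lapply(ds$images, sample_features, config = config, cache = cache)
  m <- do.call(rbind, lapply(rows, unclass))
  rownames(m) <- ds$ids
  m
}

#' Write a descriptor matrix as delimited text
#'
#' Tab-separated: sample id, class label, q, stream tag, then the feature
#' values with full round-trip precision.
#'
#' @param features matrix from [compute_features()].
#' @param ds the [texture_dataset()] the features came from.
#' @param config the [pipeline_config()] used.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, ds, config, path) {
  df <- data.frame(id = ds$ids, label = as.character(ds$labels),
                   q = config$q, stream = config$stream,
                   check.names = FALSE)
  vals <- as.data.frame(features)
  names(vals) <- sprintf("f%03d", seq_len(ncol(features)))
  utils::write.table(cbind(df, vals), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
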