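#' Train/test split plans under benchmark protocols
#'
#' Two protocols are supported:
#'
#' * `"sample_holdout"` (KTH-TIPS-2b style): each class is divided into a few
#'   acquisition samples (tags); every fold holds out one whole tag for
#'   testing and trains on the rest, enumerating all tag combinations — with
#'   4 tags this gives exactly 4 folds.
#' * `"half_half"` (FMD/UIUC/UMD/1200Tex style): within every class, half of
#'   the images are drawn at random for training and the other half for
#'   testing; repeated `repetitions` times (default 10). With an odd class
#'   size the extra image goes to training.
#'
#' The plan is deterministic given `seed`: the master seed is expanded into
#' one seed per fold by a fixed counter scheme, and those per-fold seeds are
#' also used downstream (e.g. for cross-validated component selection), so a
#' persisted plan re-runs to identical results.
#'
#' @param ds a [texture_dataset()].
#' @param protocol `"sample_holdout"` or `"half_half"`.
#' @param repetitions number of random half/half repetitions (ignored for
#'   sample_holdout).
#' @param seed master integer seed.
#' @return an object of class `"split_plan"`: list with `protocol`, `folds`
#'   (each a list with integer `train`, `test` and a `seed`), `repetitions`,
#'   `seed`.
#' @export
make_split_plan <- function(ds, protocol = c("sample_holdout", "half_half"),
                            repetitions = 10L, seed = 1L) {
  protocol <- match.arg(protocol)
  labels <- ds$labels
  folds <- if (protocol == "sample_holdout") {
    if (is.null(ds$tags) || all(is.na(ds$tags)))
      stop("protocol 'sample_holdout' requires acquisition-sample tags")
    tags <- ds$tags
    utags <- sort(unique(stats::na.omit(tags)))
    fseeds <- derive_seeds(seed, length(utags))
    lapply(seq_along(utags), function(i) {
      test <- which(tags == utags[i])
      train <- which(tags != utags[i] & !is.na(tags))
      list(train = train, test = test, seed = fseeds[i],
           held_out_tag = utags[i])
    })
  } else {
    fseeds <- derive_seeds(seed, repetitions)
    lapply(seq_len(repetitions), function(rep) {
      train <- integer()
      with_seed(fseeds[rep], {
        for (cl in levels(labels)) {
          idx <- which(labels == cl)
          train <- c(train, sample(idx, ceiling(length(idx) / 2)))
        }
      })
      list(train = sort(train),
           test = setdiff(seq_along(labels), train),
           seed = fseeds[rep])
    })
  }
  for (f in folds) {
    if (length(f$train) == 0L || length(f$test) == 0L)
      stop("degenerate fold with an empty train or test set")
  }
  structure(list(protocol = protocol, folds = folds,
                 repetitions = if (protocol == "half_half") repetitions else
                   length(folds),
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %s, %d folds, seed %s>\n", x$protocol,
              length(x$folds), format(x$seed)))
  for (i in seq_along(x$folds)) {
    f <- x$folds[[i]]
    cat(sprintf("  fold %d: %d train / %d test%s\n", i, length(f$train),
                length(f$test),
                if (!is.null(f$held_out_tag))
                  paste0(" (held-out tag ", f$held_out_tag, ")") else ""))
  }
  invisible(x)
}

# Stratified assignment of samples to k cross-validation folds: within each
# class, shuffled indices are dealt round-robin, so per-class (and total)
# fold sizes differ by at most one.
assign_cv_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  ptr <- 0L
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      fold[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
      ptr <- ptr + length(idx)
    }
  })
  fold
}
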