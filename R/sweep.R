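#' Select the entropic index q by K-fold cross-validation
#'
#' Sweeps a grid of q values through the full pipeline on the training set
#' only: the training images are divided at random into K subsets of roughly
#' equal size (stratified by class, sizes differing by at most one); for each
#' q the descriptors are recomputed, the reducer and classifier are refit on
#' K-1 subsets and scored on the held-out subset, and the mean accuracy over
#' the K folds is recorded. The q attaining the highest mean accuracy is
#' selected; ties are broken toward the q closest to 1 (the most neutral,
#' least "regularizing" index), and toward the smaller q if still tied.
#'
#' The same fold assignment is reused for every q, so the comparison across
#' the grid is paired. Descriptors are cached per (image, stream, q): the
#' original-image stream is computed once for the whole sweep and runtime
#' scales linearly in the grid size.
#'
#' @param ds a [texture_dataset()] — training data only; the outer protocol's
#'   test samples must not be passed in.
#' @param grid numeric vector of candidate q values (all > 0). The default
#'   spans 0.25–2.
#' @param K number of validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param config a [pipeline_config()]; its `q` is overridden by each grid
#'   value.
#' @param cache optional [feature_cache()].
#' @return an object of class `"q_sweep"`: `table` (data frame with `q`,
#'   `mean_cv_accuracy`, `sd_cv_accuracy`), `best_q`, `K`, `seed`.
#' @examples
#' ds <- generate_texture_dataset(default_texture_classes(),
#'                                n_per_class = 6, side = 32, seed = 1)
#' sweep_q(ds, grid = c(0.5, 1.5), K = 3, seed = 1)
#' @export
sweep_q <- function(ds, grid = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
                    K = 5L, seed = 1L, config = pipeline_config(),
                    cache = NULL) {
  if (length(grid) == 0L) stop("`grid` must contain at least one q value")
  if (any(!is.finite(grid)) || any(grid <= 0))
    stop("all q values in `grid` must be positive")
  if (K < 2L) stop("`K` must be at least 2")
  if (is.null(cache)) cache <- feature_cache()
  labels <- droplevels(ds$labels)
  fold <- assign_cv_folds(labels, K, seed)
  fold_seeds <- derive_seeds(seed, K)
  mean_acc <- sd_acc <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    cfg <- config
    cfg$q <- grid[gi]
    cfg$entropy <- entropy_spec(q = grid[gi], q1 = config$entropy$q1)
    features <- compute_features(ds, cfg, cache)
    accs <- vapply(seq_len(K), function(f) {
      tr <- which(fold != f)
      te <- which(fold == f)
      model <- texture_classifier(subset_dataset(ds, tr), cfg,
                                  seed = fold_seeds[f],
                                  features = features[tr, , drop = FALSE])
      pred <- predict(model, features[te, , drop = FALSE])
      mean(as.character(pred) == as.character(labels[te]))
    }, 0)
    mean_acc[gi] <- mean(accs)
    sd_acc[gi] <- stats::sd(accs)
  }
  best_acc <- max(mean_acc)
  contenders <- grid[mean_acc == best_acc]
  best_q <- contenders[order(abs(contenders - 1), contenders)][1L]
  structure(list(table = data.frame(q = grid, mean_cv_accuracy = mean_acc,
                                    sd_cv_accuracy = sd_acc),
                 best_q = best_q, K = K, seed = seed),
            class = "q_sweep")
}

#' @export
print.q_sweep <- function(x, ...) {
  cat(sprintf("<q_sweep: %d-fold CV over %d q values, seed %s>\n",
              x$K, nrow(x$table), format(x$seed)))
  print(x$table, row.names = FALSE)
  cat(sprintf("  best q: %g\n", x$best_q))
  invisible(x)
}

#' @export
plot.q_sweep <- function(x, ...) {
  graphics::plot(x$table$q, x$table$mean_cv_accuracy, type = "b",
                 xlab = "entropic index q", ylab = "mean CV accuracy", ...)
  graphics::abline(v = x$best_q, lty = 2)
  invisible(x)
}
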