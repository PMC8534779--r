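#' Evaluate the pipeline under a split protocol
#'
#' For every fold of the plan the model (PCA reducer + LDA, on the configured
#' descriptor stream) is fit on the fold's training samples only and applied
#' to its test samples; per-fold accuracies, their mean, and a pooled
#' confusion matrix are reported. Descriptors are computed once per sample
#' and shared across folds (they involve no fitting, so this leaks nothing);
#' all fitted parameters depend only on training indices.
#'
#' @param ds a [texture_dataset()].
#' @param plan a [make_split_plan()] for `ds`.
#' @param config a [pipeline_config()].
#' @param cache optional [feature_cache()] (one is created internally if
#'   `NULL`, so repeated streams within the run are never recomputed).
#' @return an object of class `"eval_report"`: `per_fold_accuracy`,
#'   `mean_accuracy`, `confusion` (rows = true, columns = predicted, counts
#'   pooled over folds), `chosen_components` (per fold), `q_used`,
#'   `protocol`, `stream`.
#' @examples
#' ds <- generate_texture_dataset(default_texture_classes(),
#'                                n_per_class = 6, side = 32, seed = 1)
#' plan <- make_split_plan(ds, "half_half", repetitions = 2, seed = 1)
#' evaluate(ds, plan, pipeline_config(q = 1.5))
#' @export
evaluate <- function(ds, plan, config = pipeline_config(), cache = NULL) {
  if (is.null(cache)) cache <- feature_cache()
  features <- compute_features(ds, config, cache)
  labels <- ds$labels
  classes <- levels(labels)
  nf <- length(plan$folds)
  acc <- numeric(nf)
  ncomp <- integer(nf)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (f in seq_len(nf)) {
    fold <- plan$folds[[f]]
    res <- tryCatch({
      model <- texture_classifier(
        subset_dataset(ds, fold$train), config,
        seed = fold$seed,
        features = features[fold$train, , drop = FALSE])
      pred <- predict(model, features[fold$test, , drop = FALSE])
      list(model = model, pred = pred)
    }, error = function(e) {
      stop("fold ", f, " failed: ", conditionMessage(e), call. = FALSE)
    })
    truth <- factor(labels[fold$test], levels = classes)
    pred <- factor(res$pred, levels = classes)
    acc[f] <- mean(pred == truth)
    ncomp[f] <- res$model$reducer$ncomp
    confusion <- confusion + unclass(table(truth, pred))
  }
  structure(list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
                 confusion = confusion, chosen_components = ncomp,
                 q_used = config$q, protocol = plan$protocol,
                 stream = config$stream),
            class = "eval_report")
}

subset_dataset <- function(ds, idx) {
  structure(list(images = ds$images[idx], labels = droplevels(ds$labels[idx]),
                 classes = levels(droplevels(ds$labels[idx])),
                 tags = if (is.null(ds$tags)) NULL else ds$tags[idx],
                 ids = ds$ids[idx]),
            class = "texture_dataset")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: %s protocol, %d folds, stream = %s, q = %g>\n",
    x$protocol, length(x$per_fold_accuracy), x$stream, x$q_used))
  cat(sprintf("  mean accuracy: %.4f  (per fold: %s)\n", x$mean_accuracy,
              paste(sprintf("%.3f", x$per_fold_accuracy), collapse = ", ")))
  cat(sprintf("  PCA components per fold: %s\n",
              paste(x$chosen_components, collapse = ", ")))
  invisible(x)
}

#' @export
summary.eval_report <- function(object, ...) {
  print(object)
  cat("\nPooled confusion matrix (rows = true, columns = predicted):\n")
  print(object$confusion)
  invisible(object)
}

#' Serialize an evaluation report
#'
#' Writes the accuracies, chosen component counts and q as JSON, and the
#' pooled confusion matrix as a tab-delimited table.
#'
#' @param report an `"eval_report"`.
#' @param json_path output JSON file.
#' @param confusion_path optional output TSV for the confusion matrix.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(report, json_path, confusion_path = NULL) {
  jsonlite::write_json(
    list(protocol = report$protocol, stream = report$stream,
         q = report$q_used,
         mean_accuracy = report$mean_accuracy,
         per_fold_accuracy = report$per_fold_accuracy,
         chosen_components = report$chosen_components),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_path))
    utils::write.table(report$confusion, confusion_path, sep = "\t",
                       quote = FALSE, col.names = NA)
  invisible(json_path)
}
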