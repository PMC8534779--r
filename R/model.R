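#' Fit the full texture recognition model
#'
#' Fits the complete pipeline on a labeled dataset: descriptors (original
#' stream, local-entropy stream, or their fusion, per `config$stream`), PCA
#' with cross-validated component count, and the LDA classifier. This is the
#' model that [evaluate()] refits on every fold of a split plan.
#'
#' @param ds a [texture_dataset()] — the training data.
#' @param config a [pipeline_config()].
#' @param seed integer seed controlling the component-selection folds.
#' @param cache optional [feature_cache()].
#' @param features optional precomputed feature matrix for `ds` (rows in
#'   dataset order), bypassing descriptor computation.
#' @return an object of class `"texture_classifier"` with components
#'   `config`, `reducer` (a `"pca_reducer"`), `lda` (a `"tex_lda"`),
#'   `classes`, `n_train`.
#' @seealso [predict.texture_classifier()], [evaluate()]
#' @examples
#' specs <- default_texture_classes()
#' ds <- generate_texture_dataset(specs, n_per_class = 6, side = 32, seed = 1)
#' fit <- texture_classifier(ds, pipeline_config(q = 1.5), seed = 1)
#' fit
#' @export
texture_classifier <- function(ds, config = pipeline_config(), seed = 1L,
                               cache = NULL, features = NULL) {
  if (is.null(features)) features <- compute_features(ds, config, cache)
  labels <- droplevels(ds$labels)
  reducer <- fit_reducer(features, labels, config$reducer, seed = seed)
  lda <- train_classifier(predict(reducer, features), labels)
  structure(list(config = config, reducer = reducer, lda = lda,
                 classes = levels(labels), n_train = nrow(features)),
            class = "texture_classifier")
}

#' Predict classes for new images
#'
#' @param object a fitted [texture_classifier()].
#' @param newdata a [texture_dataset()], a list of images, or a precomputed
#'   feature matrix with the same columns as the training features.
#' @param cache optional [feature_cache()].
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.texture_classifier <- function(object, newdata, cache = NULL, ...) {
  features <- if (is.matrix(newdata)) {
    newdata
  } else {
    if (!inherits(newdata, "texture_dataset")) {
      imgs <- if (is.list(newdata)) newdata else list(newdata)
      do.call(rbind, lapply(imgs, function(im)
        unclass(sample_features(im, object$config, cache))))
    } else {
      compute_features(newdata, object$config, cache)
    }
  }
  predict(object$lda, predict(object$reducer, features))
}

#' @export
print.texture_classifier <- function(x, ...) {
  cat(sprintf(
    "<texture_classifier: %d classes, %d training samples>\n  stream = %s, q = %g, backbone = %s\n  PCA components = %d (CV-selected), LDA engine = %s\n",
    length(x$classes), x$n_train, x$config$stream, x$config$q,
    x$config$backbone, x$reducer$ncomp, x$lda$engine))
  invisible(x)
}

#' @export
summary.texture_classifier <- function(object, ...) {
  print(object)
  cat("\nComponent selection (5-fold CV on training set):\n")
  print(object$reducer$cv, row.names = FALSE)
  invisible(object)
}
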