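#' Dimension reduction specification
#'
#' PCA precedes the discriminant classifier to bound its dimension. The
#' number of components is chosen from `grid` by `cv_folds`-fold
#' cross-validated accuracy of the downstream classifier on the training set
#' only, never more than `max_components` (default 200) nor the rank bound
#' `min(n_train - 1, n_features)`. Ties are broken toward fewer components.
#'
#' @param max_components hard cap on retained components (default 200).
#' @param grid candidate component counts (intersected with the rank bound).
#' @param cv_folds folds for the selection cross-validation (default 5).
#' @return an object of class `"reducer_spec"`.
#' @export
reducer_spec <- function(max_components = 200L,
                         grid = c(10L, 25L, 50L, 100L, 150L, 200L),
                         cv_folds = 5L) {
  structure(list(max_components = as.integer(max_components),
                 grid = sort(unique(as.integer(grid))),
                 cv_folds = as.integer(cv_folds)),
            class = "reducer_spec")
}

#' Fit a cross-validated PCA reducer
#'
#' Principal components are fit on the training features only (centering, no
#' whitening — the discriminant handles scaling). For each candidate
#' component count, PCA and the classifier are refit within each
#' cross-validation fold and the mean held-out accuracy is recorded; the
#' smallest count attaining the maximum is selected and a final PCA with
#' that many components is fit on the full training set.
#'
#' @param x training feature matrix (rows = samples).
#' @param labels training class labels.
#' @param spec a [reducer_spec()].
#' @param seed integer seed for the fold assignment.
#' @return an object of class `"pca_reducer"`: `center`, `rotation`,
#'   `ncomp`, and `cv` (data frame of candidate counts and CV accuracies).
#'   Use `predict()` to project new feature rows.
#' @export
fit_reducer <- function(x, labels, spec = reducer_spec(), seed = 1L) {
  x <- as.matrix(x)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L)
    stop("cannot fit a reducer on a single-class training set")
  n <- nrow(x)
  k <- spec$cv_folds
  fold <- assign_cv_folds(labels, k, seed)
  min_train <- min(vapply(seq_len(k), function(f) sum(fold != f), 0L))
  cap <- min(spec$max_components, n - 1L, ncol(x), min_train - 1L)
  cand <- spec$grid[spec$grid <= cap]
  if (length(cand) == 0L) cand <- cap
  if (min(table(labels)) < 3L) {
    # too few samples per class for internal CV (some CV-training part would
    # hold a single sample of a class); fall back to the fewest components
    message("training classes too small for component cross-validation; ",
            "using ", cand[1L], " components")
    pca <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = cand[1L])
    ncomp <- min(cand[1L], ncol(pca$rotation), pca_effective_rank(pca))
    return(structure(list(center = pca$center,
                          rotation = pca$rotation[, seq_len(ncomp),
                                                  drop = FALSE],
                          ncomp = ncomp,
                          cv = data.frame(ncomp = cand[1L],
                                          cv_accuracy = NA_real_)),
                     class = "pca_reducer"))
  }
  cv_acc <- numeric(length(cand))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L || sum(!tr) == 0L) next
    pca <- stats::prcomp(x[tr, , drop = FALSE], center = TRUE,
                         scale. = FALSE, rank. = max(cand))
    erank <- pca_effective_rank(pca)
    ztr <- pca$x
    zte <- scale(x[!tr, , drop = FALSE], center = pca$center,
                 scale = FALSE) %*% pca$rotation
    for (ci in seq_along(cand)) {
      d <- min(cand[ci], ncol(ztr), erank)
      cls <- train_classifier(ztr[, seq_len(d), drop = FALSE], labels[tr])
      pred <- predict(cls, zte[, seq_len(d), drop = FALSE])
      cv_acc[ci] <- cv_acc[ci] + mean(pred == labels[!tr]) / k
    }
  }
  best <- cand[which.max(cv_acc)]  # which.max takes the first (fewest) on ties
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = best)
  ncomp <- min(best, ncol(pca$rotation), pca_effective_rank(pca))
  structure(list(center = pca$center,
                 rotation = pca$rotation[, seq_len(ncomp), drop = FALSE],
                 ncomp = ncomp,
                 cv = data.frame(ncomp = cand, cv_accuracy = cv_acc)),
            class = "pca_reducer")
}

# Number of principal components carrying non-negligible variance; retained
# components are capped here so downstream covariances stay non-singular.
pca_effective_rank <- function(pca, tol = 1e-8) {
  sum(pca$sdev > pca$sdev[1L] * tol)
}

#' @export
predict.pca_reducer <- function(object, newdata, ...) {
  scale(as.matrix(newdata), center = object$center, scale = FALSE) %*%
    object$rotation
}

#' @export
print.pca_reducer <- function(x, ...) {
  cat(sprintf("<pca_reducer: %d components (CV-selected)>\n", x$ncomp))
  print(x$cv, row.names = FALSE)
  invisible(x)
}

#' Train the linear discriminant classifier
#'
#' Classic pooled-within-class-covariance LDA, the classifier of the
#' pipeline (chosen because it involves no critical hyperparameter). Fitting
#' is delegated to [MASS::lda()]; if the pooled covariance is singular
#' (constant or collinear variables), the model is refit with a small ridge
#' `lambda = 1e-6 * trace(S) / d` added to the diagonal, with a message.
#' Priors are the training class proportions. Deterministic.
#'
#' @param x training feature matrix (typically PCA scores).
#' @param labels training class labels; every class needs at least 2
#'   samples.
#' @return an object of class `"tex_lda"`; use `predict()` for class labels.
#' @export
train_classifier <- function(x, labels) {
  x <- as.matrix(x)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 training samples")
  fit <- tryCatch(
    suppressWarnings(MASS::lda(x, grouping = labels)),
    error = function(e) NULL)
  if (!is.null(fit))
    return(structure(list(engine = "mass", fit = fit,
                          levels = levels(labels)),
                     class = "tex_lda"))
  message("pooled covariance is singular; applying ridge regularization")
  ridge_lda(x, labels)
}

# Ridge-regularized pooled-covariance LDA, used only when MASS::lda cannot
# invert the within-class covariance.
ridge_lda <- function(x, labels, lambda_scale = 1e-6) {
  d <- ncol(x)
  lev <- levels(labels)
  M <- t(vapply(lev, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                numeric(d)))
  S <- matrix(0, d, d)
  for (cl in lev) {
    xc <- scale(x[labels == cl, , drop = FALSE], center = M[cl, ],
                scale = FALSE)
    S <- S + crossprod(xc)
  }
  S <- S / (nrow(x) - length(lev))
  lambda <- lambda_scale * sum(diag(S)) / d
  if (lambda <= 0) lambda <- lambda_scale
  W <- solve(S + diag(lambda, d))
  priors <- as.numeric(table(labels)) / nrow(x)
  structure(list(engine = "ridge", means = M, W = W,
                 log_priors = log(priors), levels = lev, lambda = lambda),
            class = "tex_lda")
}

#' @export
predict.tex_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$engine == "mass") {
    return(stats::predict(object$fit, newdata)$class)
  }
  A <- object$W %*% t(object$means)                       # d x K
  scores <- newdata %*% A                                 # n x K
  offs <- -0.5 * colSums(t(object$means) * A) + object$log_priors
  scores <- sweep(scores, 2L, offs, "+")
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.tex_lda <- function(x, ...) {
  cat(sprintf("<tex_lda: %d classes, engine = %s%s>\n",
              length(x$levels), x$engine,
              if (x$engine == "ridge")
                sprintf(" (lambda = %.3g)", x$lambda) else ""))
  invisible(x)
}
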