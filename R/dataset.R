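#' Labeled texture datasets
#'
#' `texture_dataset()` builds an in-memory labeled dataset from a list of
#' images; `load_dataset()` reads one from disk in the standard
#' class-per-subdirectory layout used by texture benchmarks (KTH-TIPS-2b,
#' FMD, UIUC, UMD, 1200Tex): one subdirectory per class, image files inside.
#' Classes are ordered lexicographically by directory name so confusion
#' matrices are deterministic.
#'
#' For protocols that hold out whole acquisition samples (KTH-TIPS-2b style,
#' where each class is divided into a few acquisition samples differing in
#' scale, pose and illumination), a `tag_pattern` — a regular expression with
#' one capture group — extracts the acquisition-sample tag from each
#' filename; files not matching get tag `NA` and cannot be used with the
#' sample-holdout protocol.
#'
#' @param images list of integer intensity matrices or H x W x 3 arrays.
#' @param labels class label per image (coerced to factor).
#' @param tags optional acquisition-sample tag per image.
#' @param ids optional sample identifiers (defaults to file paths or an
#'   index).
#' @return an object of class `"texture_dataset"`: list with `images`,
#'   `labels` (factor), `classes`, `tags`, `ids`.
#' @export
texture_dataset <- function(images, labels, tags = NULL, ids = NULL) {
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list")
  labels <- factor(labels)
  if (length(labels) != length(images))
    stop("`labels` must have one entry per image")
  if (nlevels(labels) < 2L)
    stop("a labeled dataset needs at least 2 classes")
  if (!is.null(tags) && length(tags) != length(images))
    stop("`tags` must have one entry per image")
  if (is.null(ids)) ids <- sprintf("sample_%04d", seq_along(images))
  structure(list(images = images, labels = labels, classes = levels(labels),
                 tags = tags, ids = as.character(ids)),
            class = "texture_dataset")
}

#' @rdname texture_dataset
#' @param root dataset root directory (one subdirectory per class).
#' @param tag_pattern optional regular expression with one capture group
#'   applied to filenames to extract acquisition-sample tags, e.g.
#'   `"^[^_]+_sample_([a-d])"`.
#' @export
load_dataset <- function(root, tag_pattern = NULL) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  class_dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(class_dirs) < 2L)
    stop("dataset root must contain at least 2 class subdirectories")
  images <- list()
  labels <- character()
  tags <- character()
  ids <- character()
  n_skipped <- 0L
  for (d in class_dirs) {
    cls <- basename(d)
    files <- sort(list.files(d, full.names = TRUE,
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE))
    if (length(files) == 0L)
      stop("class directory '", cls, "' contains no readable images")
    for (f in files) {
      img <- tryCatch(read_image(f), error = function(e) NULL)
      if (is.null(img)) { n_skipped <- n_skipped + 1L; next }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cls)
      ids <- c(ids, f)
      tags <- c(tags, if (is.null(tag_pattern)) NA_character_ else {
        b <- basename(f)
        if (grepl(tag_pattern, b)) sub(paste0(".*?", tag_pattern, ".*"), "\\1", b)
        else NA_character_
      })
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " unreadable image file(s) skipped")
  texture_dataset(images, labels,
                  tags = if (is.null(tag_pattern)) NULL else tags,
                  ids = ids)
}

#' @export
print.texture_dataset <- function(x, ...) {
  cat(sprintf("<texture_dataset: %d samples, %d classes>\n",
              length(x$images), length(x$classes)))
  print(table(x$labels))
  if (!is.null(x$tags))
    cat("acquisition-sample tags:",
        paste(sort(unique(stats::na.omit(x$tags))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.texture_dataset <- function(x) length(x$images)

#' Write a dataset to disk in the class-per-directory layout
#'
#' Grayscale images are written as 8-bit PNG files, one subdirectory per
#' class — the layout [load_dataset()] reads.
#'
#' @param ds a [texture_dataset()].
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(ds, root) {
  for (i in seq_along(ds$images)) {
    cls <- as.character(ds$labels[i])
    dir.create(file.path(root, cls), recursive = TRUE, showWarnings = FALSE)
    stem <- tools::file_path_sans_ext(basename(ds$ids[i]))
    png::writePNG(ds$images[[i]] / 255,
                  file.path(root, cls, sprintf("%s.png", stem)))
  }
  invisible(root)
}
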