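#' Read a raster image as integer intensities
#'
#' Decodes a PNG, JPEG or TIFF file (by extension) into an integer intensity
#' matrix (grayscale) or a height x width x 3 integer array (color), values
#' in `[0, 255]`. An alpha channel is dropped. Images with more than 8 bits
#' per sample are rescaled to `[0, 255]` with a warning. No color management
#' is applied: raw decoded values are used.
#'
#' @param path image file path.
#' @return integer matrix (grayscale) or H x W x 3 integer array (color).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' for ", path)
  )
  if (max(raw) > 1) {  # 16-bit TIFF decoded as raw integers
    warning("more than 8 bits per sample in ", basename(path),
            "; rescaling to [0, 255]")
    raw <- raw / max(raw)
  }
  v <- round(raw * 255)
  if (length(dim(v)) == 3L) {
    if (dim(v)[3L] >= 3L) return(array(as.integer(v[, , 1:3]), dim = c(dim(v)[1:2], 3L)))
    v <- v[, , 1L]
  }
  matrix(as.integer(v), nrow(v), ncol(v))
}

#' Write an 8-bit grayscale preview of a matrix as PNG
#'
#' Min-max scales `x` to `[0, 1]` (a constant matrix maps to mid-gray) and
#' writes it as an 8-bit grayscale PNG — the lossy companion of
#' [write_entropy_map()].
#'
#' @param x numeric matrix (e.g. an `"entropy_map"`).
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_preview_png <- function(x, path) {
  rng <- range(x)
  v <- if (rng[2] > rng[1]) (unclass(x) - rng[1]) / (rng[2] - rng[1])
       else matrix(0.5, nrow(x), ncol(x))
  png::writePNG(v, path)
  invisible(path)
}

#' Convert a color image to grayscale luminance
#'
#' ITU-R BT.601 luma weights (0.299, 0.587, 0.114), rounded to integers in
#' `[0, 255]`. A grayscale matrix is returned unchanged.
#'
#' @param img H x W x 3 integer array, or an integer matrix.
#' @return integer intensity matrix.
#' @examples
#' to_grayscale(array(c(255, 0, 0), c(1, 1, 3)))  # 76
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("`img` must be a matrix or an H x W x 3 array")
  g <- round(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  matrix(as.integer(g), dim(img)[1L], dim(img)[2L])
}

# Replicate a grayscale matrix into an H x W x 3 array; pass color through.
as_color <- function(img) {
  if (is.matrix(img)) array(img, c(dim(img), 3L)) else img
}

# Bilinear resize of an H x W x 3 array (or matrix) to side x side,
# delegated to EBImage (which stores images x-first, hence the transposes).
# Returns integers clamped to [0, 255].
resize_color <- function(img, side) {
  arr <- as_color(img)
  if (nrow(arr) == side && ncol(arr) == side) return(arr)
  e <- EBImage::Image(aperm(arr, c(2L, 1L, 3L)) / 255, colormode = "Color")
  r <- EBImage::resize(e, w = side, h = side, filter = "bilinear")
  out <- round(aperm(EBImage::imageData(r), c(2L, 1L, 3L)) * 255)
  array(as.integer(pmin(pmax(out, 0L), 255L)), c(side, side, 3L))
}
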