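#' Construct a cone image
#'
#' A light container for a grayscale AOSLO frame: an intensity matrix plus an
#' optional micron-per-pixel scale and a modality tag.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param scale optional microns per pixel (> 0); required for cone density.
#' @param modality free tag, typically "confocal", "splitdetector" or
#'   "unknown".
#' @return An object of class `cone_image` with fields `pixels`, `height`,
#'   `width`, `scale` and `modality`.
#' @export
cone_image <- function(pixels, scale = NULL, modality = "unknown") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels))) stop("image contains non-finite pixels")
  if (!is.null(scale)) {
    if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
      stop("`scale` must be a single positive number (microns per pixel)")
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         scale = scale, modality = as.character(modality)),
    class = "cone_image")
}

#' @export
print.cone_image <- function(x, ...) {
  cat(sprintf("<cone_image> %d x %d px, modality: %s%s\n",
              x$height, x$width, x$modality,
              if (is.null(x$scale)) "" else
                sprintf(", %.4g um/px", x$scale)))
  rng <- range(x$pixels)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

as_cone_image <- function(x) {
  if (inherits(x, "cone_image")) return(x)
  if (is.matrix(x)) return(cone_image(x))
  stop("expected a cone_image or a numeric matrix")
}

#' Read a grayscale image from TIFF or PNG
#'
#' RGB input is converted to luminance by averaging the channels. Pixel
#' values are returned as doubles preserving the file's dynamic range
#' (integer TIFF samples are read as stored; PNG samples are rescaled to
#' 0--255 for 8-bit-equivalent range).
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @inheritParams cone_image
#' @return A [cone_image()].
#' @export
load_image <- function(path, scale = NULL, modality = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    tryCatch(tiff::readTIFF(path, as.is = TRUE),
             error = function(e) stop("unreadable TIFF: ", conditionMessage(e)))
  } else if (ext == "png") {
    tryCatch(png::readPNG(path) * 255,
             error = function(e) stop("unreadable PNG: ", conditionMessage(e)))
  } else stop("unsupported image format: .", ext)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    arr <- apply(arr[, , seq_len(min(nc, 3L)), drop = FALSE], c(1, 2), mean)
  }
  if (!is.matrix(arr) || nrow(arr) == 0L || ncol(arr) == 0L)
    stop("zero-sized or malformed image: ", path)
  cone_image(arr * 1.0, scale = scale, modality = modality)
}

#' Construct a set of marked cone positions
#'
#' @param x,y continuous pixel coordinates (x = column, y = row, 0-based).
#' @param source "manual" or "automatic".
#' @param image optional [cone_image()]; if given, points are checked to lie
#'   inside its bounds.
#' @return A data frame of class `marked_cones` with columns `x`, `y` and a
#'   `source` attribute.
#' @export
marked_cones <- function(x, y, source = c("manual", "automatic"),
                         image = NULL) {
  source <- match.arg(source)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  if (anyDuplicated(cbind(x, y)))
    stop("duplicate cone coordinates are not allowed")
  if (!is.null(image)) {
    image <- as_cone_image(image)
    if (any(x < 0 | x > image$width - 1 | y < 0 | y > image$height - 1))
      stop("cone coordinates outside image bounds")
  }
  structure(data.frame(x = x, y = y),
            source = source, class = c("marked_cones", "data.frame"))
}

#' @export
print.marked_cones <- function(x, ...) {
  cat(sprintf("<marked_cones> %d points (%s)\n", nrow(x), attr(x, "source")))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read cone coordinates from CSV
#'
#' Expects a header `x,y` and one row per cone, coordinates in pixels
#' (0-based, x = column). Sub-pixel coordinates are accepted.
#'
#' @param path CSV file path.
#' @inheritParams marked_cones
#' @return A [marked_cones()] set.
#' @export
load_coordinates <- function(path, source = "manual", image = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("coordinate file must have columns 'x' and 'y': ", path)
  marked_cones(df$x, df$y, source = source, image = image)
}

#' Write cone coordinates to CSV
#'
#' Coordinates are written with 17 significant digits so that a read/write
#' round trip is bit-exact.
#'
#' @param cones a [marked_cones()] set.
#' @param path destination path.
#' @export
save_coordinates <- function(cones, path) {
  stopifnot(inherits(cones, "marked_cones"))
  lines <- c("x,y",
             sprintf("%.17g,%.17g", cones$x, cones$y))
  writeLines(lines, path)
  invisible(path)
}

#' Min--max intensity normalization
#'
#' Linearly stretches intensities so the minimum maps to 0 and the maximum to
#' 255, the scale the classifier is trained on. A constant image (zero
#' dynamic range) maps to all zeros.
#'
#' @param image a [cone_image()] or numeric matrix.
#' @return A [cone_image()] with pixels in \[0, 255\].
#' @export
normalize_intensity <- function(image) {
  image <- as_cone_image(image)
  p <- image$pixels
  rng <- range(p)
  p <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) * 255
       else p * 0
  cone_image(p, scale = image$scale, modality = image$modality)
}
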