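PATCH_SIZE <- 33L
PATCH_HALF <- 16L

#' Construct a labelled patch set
#'
#' @param patches numeric array `33 x 33 x n`.
#' @param labels character vector ("cone"/"noncone"), parallel to patches.
#' @param provenance data frame with one row per patch: `image` id and the
#'   patch centre `x`, `y`.
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(patches, labels, provenance) {
  if (length(dim(patches)) != 3L ||
      dim(patches)[1] != PATCH_SIZE || dim(patches)[2] != PATCH_SIZE)
    stop("patches must be a 33 x 33 x n array")
  n <- dim(patches)[3]
  labels <- as.character(labels)
  if (length(labels) != n || !all(labels %in% c("cone", "noncone")))
    stop("labels must be 'cone'/'noncone', one per patch")
  if (!is.data.frame(provenance) || nrow(provenance) != n)
    stop("provenance must have one row per patch")
  structure(list(patches = patches, labels = labels, provenance = provenance),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%d cone, %d noncone) from %d image(s)\n",
              length(x$labels), sum(x$labels == "cone"),
              sum(x$labels == "noncone"),
              length(unique(x$provenance$image))))
  invisible(x)
}

c_patch_sets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(s) length(s$labels) > 0L, logical(1))]
  if (!length(sets)) stop("no non-empty patch sets to combine")
  patch_set(
    array(unlist(lapply(sets, function(s) s$patches)),
          dim = c(PATCH_SIZE, PATCH_SIZE,
                  sum(vapply(sets, function(s) length(s$labels), integer(1))))),
    unlist(lapply(sets, function(s) s$labels)),
    do.call(rbind, lapply(sets, function(s) s$provenance)))
}

#' Extract 33x33 training patches around given centres
#'
#' The patch around centre (x, y) places the centre pixel at patch index
#' (16, 16) (0-based). Centres whose patch would cross the image border are
#' silently dropped, as in training-set construction.
#'
#' @param image a normalized [cone_image()] (or matrix).
#' @param centers two-column matrix/data frame of integer pixel centres
#'   (`x`, `y`, 0-based); fractional centres are rounded.
#' @param label "cone" or "noncone", applied to all patches.
#' @param image_id id recorded in the provenance.
#' @return A [patch_set()] (possibly with zero patches).
#' @export
extract_patches <- function(image, centers, label = c("cone", "noncone"),
                            image_id = "image") {
  label <- match.arg(label)
  image <- as_cone_image(image)
  centers <- as.matrix(as.data.frame(centers)[, c("x", "y")])
  x <- as.integer(round(centers[, "x"]))
  y <- as.integer(round(centers[, "y"]))
  ok <- x >= PATCH_HALF & x <= image$width - 1L - PATCH_HALF &
        y >= PATCH_HALF & y <= image$height - 1L - PATCH_HALF
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  patches <- array(0, dim = c(PATCH_SIZE, PATCH_SIZE, n))
  for (k in seq_len(n)) {
    patches[, , k] <- image$pixels[(y[k] - PATCH_HALF + 1L):(y[k] + PATCH_HALF + 1L),
                                   (x[k] - PATCH_HALF + 1L):(x[k] + PATCH_HALF + 1L)]
  }
  patch_set(patches, rep(label, n),
            data.frame(image = rep(image_id, n), x = x, y = y,
                       stringsAsFactors = FALSE))
}

#' Build the labelled cone / non-cone training set
#'
#' For every training image: the image is min--max normalized; a cone patch
#' is extracted at every (rounded) manual mark; non-cone patches are
#' extracted at one point sampled uniformly along each Voronoi edge of the
#' marks. Patches crossing the image border are excluded.
#'
#' @param images list of [cone_image()] objects.
#' @param marks parallel list of manual [marked_cones()].
#' @param seed integer seed controlling the edge sampling (bit-reproducible).
#' @param image_ids optional character ids, default `names(images)` or
#'   "img1", "img2", ...
#' @return A [patch_set()] with provenance.
#' @export
build_training_set <- function(images, marks, seed = 0L, image_ids = NULL) {
  stopifnot(length(images) == length(marks), length(images) >= 1L)
  if (is.null(image_ids))
    image_ids <- if (!is.null(names(images))) names(images)
                 else paste0("img", seq_along(images))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sets <- vector("list", 2L * length(images))
  for (k in seq_along(images)) {
    img <- normalize_intensity(images[[k]])
    mk <- marks[[k]]
    if (nrow(mk) < 3L) stop("image ", image_ids[k], " has fewer than 3 marks")
    sets[[2L * k - 1L]] <- extract_patches(img, mk, "cone", image_ids[k])
    ed <- voronoi_edges(mk, img)
    nc <- sample_noncone_points(ed)
    sets[[2L * k]] <- extract_patches(img, as.data.frame(nc), "noncone",
                                      image_ids[k])
  }
  do.call(c_patch_sets, sets)
}
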