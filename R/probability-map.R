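#' Detection post-processing parameters
#'
#' The post-processing triple applied to the probability map: Gaussian
#' smoothing standard deviation `sigma` (pixels), extended-maxima height `h`
#' and cluster probability threshold `t`. Published optima, selected
#' automatically by Dice maximisation over the training images, were
#' (1.3, 0, 0.3) for the confocal network, (2, 0.1, 0.5) for the
#' split-detector network and (0.4, 0.25, 0.9) for the mixed network.
#'
#' @param sigma Gaussian std in pixels, >= 0.
#' @param h extended-maxima height, >= 0.
#' @param t cluster threshold in \[0, 1\].
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(sigma, h, t) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(h), length(h) == 1L, h >= 0,
            is.numeric(t), length(t) == 1L, t >= 0, t <= 1)
  structure(list(sigma = sigma, h = h, t = t), class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf("<detection_params> sigma = %g px, H = %g, T = %g\n",
              x$sigma, x$h, x$t))
  invisible(x)
}

#' Attach detection parameters to a fitted network
#' @param net a `cone_cnn` object.
#' @param params a [detection_params()].
#' @return The network with `detection_params` set.
#' @export
set_detection_params <- function(net, params) {
  stopifnot(inherits(net, "cone_cnn"), inherits(params, "detection_params"))
  net$detection_params <- params
  net
}

# half-sample symmetric (edge-duplicating) mirror pad by `half` pixels
mirror_pad <- function(pixels, half = PATCH_HALF) {
  H <- nrow(pixels); W <- ncol(pixels)
  stopifnot(H >= half, W >= half)
  ridx <- c(half:1, 1:H, H:(H - half + 1L))
  cidx <- c(half:1, 1:W, W:(W - half + 1L))
  pixels[ridx, cidx]
}

# Fold inference-mode batch norm (an affine map per channel) into the
# preceding convolution / FC weights, and reshape conv kernels to im2col
# layout for the whole-image inference kernel.
fold_inference_params <- function(par, eps) {
  sc <- function(i) par[[paste0("bn", i, "_g")]] /
    sqrt(par[[paste0("bn", i, "_rv")]] + eps)
  sh <- function(i, s, b) s * (b - par[[paste0("bn", i, "_rm")]]) +
    par[[paste0("bn", i, "_b")]]
  s1 <- sc(1); s2 <- sc(2); s3 <- sc(3); s4 <- sc(4)
  list(w1 = sweep(matrix(par$conv1_w, 25L, 32L), 2L, s1, "*"),
       b1 = sh(1, s1, par$conv1_b),
       w2 = sweep(matrix(par$conv2_w, 800L, 32L), 2L, s2, "*"),
       b2 = sh(2, s2, par$conv2_b),
       w3 = sweep(matrix(par$conv3_w, 800L, 64L), 2L, s3, "*"),
       b3 = sh(3, s3, par$conv3_b),
       fw1 = par$fc1_w * s4,
       fb1 = sh(4, s4, par$fc1_b),
       fw2 = par$fc2_w, fb2 = par$fc2_b)
}

#' Per-pixel cone probability map
#'
#' Classifies the 33x33 patch centred at every pixel of the image and
#' assembles the "cone" probabilities into a map with the same dimensions as
#' the image. Patches that extend beyond the image are completed by
#' mirroring the pixel values at the edge by half the patch length
#' (16 pixels). The image must already be on the normalized 0--255 scale
#' (see [normalize_intensity()]).
#'
#' @param net a trained [cone_cnn()].
#' @param image a normalized [cone_image()] or matrix.
#' @param batch_size pixels classified per forward pass (affects speed and
#'   memory only; results agree within 1e-6 regardless).
#' @return Numeric matrix in \[0, 1\], same dimensions as the image.
#' @export
compute_probability_map <- function(net, image, batch_size = 128L) {
  stopifnot(inherits(net, "cone_cnn"))
  image <- as_cone_image(image)
  H <- image$height; W <- image$width
  if (H < 1L || W < 1L) stop("empty image")
  padded <- mirror_pad(image$pixels)
  fp <- fold_inference_params(net$par, net$config$bn_eps)
  infer_probmap(padded, fp, as.integer(batch_size))
}

#' Gaussian smoothing of a probability map
#'
#' Separable Gaussian filter with kernel truncated at 4 sigma and reflective
#' (edge-duplicating) boundary handling; `sigma = 0` is the identity.
#'
#' @param map numeric matrix.
#' @param sigma standard deviation in pixels, >= 0.
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth_map <- function(map, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  gaussian_blur(as.matrix(map), sigma)
}

#' Extended-maxima transform
#'
#' Regional maxima of the H-maxima transform: the map minus `h` is
#' morphologically reconstructed under the map (geodesic dilation to
#' stability, 8-connectivity), and the regional maxima of the result are
#' returned. This suppresses maxima whose height above their surroundings is
#' at most `h`; `h = 0` reduces to plain regional maxima. Semantics match
#' MATLAB's `imextendedmax`.
#'
#' @param map numeric matrix.
#' @param h maxima height, >= 0.
#' @return Logical matrix marking the extended maxima.
#' @export
extended_maxima <- function(map, h) {
  if (!is.numeric(h) || length(h) != 1L || h < 0)
    stop("`h` must be a single non-negative number")
  map <- as.matrix(map)
  hm <- if (h == 0) map else grey_reconstruct(map - h, map)
  regional_maxima(hm)
}

#' Cone localization from the extended-maxima mask
#'
#' Labels the 8-connected clusters of the binary mask, removes clusters
#' whose maximum value in the smoothed probability map is below the
#' threshold `t`, and returns one cone per surviving cluster at the
#' unweighted centroid of its pixels (optionally weighted by the smoothed
#' probability).
#'
#' @param mask logical matrix from [extended_maxima()].
#' @param smoothed smoothed probability map, same dimensions.
#' @param t cluster threshold in \[0, 1\].
#' @param weighted if TRUE, centroids are probability-weighted.
#' @return A [marked_cones()] set with `source = "automatic"` (possibly
#'   empty).
#' @export
localize_cones <- function(mask, smoothed, t, weighted = FALSE) {
  smoothed <- as.matrix(smoothed)
  stopifnot(identical(dim(mask), dim(smoothed)))
  lab <- label_components(mask)
  nl <- max(lab)
  if (nl == 0L) return(marked_cones(numeric(0), numeric(0), "automatic"))
  sel <- lab > 0L
  li <- lab[sel]
  rows <- row(lab)[sel] - 1L   # 0-based y
  cols <- col(lab)[sel] - 1L   # 0-based x
  vals <- smoothed[sel]
  keep <- vapply(split(vals, li), max, numeric(1)) >= t
  w <- if (weighted) vals else rep(1, length(vals))
  sw <- rowsum(w, li)           # rows ordered by label 1..nl
  cx <- rowsum(cols * w, li) / sw
  cy <- rowsum(rows * w, li) / sw
  marked_cones(cx[keep], cy[keep], "automatic")
}

#' Detect cones in an AOSLO image
#'
#' End-to-end detection: min--max normalization, per-pixel probability map
#' from the trained network, Gaussian smoothing with `params$sigma`,
#' extended-maxima transform with height `params$h`, and cluster filtering
#' at threshold `params$t` with centroid extraction.
#'
#' @param image a [cone_image()] or matrix (raw intensities; normalization
#'   is applied internally).
#' @param net a trained [cone_cnn()].
#' @param params a [detection_params()]; defaults to the parameters attached
#'   to the network.
#' @param batch_size see [compute_probability_map()].
#' @param weighted see [localize_cones()].
#' @return A [marked_cones()] set (`source = "automatic"`).
#' @export
detect_cones <- function(image, net, params = net$detection_params,
                         batch_size = 128L, weighted = FALSE) {
  if (is.null(params))
    stop("no detection parameters: pass `params` or run optimize_params()")
  stopifnot(inherits(params, "detection_params"))
  image <- normalize_intensity(image)
  map <- compute_probability_map(net, image, batch_size = batch_size)
  sm <- smooth_map(map, params$sigma)
  mask <- extended_maxima(sm, params$h)
  localize_cones(mask, sm, params$t, weighted = weighted)
}
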