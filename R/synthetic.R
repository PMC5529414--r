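#' Parameters for the synthetic cone-mosaic generator
#'
#' Describes a jittered hexagonal cone mosaic rendered in either confocal
#' (bright isotropic Gaussian blobs) or split-detector (horizontal
#' bright/dark dipole) appearance, with additive Gaussian noise and a
#' slowly varying background. Defaults emulate a 150 x 150 px AOSLO region
#' containing roughly 100 cones.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param lattice_constant target cone spacing in pixels.
#' @param jitter_sd Gaussian positional jitter SD in pixels
#'   (< lattice_constant / 2).
#' @param modality "confocal" or "splitdetector".
#' @param cone_amplitude mean cone peak amplitude (arbitrary intensity
#'   units).
#' @param cone_amplitude_sd per-cone amplitude SD.
#' @param cone_sigma Gaussian radius parameter of a cone profile in pixels.
#' @param cone_sigma_sd per-cone SD of `cone_sigma`.
#' @param background constant background level.
#' @param background_lf amplitude of the slowly varying background field.
#' @param noise_sd additive Gaussian noise SD.
#' @param dropout fraction of lattice sites randomly left empty, in \[0, 1).
#' @param scale microns per pixel recorded on the image (for density).
#' @param seed RNG seed; generation is bit-reproducible.
#' @return A list of class `mosaic_params`.
#' @export
mosaic_params <- function(image_size = c(150L, 150L), lattice_constant = 14,
                          jitter_sd = 1, modality = c("confocal",
                                                      "splitdetector"),
                          cone_amplitude = 150, cone_amplitude_sd = 20,
                          cone_sigma = 2.2, cone_sigma_sd = 0.2,
                          background = 30, background_lf = 10, noise_sd = 8,
                          dropout = 0.1, scale = 0.45, seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(length(image_size) == 2L, all(image_size >= 33L),
            lattice_constant > 2 * 2 * cone_sigma,   # spacing > cone diameter
            jitter_sd >= 0, jitter_sd < lattice_constant / 2,
            cone_amplitude > 0, cone_sigma > 0, noise_sd >= 0,
            dropout >= 0, dropout < 1, scale > 0)
  structure(list(image_size = as.integer(image_size),
                 lattice_constant = lattice_constant, jitter_sd = jitter_sd,
                 modality = modality, cone_amplitude = cone_amplitude,
                 cone_amplitude_sd = cone_amplitude_sd,
                 cone_sigma = cone_sigma, cone_sigma_sd = cone_sigma_sd,
                 background = background, background_lf = background_lf,
                 noise_sd = noise_sd, dropout = dropout, scale = scale,
                 seed = as.integer(seed)),
            class = "mosaic_params")
}

#' Generate a synthetic cone mosaic with ground truth
#'
#' Cone centres sit on a hexagonal (triangular) lattice with random phase,
#' i.i.d. Gaussian jitter and random dropout, keeping a margin so every
#' rendered cone lies fully inside the image. Confocal rendering sums
#' isotropic Gaussian blobs; split-detector rendering sums horizontal
#' first-derivative-of-Gaussian dipoles (bright left lobe, dark right lobe)
#' whose zero crossing marks the cone centre. A constant background, a
#' smooth low-frequency field and white Gaussian noise are added. The
#' returned ground truth holds the exact (sub-pixel) jittered centres.
#'
#' @param params a [mosaic_params()].
#' @return A list with `image` (a [cone_image()]), `cones` (ground-truth
#'   [marked_cones()], `source = "manual"`) and `params`.
#' @export
generate_mosaic <- function(params = mosaic_params()) {
  stopifnot(inherits(params, "mosaic_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  H <- params$image_size[1]; W <- params$image_size[2]
  a <- params$lattice_constant
  margin <- 2 * params$cone_sigma + 1
  ry <- a * sqrt(3) / 2                      # row spacing
  x0 <- runif(1, 0, a); y0 <- runif(1, 0, ry)
  rows <- seq(-1L, ceiling(H / ry) + 1L)
  pts <- do.call(rbind, lapply(rows, function(i) {
    xs <- seq(-1, ceiling(W / a) + 1) * a + x0 + (i %% 2) * a / 2
    cbind(x = xs, y = y0 + i * ry)
  }))
  pts[, "x"] <- pts[, "x"] + rnorm(nrow(pts), sd = params$jitter_sd)
  pts[, "y"] <- pts[, "y"] + rnorm(nrow(pts), sd = params$jitter_sd)
  keep <- runif(nrow(pts)) >= params$dropout
  inb <- pts[, "x"] >= margin & pts[, "x"] <= W - 1 - margin &
         pts[, "y"] >= margin & pts[, "y"] <= H - 1 - margin
  pts <- pts[keep & inb, , drop = FALSE]
  n <- nrow(pts)
  amp <- pmax(rnorm(n, params$cone_amplitude, params$cone_amplitude_sd),
              params$cone_amplitude / 4)
  csig <- pmax(rnorm(n, params$cone_sigma, params$cone_sigma_sd),
               params$cone_sigma / 2)
  img <- matrix(params$background, H, W)
  # low-frequency background: a few random long-wavelength sinusoids
  if (params$background_lf > 0) {
    xg <- matrix(0:(W - 1), H, W, byrow = TRUE)
    yg <- matrix(0:(H - 1), H, W)
    for (k in 1:3) {
      th <- runif(1, 0, 2 * pi)
      wl <- runif(1, 0.5, 1.5) * max(H, W)
      ph <- runif(1, 0, 2 * pi)
      img <- img + params$background_lf / 3 *
        sin(2 * pi * (cos(th) * xg + sin(th) * yg) / wl + ph)
    }
  }
  # render each cone over a local window
  for (k in seq_len(n)) {
    s <- csig[k]
    r <- ceiling(4 * s)
    xc <- pts[k, "x"]; yc <- pts[k, "y"]
    cx <- max(0L, floor(xc) - r):min(W - 1L, ceiling(xc) + r)
    cy <- max(0L, floor(yc) - r):min(H - 1L, ceiling(yc) + r)
    dx <- outer(rep(1, length(cy)), cx - xc)
    dy <- outer(cy - yc, rep(1, length(cx)))
    g <- exp(-(dx^2 + dy^2) / (2 * s^2))
    blob <- if (params$modality == "confocal") amp[k] * g
            else amp[k] * (-dx / s) * g       # bright left, dark right
    img[cy + 1L, cx + 1L] <- img[cy + 1L, cx + 1L] + blob
  }
  if (params$noise_sd > 0)
    img <- img + matrix(rnorm(H * W, sd = params$noise_sd), H, W)
  image <- cone_image(img, scale = params$scale,
                      modality = params$modality)
  cones <- marked_cones(pts[, "x"], pts[, "y"], "manual", image = image)
  list(image = image, cones = cones, params = params)
}

#' Generate a train/validation fixture suite of mosaics
#'
#' Builds `n_train` training and `n_val` validation mosaics for one modality
#' with disjoint per-image seeds derived from `seed`, so every other module
#' of the package can be exercised end-to-end without real data.
#'
#' @param seed base integer seed.
#' @param modality "confocal" or "splitdetector".
#' @param n_train,n_val number of training / validation images.
#' @param base a [mosaic_params()] supplying everything except the per-image
#'   seed.
#' @return A list with `train` and `val`, each a list of
#'   [generate_mosaic()] results.
#' @export
make_fixture_suite <- function(seed = 1L, modality = "confocal",
                               n_train = 20L, n_val = 10L,
                               base = mosaic_params(modality = modality)) {
  seeds <- (as.integer(seed) %% 1000000L) * 1000L + seq_len(n_train + n_val)
  make1 <- function(s) {
    p <- base
    p$seed <- as.integer(s)
    generate_mosaic(p)
  }
  list(train = lapply(seeds[seq_len(n_train)], make1),
       val = lapply(seeds[n_train + seq_len(n_val)], make1))
}
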