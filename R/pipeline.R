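# End-to-end orchestration over in-memory image/mark lists. Each stage is a
# plain function so scripted runs and the bundled CLI share one code path.

#' Train a network from marked images
#'
#' Builds the labelled patch set (cone patches at the manual marks, non-cone
#' patches from Voronoi-edge samples) and fits the classifier.
#'
#' @param images list of [cone_image()] objects.
#' @param marks parallel list of manual [marked_cones()].
#' @param config a [cnn_config()].
#' @param out_dir optional directory; when given the bundle is written there
#'   with [save_model()].
#' @param verbose per-epoch training log.
#' @return A trained `cone_cnn`.
#' @export
run_train <- function(images, marks, config = cnn_config(), out_dir = NULL,
                      verbose = FALSE) {
  patches <- build_training_set(images, marks, seed = config$seed)
  net <- cone_cnn(patches, config, verbose = verbose)
  if (!is.null(out_dir)) save_model(net, out_dir)
  net
}

#' Tune detection parameters on training images
#'
#' Computes probability maps for the selected training images and picks
#' (sigma, H, T) by mean-Dice maximisation over the grid. The chosen
#' parameters are attached to the returned network.
#'
#' @param net a trained `cone_cnn` (error if untrained: run the training
#'   stage first).
#' @param images,marks training images and manual marks.
#' @param grid a [param_grid()].
#' @param n_images number of training images to compute probability maps
#'   for (maps dominate tuning cost; the grid search itself is exhaustive).
#' @param border,radius_factor matching settings, see [optimize_params()].
#' @param batch_size see [compute_probability_map()].
#' @return The network with `detection_params` set; the full score table is
#'   attached as attribute `"tuning"`.
#' @export
run_tune <- function(net, images, marks, grid = param_grid(),
                     n_images = length(images), border = 7,
                     radius_factor = 0.75, batch_size = 128L) {
  if (!inherits(net, "cone_cnn") || !isTRUE(net$trained))
    stop("tuning requires a trained network: run run_train() first")
  take <- seq_len(min(n_images, length(images)))
  maps <- lapply(take, function(k)
    compute_probability_map(net, normalize_intensity(images[[k]]),
                            batch_size = batch_size))
  opt <- optimize_params(maps, marks[take], grid, border = border,
                         radius_factor = radius_factor)
  net <- set_detection_params(net, opt$params)
  attr(net, "tuning") <- opt
  net
}

#' Detect cones in a list of images
#'
#' @param net a trained `cone_cnn` with detection parameters attached
#'   (error otherwise: run the tuning stage first).
#' @param images list of [cone_image()] objects (raw intensities).
#' @param out_dir optional; when given, one `*_cones.csv` per image is
#'   written there.
#' @param batch_size see [compute_probability_map()].
#' @return List of [marked_cones()] detections.
#' @export
run_detect <- function(net, images, out_dir = NULL, batch_size = 128L) {
  if (!inherits(net, "cone_cnn") || !isTRUE(net$trained))
    stop("detection requires a trained network: run run_train() first")
  if (is.null(net$detection_params))
    stop("no detection parameters attached: run run_tune() first")
  dets <- lapply(images, detect_cones, net = net,
                 batch_size = batch_size)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ids <- if (!is.null(names(images))) names(images)
           else sprintf("image%03d", seq_along(images))
    for (k in seq_along(dets))
      save_coordinates(dets[[k]],
                       file.path(out_dir, paste0(ids[k], "_cones.csv")))
  }
  dets
}

#' Score detections against manual marks
#'
#' Per-image one-to-one matching and metrics, plus summary rows (mean, SD,
#' median) and a Bland--Altman analysis of manual minus automatic cone
#' density when the images carry a scale.
#'
#' @param detections list of automatic [marked_cones()].
#' @param marks parallel list of manual [marked_cones()].
#' @param images parallel list of [cone_image()] objects.
#' @param border edge exclusion in pixels.
#' @param radius_factor multiple of the median spacing for the match radius.
#' @return A list with `per_image` (data frame), `summary` (data frame of
#'   mean/sd/median per metric) and `bland_altman` (or NULL without scale).
#' @export
run_evaluate <- function(detections, marks, images, border = 7,
                         radius_factor = 0.75) {
  stopifnot(length(detections) == length(marks),
            length(marks) == length(images))
  rows <- lapply(seq_along(images), function(k) {
    d <- match_radius(marks[[k]], factor = radius_factor)
    mr <- match_cones(detections[[k]], marks[[k]], d,
                      image = images[[k]], border = border)
    met <- compute_metrics(mr)
    has_scale <- !is.null(as_cone_image(images[[k]])$scale)
    data.frame(image = k, d = d, n_tp = met$n_tp, n_fp = met$n_fp,
               n_fn = met$n_fn,
               true_positive_rate = met$true_positive_rate,
               false_discovery_rate = met$false_discovery_rate,
               dice = met$dice,
               density_manual = if (has_scale)
                 cone_density(marks[[k]], images[[k]]) else NA_real_,
               density_auto = if (has_scale)
                 cone_density(detections[[k]], images[[k]]) else NA_real_)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- c("true_positive_rate", "false_discovery_rate", "dice")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(per_image[metric_cols], mean, numeric(1)),
    sd = vapply(per_image[metric_cols], sd, numeric(1)),
    median = vapply(per_image[metric_cols], median, numeric(1)),
    row.names = NULL)
  ba <- NULL
  if (all(is.finite(per_image$density_manual)) && nrow(per_image) >= 2L)
    ba <- bland_altman(per_image$density_manual - per_image$density_auto)
  list(per_image = per_image, summary = summary, bland_altman = ba)
}

#' Run the full pipeline on a fixture suite
#'
#' Train on the suite's training images, tune (sigma, H, T), detect on the
#' validation images and score against the ground truth.
#'
#' @param suite a [make_fixture_suite()] result (or any list with `train`
#'   and `val` lists of `image`/`cones` pairs).
#' @param config a [cnn_config()].
#' @param grid a [param_grid()].
#' @param tune_n training images used for tuning probability maps.
#' @param border evaluation edge exclusion.
#' @param verbose per-epoch training log.
#' @return A list with `net` (tuned network), `detections` and `evaluation`
#'   (from [run_evaluate()]).
#' @export
run_pipeline <- function(suite, config = cnn_config(), grid = param_grid(),
                         tune_n = 4L, border = 7, verbose = FALSE) {
  tr_imgs <- lapply(suite$train, `[[`, "image")
  tr_marks <- lapply(suite$train, `[[`, "cones")
  net <- run_train(tr_imgs, tr_marks, config, verbose = verbose)
  net <- run_tune(net, tr_imgs, tr_marks, grid, n_images = tune_n,
                  border = border)
  val_imgs <- lapply(suite$val, `[[`, "image")
  val_marks <- lapply(suite$val, `[[`, "cones")
  dets <- run_detect(net, val_imgs)
  list(net = net, detections = dets,
       evaluation = run_evaluate(dets, val_marks, val_imgs, border = border))
}
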