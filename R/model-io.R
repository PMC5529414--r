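#' Save a trained network bundle
#'
#' Writes a directory with two JSON files: `metadata.json` (training config,
#' class order, normalization convention, layer shape table, detection
#' parameters if attached, training history) and `weights.json` (every
#' parameter array at full double precision). JSON keeps the bundle
#' diff-able and language-portable.
#'
#' @param net a `cone_cnn` object.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(net, dir) {
  stopifnot(inherits(net, "cone_cnn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "conefinder", format = 1L,
               classes = net$classes,
               normalization = net$normalization,
               trained = net$trained,
               config = unclass(net$config),
               param_shapes = CNN_PARAM_SHAPES,
               detection_params =
                 if (!is.null(net$detection_params))
                   unclass(net$detection_params),
               history = net$history)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  weights <- lapply(net$par, function(p) {
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         data = as.numeric(p))
  })
  jsonlite::write_json(weights, file.path(dir, "weights.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' Load a network bundle
#'
#' Reads a bundle written by [save_model()] and validates every parameter
#' shape against the architecture before returning; a mismatch raises an
#' error naming the offending layer.
#'
#' @param dir bundle directory.
#' @return A `cone_cnn` object.
#' @export
load_model <- function(dir) {
  mpath <- file.path(dir, "metadata.json")
  wpath <- file.path(dir, "weights.json")
  if (!file.exists(mpath) || !file.exists(wpath))
    stop("not a model bundle (missing metadata.json/weights.json): ", dir)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  weights <- jsonlite::read_json(wpath, simplifyVector = TRUE)
  par <- list()
  for (nm in names(CNN_PARAM_SHAPES)) {
    expect <- CNN_PARAM_SHAPES[[nm]]
    w <- weights[[nm]]
    if (is.null(w)) stop("bundle is missing parameter ", nm)
    got <- as.integer(unlist(w$dim))
    if (!identical(got, as.integer(expect)))
      stop(sprintf("parameter %s has shape (%s), expected (%s)",
                   nm, paste(got, collapse = "x"),
                   paste(expect, collapse = "x")))
    vals <- as.numeric(unlist(w$data))
    if (length(vals) != prod(expect))
      stop("parameter ", nm, " has the wrong number of values")
    par[[nm]] <- if (length(expect) > 1L) array(vals, dim = expect) else vals
  }
  cfgl <- meta$config
  cfg <- cnn_config(epochs = cfgl$epochs, minibatch_size = cfgl$minibatch_size,
                    lr_w = cfgl$lr_w, lr_w_final = cfgl$lr_w_final,
                    lr_b = cfgl$lr_b, lr_b_final = cfgl$lr_b_final,
                    lr_drop_epochs = unlist(cfgl$lr_drop_epochs),
                    lr_drop_factor = cfgl$lr_drop_factor,
                    weight_decay = cfgl$weight_decay,
                    momentum = cfgl$momentum, init_sd = cfgl$init_sd,
                    bn_eps = cfgl$bn_eps, bn_momentum = cfgl$bn_momentum,
                    seed = cfgl$seed)
  dp <- NULL
  if (!is.null(meta$detection_params))
    dp <- detection_params(meta$detection_params$sigma,
                           meta$detection_params$h,
                           meta$detection_params$t)
  structure(list(par = par, config = cfg,
                 classes = unlist(meta$classes),
                 trained = isTRUE(meta$trained),
                 history = if (!is.null(meta$history))
                   as.data.frame(meta$history),
                 detection_params = dp,
                 normalization = meta$normalization),
            class = "cone_cnn")
}
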