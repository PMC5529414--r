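#' Candidate grid for the detection parameters
#'
#' Default grid: sigma 0 to 3 px in steps of 0.1, H 0 to 0.5 in steps of
#' 0.05, T 0.1 to 0.9 in steps of 0.1. Values are built by integer division
#' so the published optima (1.3, 0, 0.3), (2, 0.1, 0.5) and (0.4, 0.25,
#' 0.9) are exact grid points.
#'
#' @param sigma,h,t numeric candidate vectors.
#' @return A data frame of class `param_grid` with columns `sigma`, `h`,
#'   `t`, one row per combination (t varies fastest, then h, then sigma).
#' @export
param_grid <- function(sigma = (0:30) / 10, h = (0:10) / 20, t = (1:9) / 10) {
  stopifnot(length(sigma) > 0, length(h) > 0, length(t) > 0,
            all(sigma >= 0), all(h >= 0), all(t >= 0 & t <= 1))
  g <- expand.grid(t = t, h = h, sigma = sigma,
                   KEEP.OUT.ATTRS = FALSE)[, c("sigma", "h", "t")]
  rownames(g) <- NULL
  class(g) <- c("param_grid", "data.frame")
  g
}

# detections for every (h, t) of one smoothed map, reusing the cluster
# decomposition: the extended-maxima mask depends only on h, and t merely
# deselects clusters by their maximum smoothed probability
detect_from_smoothed <- function(sm, h_values, t_values, weighted = FALSE) {
  out <- vector("list", length(h_values))
  names(out) <- as.character(h_values)
  for (hi in seq_along(h_values)) {
    mask <- extended_maxima(sm, h_values[hi])
    lab <- label_components(mask)
    nl <- max(lab)
    if (nl == 0L) {
      empty <- marked_cones(numeric(0), numeric(0), "automatic")
      out[[hi]] <- lapply(t_values, function(t) empty)
      names(out[[hi]]) <- as.character(t_values)
      next
    }
    sel <- lab > 0L
    li <- lab[sel]
    vals <- sm[sel]
    w <- if (weighted) vals else rep(1, length(vals))
    sw <- rowsum(w, li)
    cx <- rowsum((col(lab)[sel] - 1) * w, li) / sw
    cy <- rowsum((row(lab)[sel] - 1) * w, li) / sw
    mx <- vapply(split(vals, li), max, numeric(1))
    out[[hi]] <- lapply(t_values, function(t)
      marked_cones(cx[mx >= t], cy[mx >= t], "automatic"))
    names(out[[hi]]) <- as.character(t_values)
  }
  out
}

#' Select detection parameters by Dice maximisation
#'
#' Exhaustively evaluates every (sigma, H, T) grid point: each training
#' image's precomputed probability map is smoothed, the extended-maxima
#' clusters are located and filtered, and the detections are matched
#' one-to-one against the manual marks (border pruning and match radius as
#' in [match_cones()]). The grid point with the highest mean per-image
#' Dice's coefficient wins; ties are broken towards the smallest sigma, then
#' smallest H, then largest T.
#'
#' @param probmaps list of probability maps (matrices), one per training
#'   image, from [compute_probability_map()].
#' @param manual parallel list of manual [marked_cones()].
#' @param grid a [param_grid()].
#' @param border edge exclusion in pixels for the matching (default 7).
#' @param radius_factor multiple of median spacing for the match radius.
#' @param weighted probability-weighted centroids (default FALSE).
#' @return A list with `params` (the winning [detection_params()]), `dice`
#'   (its mean Dice) and `table` (the full score table, one row per grid
#'   point).
#' @export
optimize_params <- function(probmaps, manual, grid = param_grid(),
                            border = 7, radius_factor = 0.75,
                            weighted = FALSE) {
  stopifnot(length(probmaps) == length(manual), length(probmaps) >= 1L)
  if (!nrow(grid)) stop("empty parameter grid")
  sig_v <- sort(unique(grid$sigma))
  h_v <- sort(unique(grid$h))
  t_v <- sort(unique(grid$t))
  full <- nrow(grid) == length(sig_v) * length(h_v) * length(t_v)
  d_all <- vapply(manual, match_radius, numeric(1), factor = radius_factor)
  dice_sum <- array(0, c(length(sig_v), length(h_v), length(t_v)))
  for (k in seq_along(probmaps)) {
    pm <- as.matrix(probmaps[[k]])
    dims <- dim(pm)
    for (si in seq_along(sig_v)) {
      sm <- smooth_map(pm, sig_v[si])
      dets <- detect_from_smoothed(sm, h_v, t_v, weighted = weighted)
      for (hi in seq_along(h_v))
        for (ti in seq_along(t_v)) {
          mr <- match_cones(dets[[hi]][[ti]], manual[[k]], d_all[k],
                            image = dims, border = border)
          dice <- compute_metrics(mr)$dice
          dice_sum[si, hi, ti] <- dice_sum[si, hi, ti] +
            if (is.na(dice)) 0 else dice
        }
    }
  }
  tab <- expand.grid(sigma = sig_v, h = h_v, t = t_v,
                     KEEP.OUT.ATTRS = FALSE)
  tab$mean_dice <- as.vector(dice_sum) / length(probmaps)
  if (!full) {
    key <- paste(tab$sigma, tab$h, tab$t)
    tab <- tab[key %in% paste(grid$sigma, grid$h, grid$t), , drop = FALSE]
  }
  # best score; ties -> smallest sigma, then smallest h, then largest t
  ord <- order(-tab$mean_dice, tab$sigma, tab$h, -tab$t)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab[1L, ]
  list(params = detection_params(best$sigma, best$h, best$t),
       dice = best$mean_dice, table = tab)
}
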