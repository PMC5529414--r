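#' Match radius from the manual cone spacing
#'
#' The matching radius is 0.75 times the median spacing of the manual marks,
#' where spacing is the median over cones of the Euclidean distance to the
#' nearest neighbouring manual cone (the standard mosaic spacing statistic).
#'
#' @param manual a [marked_cones()] set with at least 2 points.
#' @param factor multiple of the median spacing (default 0.75).
#' @return Match radius `d` in pixels.
#' @export
match_radius <- function(manual, factor = 0.75) {
  if (nrow(manual) < 2L)
    stop("need at least 2 manual cones to estimate spacing")
  dm <- as.matrix(stats::dist(cbind(manual$x, manual$y)))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  factor * median(nn)
}

prune_border <- function(pts, dims, border) {
  if (border <= 0 || nrow(pts) == 0L) return(seq_len(nrow(pts)))
  H <- dims[1]; W <- dims[2]
  which(pts$x >= border & pts$x <= W - 1 - border &
        pts$y >= border & pts$y <= H - 1 - border)
}

#' One-to-one matching of automatic to manual cones
#'
#' Points within `border` pixels of any image edge are removed from both
#' sets first. Candidate pairs closer than the match radius `d` are then
#' accepted greedily in ascending distance order, each cone used at most
#' once, so that when several automatic cones fall within `d` of one manual
#' cone only the closest becomes the true positive. Remaining automatic
#' cones are false positives, remaining manual cones false negatives.
#'
#' @param auto,manual [marked_cones()] sets.
#' @param d match radius in pixels (> 0), typically from [match_radius()].
#' @param image a [cone_image()] or `c(height, width)`; needed when
#'   `border > 0`.
#' @param border edge exclusion zone in pixels (default 7).
#' @return A list of class `match_result`: `pairs` (data frame `auto`,
#'   `manual`, `distance`, indices into the pruned sets), `unmatched_auto`,
#'   `unmatched_manual`, counts `n_tp`, `n_fp`, `n_fn`, `n_auto`,
#'   `n_manual`, plus `d`, `border` and the pruned point sets.
#' @export
match_cones <- function(auto, manual, d, image = NULL, border = 7) {
  stopifnot(is.numeric(d), length(d) == 1L, d > 0)
  if (border > 0 && is.null(image))
    stop("`image` (or its dimensions) is required for border pruning")
  dims <- if (inherits(image, "cone_image")) c(image$height, image$width)
          else if (!is.null(image)) as.numeric(image)
  if (border > 0) {
    auto <- auto[prune_border(auto, dims, border), , drop = FALSE]
    manual <- manual[prune_border(manual, dims, border), , drop = FALSE]
  }
  na <- nrow(auto); nm <- nrow(manual)
  pairs <- data.frame(auto = integer(), manual = integer(),
                      distance = numeric())
  if (na > 0L && nm > 0L) {
    dx <- outer(auto$x, manual$x, "-")
    dy <- outer(auto$y, manual$y, "-")
    dd <- sqrt(dx^2 + dy^2)
    cand <- which(dd <= d, arr.ind = TRUE)
    if (nrow(cand)) {
      dists <- dd[cand]
      # ascending distance; exact ties broken by manual index, then auto
      ord <- order(dists, cand[, 2L], cand[, 1L])
      used_a <- logical(na); used_m <- logical(nm)
      keep <- integer(0)
      for (k in ord) {
        a <- cand[k, 1L]; m <- cand[k, 2L]
        if (!used_a[a] && !used_m[m]) {
          used_a[a] <- TRUE; used_m[m] <- TRUE
          keep <- c(keep, k)
        }
      }
      pairs <- data.frame(auto = cand[keep, 1L], manual = cand[keep, 2L],
                          distance = dists[keep])
    }
  }
  structure(list(pairs = pairs,
                 unmatched_auto = setdiff(seq_len(na), pairs$auto),
                 unmatched_manual = setdiff(seq_len(nm), pairs$manual),
                 n_tp = nrow(pairs),
                 n_fp = na - nrow(pairs),
                 n_fn = nm - nrow(pairs),
                 n_auto = na, n_manual = nm,
                 d = d, border = border,
                 auto = auto, manual = manual),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d, FP %d, FN %d (auto %d, manual %d, d = %.3g px)\n",
    x$n_tp, x$n_fp, x$n_fn, x$n_auto, x$n_manual, x$d))
  invisible(x)
}

#' Detection performance metrics
#'
#' True positive rate `TP / N_manual`, false discovery rate
#' `FP / N_automatic` and Dice's coefficient
#' `2 TP / (N_manual + N_automatic)`. A metric whose denominator is zero is
#' returned as `NA` rather than silently coerced to 0.
#'
#' @param match a [match_cones()] result.
#' @return A list of class `metrics_record` with `true_positive_rate`,
#'   `false_discovery_rate`, `dice` and the underlying counts.
#' @export
compute_metrics <- function(match) {
  stopifnot(inherits(match, "match_result"))
  tpr <- if (match$n_manual > 0L) match$n_tp / match$n_manual else NA_real_
  fdr <- if (match$n_auto > 0L) match$n_fp / match$n_auto else NA_real_
  denom <- match$n_manual + match$n_auto
  dice <- if (denom > 0L) 2 * match$n_tp / denom else NA_real_
  structure(list(true_positive_rate = tpr, false_discovery_rate = fdr,
                 dice = dice, n_tp = match$n_tp, n_fp = match$n_fp,
                 n_fn = match$n_fn, n_auto = match$n_auto,
                 n_manual = match$n_manual),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics> TPR %.4f  FDR %.4f  Dice %.4f\n",
              x$true_positive_rate, x$false_discovery_rate, x$dice))
  invisible(x)
}

#' Cone density in cones per square millimetre
#'
#' Density is the cone count divided by the image area, which requires the
#' image's micron-per-pixel scale. By default no border exclusion is
#' applied; set `border` to prune cones near the edges (the full pixel area
#' is still used unless `prune_area` is set).
#'
#' @param cones a [marked_cones()] set.
#' @param image a [cone_image()] with a `scale`.
#' @param border edge exclusion for the count, in pixels (default 0).
#' @param prune_area if TRUE the area is shrunk to the retained region.
#' @return Density in cones/mm^2.
#' @export
cone_density <- function(cones, image, border = 0, prune_area = FALSE) {
  image <- as_cone_image(image)
  if (is.null(image$scale))
    stop("image has no micron-per-pixel scale; density is undefined")
  n <- length(prune_border(cones, c(image$height, image$width), border))
  hpx <- image$height - if (prune_area) 2 * border else 0
  wpx <- image$width - if (prune_area) 2 * border else 0
  area_mm2 <- (hpx * image$scale) * (wpx * image$scale) / 1e6
  if (area_mm2 <= 0) stop("non-positive image area")
  n / area_mm2
}

#' Bland--Altman limits of agreement
#'
#' Mean difference and 95% limits of agreement (mean +/- 1.96 sample SD) for
#' paired per-image differences, e.g. manual minus automatic cone density.
#'
#' @param differences numeric vector of per-image differences (length >= 2).
#' @return A list of class `bland_altman` with `mean_difference`, `sd`,
#'   `lower`, `upper` and `n`.
#' @export
bland_altman <- function(differences) {
  differences <- as.numeric(differences)
  if (length(differences) < 2L || any(!is.finite(differences)))
    stop("need >= 2 finite differences")
  m <- mean(differences)
  s <- sd(differences)
  structure(list(mean_difference = m, sd = s,
                 lower = m - 1.96 * s, upper = m + 1.96 * s,
                 n = length(differences)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean difference %.4g, 95%% limits [%.4g, %.4g] (n = %d)\n",
    x$mean_difference, x$lower, x$upper, x$n))
  invisible(x)
}
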