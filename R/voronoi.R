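#' Finite Voronoi edges of the marked cones
#'
#' Computes the edges of the Voronoi tessellation of the cone positions,
#' clipped to the image rectangle. Each returned segment is the locus of
#' points equidistant from its two generating cones and no closer to any
#' other cone; unbounded ridges are clipped at the image bounds and kept if
#' the clipped portion has positive length.
#'
#' The construction is exact half-plane intersection along each pair's
#' perpendicular bisector (quadratic in the number of cones per pair), which
#' is ample for the ~100-cone regions this package targets.
#'
#' @param cones a [marked_cones()] set with at least 3 non-collinear points.
#' @param image a [cone_image()] or `c(height, width)` giving the clip
#'   rectangle (pixel centres, so x in \[0, width-1\]).
#' @return A data frame of class `voronoi_edges` with columns `x1, y1, x2,
#'   y2` (segment endpoints) and `i, j` (1-based indices of the two
#'   generating cones).
#' @export
voronoi_edges <- function(cones, image) {
  stopifnot(inherits(cones, "marked_cones"))
  dims <- if (inherits(image, "cone_image")) c(image$height, image$width)
          else as.numeric(image)
  H <- dims[1]; W <- dims[2]
  px <- cones$x; py <- cones$y
  n <- length(px)
  if (n < 3L) stop("need at least 3 cone points for a Voronoi diagram")
  sv <- svd(cbind(px - mean(px), py - mean(py)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("cone points are collinear; Voronoi edges are undefined")
  sq <- px^2 + py^2
  res <- vector("list", n * (n - 1L) / 2L)
  m <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- px[j] - px[i]; dy <- py[j] - py[i]
      len <- sqrt(dx^2 + dy^2)
      if (len < 1e-12) next
      mx <- (px[i] + px[j]) / 2; my <- (py[i] + py[j]) / 2
      ux <- -dy / len; uy <- dx / len       # bisector direction
      # half-plane constraints from every other generator k:
      # |x - p_i|^2 <= |x - p_k|^2  <=>  a t <= b along x(t) = m + t u
      k <- seq_len(n)[-c(i, j)]
      a <- 2 * (ux * (px[k] - px[i]) + uy * (py[k] - py[i]))
      b <- (sq[k] - sq[i]) - 2 * (mx * (px[k] - px[i]) + my * (py[k] - py[i]))
      # clip rectangle constraints: 0 <= mx + t ux <= W-1, same for y
      a <- c(a,  ux, -ux,  uy, -uy)
      b <- c(b,  (W - 1) - mx, mx, (H - 1) - my, my)
      pos <- a >  1e-12
      neg <- a < -1e-12
      zer <- !pos & !neg
      if (any(zer & (b < -1e-9))) next      # infeasible
      thi <- if (any(pos)) min(b[pos] / a[pos]) else Inf
      tlo <- if (any(neg)) max(b[neg] / a[neg]) else -Inf
      if (!(thi - tlo > 1e-9) || !is.finite(thi) || !is.finite(tlo)) next
      m <- m + 1L
      res[[m]] <- c(mx + tlo * ux, my + tlo * uy,
                    mx + thi * ux, my + thi * uy, i, j)
    }
  }
  if (m == 0L) stop("no finite Voronoi edges inside the image rectangle")
  ed <- do.call(rbind, res[seq_len(m)])
  out <- data.frame(x1 = ed[, 1], y1 = ed[, 2], x2 = ed[, 3], y2 = ed[, 4],
                    i = as.integer(ed[, 5]), j = as.integer(ed[, 6]))
  class(out) <- c("voronoi_edges", "data.frame")
  out
}

#' Sample one non-cone location per Voronoi edge
#'
#' Draws a single point uniformly along the arc length of each (clipped)
#' Voronoi edge and rounds it to the nearest pixel; edges shorter than one
#' pixel contribute their rounded midpoint. Duplicate pixels arising from
#' different edges are dropped.
#'
#' @param edges a [voronoi_edges()] data frame.
#' @param seed optional integer; when given, sampling is done under this seed
#'   with the caller's RNG state restored afterwards.
#' @return Integer matrix with columns `x`, `y` (0-based pixel coordinates).
#' @export
sample_noncone_points <- function(edges, seed = NULL) {
  stopifnot(inherits(edges, "voronoi_edges"), nrow(edges) > 0L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  len <- sqrt((edges$x2 - edges$x1)^2 + (edges$y2 - edges$y1)^2)
  t <- runif(nrow(edges))
  t[len < 1] <- 0.5
  x <- round(edges$x1 + t * (edges$x2 - edges$x1))
  y <- round(edges$y1 + t * (edges$y2 - edges$y1))
  pts <- cbind(x = as.integer(x), y = as.integer(y))
  pts[!duplicated(pts), , drop = FALSE]
}
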