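test_that("square and triangle configurations give textbook Voronoi edges", {
  img <- c(100, 100)
  sq <- marked_cones(c(20, 60, 20, 60), c(20, 20, 60, 60), "manual")
  ed <- voronoi_edges(sq, img)
  # 4 edges radiating from the centre (40, 40), one per adjacent pair
  expect_equal(nrow(ed), 4L)
  mids <- unique(round(cbind(c(ed$x1, ed$x2), c(ed$y1, ed$y2))))
  expect_true(any(mids[, 1] == 40 & mids[, 2] == 40))
  # every edge endpoint equidistant from its two generators
  for (k in seq_len(nrow(ed))) {
    i <- ed$i[k]; j <- ed$j[k]
    d1 <- sqrt((ed$x1[k] - sq$x[i])^2 + (ed$y1[k] - sq$y[i])^2)
    d2 <- sqrt((ed$x1[k] - sq$x[j])^2 + (ed$y1[k] - sq$y[j])^2)
    expect_equal(d1, d2, tolerance = 1e-9)
  }

  tri <- marked_cones(c(30, 70, 50), c(30, 30, 75), "manual")
  ed3 <- voronoi_edges(tri, img)
  expect_equal(nrow(ed3), 3L)
})

test_that("interior points of every edge are equidistant from the two
           generators and no closer to any other cone", {
  set.seed(42)
  cones <- random_cones(40, source = "manual")
  ed <- voronoi_edges(cones, c(100, 100))
  for (k in seq_len(nrow(ed))) {
    for (t in c(0.25, 0.5, 0.75)) {
      px <- ed$x1[k] + t * (ed$x2[k] - ed$x1[k])
      py <- ed$y1[k] + t * (ed$y2[k] - ed$y1[k])
      dd <- sqrt((cones$x - px)^2 + (cones$y - py)^2)
      i <- ed$i[k]; j <- ed$j[k]
      expect_equal(dd[i], dd[j], tolerance = 1e-6)
      expect_gte(min(dd[-c(i, j)]) - dd[i], -1e-6)
    }
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(voronoi_edges(marked_cones(c(1, 2), c(1, 2), "manual"),
                             c(50, 50)), "at least 3")
  expect_error(voronoi_edges(marked_cones(c(1, 2, 3), c(1, 2, 3), "manual"),
                             c(50, 50)), "collinear")
})

test_that("non-cone sampling is per-edge, rounded, deduplicated and
           deterministic", {
  set.seed(9)
  cones <- random_cones(30, source = "manual")
  ed <- voronoi_edges(cones, c(100, 100))
  p1 <- sample_noncone_points(ed, seed = 4)
  p2 <- sample_noncone_points(ed, seed = 4)
  expect_identical(p1, p2)
  expect_lte(nrow(p1), nrow(ed))          # dedup can only shrink
  expect_true(all(p1 == round(p1)))       # integer pixels
  # each point within half-pixel rounding of its segment
  seg_dist <- function(px, py, e) {
    vx <- e$x2 - e$x1; vy <- e$y2 - e$y1
    tt <- pmin(1, pmax(0, ((px - e$x1) * vx + (py - e$y1) * vy) /
                            (vx^2 + vy^2)))
    sqrt((e$x1 + tt * vx - px)^2 + (e$y1 + tt * vy - py)^2)
  }
  dmin <- vapply(seq_len(nrow(p1)), function(k)
    min(seg_dist(p1[k, 1], p1[k, 2], ed)), numeric(1))
  expect_lte(max(dmin), 0.5 * sqrt(2) + 1e-9)
  # a sub-pixel edge contributes its rounded midpoint
  short <- ed[1, ]
  short$x2 <- short$x1 + 0.3; short$y2 <- short$y1
  class(short) <- class(ed)
  mp <- sample_noncone_points(short, seed = 1)
  expect_equal(as.numeric(mp[1, ]),
               c(round(short$x1 + 0.15), round(short$y1)))
})
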