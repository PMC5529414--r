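test_that("match radius is 0.75 of the median nearest-neighbour spacing", {
  # perfect square lattice, spacing 10
  g <- expand.grid(x = seq(0, 40, 10), y = seq(0, 40, 10))
  expect_equal(match_radius(marked_cones(g$x, g$y, "manual")), 7.5)
  # 3 collinear-ish cones at x = 0, 10, 30: NN distances 10, 10, 20
  three <- marked_cones(c(0, 10, 30), c(0, 0, 1e-9), "manual")
  expect_equal(match_radius(three), 7.5, tolerance = 1e-6)
  expect_error(match_radius(marked_cones(1, 1, "manual")), "at least 2")
  # jittered hex fixture: d lands in a plausible fraction of the spacing
  m <- tiny_mosaic(61)
  d <- match_radius(m$cones)
  a <- m$params$lattice_constant
  expect_gt(d / a, 0.5)
  expect_lt(d / a, 0.9)
})

test_that("identical interior sets match perfectly and the closest of
           several candidates wins", {
  img <- c(100, 100)
  set.seed(5)
  pts <- marked_cones(runif(30, 10, 89), runif(30, 10, 89), "manual")
  auto <- marked_cones(pts$x, pts$y, "automatic")
  mr <- match_cones(auto, pts, d = 5, image = img)
  expect_equal(mr$n_tp, 30L)
  expect_equal(mr$n_fp, 0L)
  expect_equal(mr$n_fn, 0L)
  # two autos at distances 2 and 4 from one manual: nearer wins, farther FP
  man <- marked_cones(50, 50, "manual")
  au <- marked_cones(c(52, 54), c(50, 50), "automatic")
  mr2 <- match_cones(au, man, d = 5, image = img)
  expect_equal(mr2$n_tp, 1L)
  expect_equal(mr2$pairs$auto, 1L)
  expect_equal(mr2$n_fp, 1L)
})

test_that("border pruning removes points within 7 px of any edge before
           matching", {
  img <- c(50, 50)
  man <- marked_cones(c(3, 25, 46), c(25, 25, 25), "manual")
  auto <- marked_cones(c(3, 25), c(25, 25), "automatic")
  mr <- match_cones(auto, man, d = 4, image = img, border = 7)
  expect_equal(mr$n_manual, 1L)   # only the centre point survives
  expect_equal(mr$n_auto, 1L)
  expect_equal(mr$n_tp, 1L)
  # boundary of the kept region: x in [7, 42] for a 50-wide image
  man2 <- marked_cones(c(7, 42, 6.9), c(25, 25, 25), "manual")
  mr2 <- match_cones(auto, man2, d = 50, image = img, border = 7)
  expect_equal(mr2$n_manual, 2L)
})

test_that("counts satisfy the bookkeeping identities on random point sets", {
  set.seed(77)
  for (rep in 1:200) {
    na <- sample(0:25, 1); nm <- sample(2:25, 1)
    auto <- random_cones(na, 60, 60, "automatic")
    man <- random_cones(nm, 60, 60, "manual")
    d <- runif(1, 1, 15)
    mr <- match_cones(auto, man, d, image = c(60, 60), border = 0)
    expect_equal(mr$n_auto, mr$n_tp + mr$n_fp)
    expect_equal(mr$n_manual, mr$n_tp + mr$n_fn)
    if (nrow(mr$pairs)) expect_lte(max(mr$pairs$distance), d)
    expect_false(any(duplicated(mr$pairs$auto)))
    expect_false(any(duplicated(mr$pairs$manual)))
  }
})

test_that("greedy matching reproduces the assignment oracle's cardinality on
           spacing-derived radii", {
  skip_if_not_installed("igraph")
  set.seed(123)
  for (rep in 1:20) {
    nm <- sample(8:15, 1)
    man <- random_cones(nm, 60, 60, "manual")
    # perturb + drop/add to mimic detections
    keep <- runif(nm) < 0.9
    auto <- marked_cones(
      c(man$x[keep] + rnorm(sum(keep), 0, 1.5), runif(2, 0, 59)),
      c(man$y[keep] + rnorm(sum(keep), 0, 1.5), runif(2, 0, 59)),
      "automatic")
    d <- match_radius(man)
    mr <- match_cones(auto, man, d, image = c(60, 60), border = 0)
    expect_equal(mr$n_tp, match_cardinality_oracle(auto, man, d))
  }
})

test_that("performance metrics follow the defining formulas", {
  fake <- structure(list(n_tp = 95L, n_fp = 5L, n_fn = 5L, n_auto = 100L,
                         n_manual = 100L), class = "match_result")
  met <- compute_metrics(fake)
  expect_equal(met$true_positive_rate, 0.95)
  expect_equal(met$false_discovery_rate, 0.05)
  expect_equal(met$dice, 0.95)
  perfect <- structure(list(n_tp = 42L, n_fp = 0L, n_fn = 0L, n_auto = 42L,
                            n_manual = 42L), class = "match_result")
  mp <- compute_metrics(perfect)
  expect_equal(c(mp$true_positive_rate, mp$false_discovery_rate, mp$dice),
               c(1, 0, 1))
  none <- structure(list(n_tp = 0L, n_fp = 10L, n_fn = 20L, n_auto = 10L,
                         n_manual = 20L), class = "match_result")
  expect_equal(compute_metrics(none)$dice, 0)
  # undefined rates flagged as NA, not silently zero
  empty <- structure(list(n_tp = 0L, n_fp = 0L, n_fn = 5L, n_auto = 0L,
                          n_manual = 5L), class = "match_result")
  expect_true(is.na(compute_metrics(empty)$false_discovery_rate))
})

test_that("cone density follows count / area and the scale law", {
  # 100 cones in 0.005 mm^2
  img <- cone_image(matrix(0, 100, 100), scale = sqrt(0.005) * 1000 / 100)
  cones <- random_cones(100, 100, 100)
  expect_equal(cone_density(cones, img), 20000, tolerance = 1e-9)
  # doubling microns-per-pixel quarters the density
  img2 <- cone_image(matrix(0, 100, 100), scale = 2 * img$scale)
  expect_equal(cone_density(cones, img2), 5000, tolerance = 1e-9)
  expect_error(cone_density(cones, cone_image(matrix(0, 10, 10))), "scale")
  # generator bookkeeping: planted density equals count / area
  m <- tiny_mosaic(62)
  area <- m$image$height * m$image$width * m$params$scale^2 / 1e6
  expect_equal(cone_density(m$cones, m$image), nrow(m$cones) / area)
})

test_that("Bland-Altman limits follow mean +/- 1.96 sd and cover ~95%", {
  z <- bland_altman(c(0, 0, 0))
  expect_equal(c(z$mean_difference, z$lower, z$upper), c(0, 0, 0))
  b <- bland_altman(c(-1, 1))
  expect_equal(b$mean_difference, 0)
  expect_equal(b$sd, sqrt(2))
  expect_equal(b$upper, 1.96 * sqrt(2))
  expect_error(bland_altman(3), ">= 2")
  set.seed(99)
  d <- rnorm(1000, 2, 3)
  ba <- bland_altman(d)
  cover <- mean(d >= ba$lower & d <= ba$upper)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})
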