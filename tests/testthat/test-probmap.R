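test_that("mirror padding matches the explicit half-sample construction and
           a constant image gives a constant map", {
  set.seed(6)
  m <- matrix(runif(40 * 36), 40, 36)
  expect_equal(conefinder:::mirror_pad(m), mirror_pad_oracle(m, 16))
  # corner pixel's patch equals the oracle-padded crop
  pad <- mirror_pad_oracle(m, 16)
  expect_equal(pad[1:33, 1:33], mirror_pad_oracle(m, 16)[1:33, 1:33])

  net <- tiny_net()
  cm <- compute_probability_map(net, cone_image(matrix(0, 40, 40)))
  expect_equal(dim(cm), c(40L, 40L))
  expect_lt(diff(range(cm)), 1e-12)         # all patches identical
  expect_true(all(cm >= 0 & cm <= 1))
})

test_that("probability map equals per-patch classification (mirror-padding
           oracle)", {
  net <- tiny_net()
  m <- tiny_mosaic(41)
  img <- normalize_intensity(m$image)
  small <- cone_image(img$pixels[1:48, 1:44])
  pm <- compute_probability_map(net, small)
  pad <- mirror_pad_oracle(small$pixels, 16)
  # check corners, edges and interior pixels against explicit patches
  pts <- rbind(c(0, 0), c(43, 0), c(0, 47), c(43, 47), c(20, 25), c(5, 40))
  for (k in seq_len(nrow(pts))) {
    x <- pts[k, 1]; y <- pts[k, 2]
    patch <- pad[y + (1:33), x + (1:33)]
    p <- unname(predict(net, patch)[1, "cone"])
    expect_equal(pm[y + 1, x + 1], p, tolerance = 1e-6)
  }
})

test_that("Gaussian smoothing is identity at sigma 0, mass preserving, peak
           calibrated, and never raises the maximum", {
  set.seed(2)
  m <- matrix(runif(50 * 50), 50, 50)
  expect_identical(smooth_map(m, 0), m)
  sm <- smooth_map(m, 2)
  expect_lt(abs(mean(sm) - mean(m)), 1e-3)
  expect_lte(max(sm), max(m) + 1e-12)
  expect_error(smooth_map(m, -1), "non-negative")

  # delta spike: peak equals the discretised kernel's central weight
  d <- matrix(0, 41, 41); d[21, 21] <- 1
  sd13 <- smooth_map(d, 1.3)
  expect_equal(sd13[21, 21], 1 / (2 * pi * 1.3^2), tolerance = 0.02)
})

test_that("extended maxima reproduce the two-peak toy example", {
  toy <- matrix(0.1, 11, 11)
  # two isolated peaks of heights 0.9 and 0.6
  toy[3, 3] <- 0.9
  toy[8, 8] <- 0.6
  em1 <- extended_maxima(toy, 0.2)
  expect_true(em1[3, 3] && em1[8, 8])
  expect_equal(sum(em1), 2L)
  em2 <- extended_maxima(toy, 0.55)
  expect_true(em2[3, 3])
  expect_false(em2[8, 8])              # short peak merges into background
  expect_equal(em1, extended_maxima_oracle(toy, 0.2))
  expect_equal(em2, extended_maxima_oracle(toy, 0.55))
  # constant map, H = 0: the whole image is one maximal region
  expect_true(all(extended_maxima(matrix(1, 7, 7), 0)))
})

test_that("localization filters clusters by threshold and returns centroids", {
  sm <- matrix(0, 30, 30)
  mask <- matrix(FALSE, 30, 30)
  mask[11:13, 11:13] <- TRUE           # 3x3 square at rows/cols 10-12 0-based
  sm[11:13, 11:13] <- 0.8
  cones <- localize_cones(mask, sm, 0.5)
  expect_equal(nrow(cones), 1L)
  expect_equal(c(cones$x, cones$y), c(11, 11))
  expect_equal(nrow(localize_cones(mask, sm, 0.9)), 0L)
  # L-shaped 3-pixel cluster: centroid at (1/3, 1/3)
  mask2 <- matrix(FALSE, 10, 10)
  mask2[1, 1] <- mask2[1, 2] <- mask2[2, 1] <- TRUE
  sm2 <- matrix(1, 10, 10)
  c2 <- localize_cones(mask2, sm2, 0.5)
  expect_equal(c(c2$x, c2$y), c(1 / 3, 1 / 3))
})

test_that("raising T never increases the detection count and centroids stay
           inside their cluster bounding box", {
  net <- tiny_net()
  m <- tiny_mosaic(43)
  img <- normalize_intensity(m$image)
  small <- cone_image(img$pixels[1:60, 1:60], scale = img$scale)
  pm <- compute_probability_map(net, small)
  sm <- smooth_map(pm, 1.3)
  mask <- extended_maxima(sm, 0.05)
  counts <- vapply(seq(0.1, 0.9, by = 0.2),
                   function(t) nrow(localize_cones(mask, sm, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  lab <- conefinder:::label_components(mask)
  det <- localize_cones(mask, sm, 0)
  expect_equal(nrow(det), max(lab))
  for (l in seq_len(max(lab))) {
    sel <- which(lab == l, arr.ind = TRUE)
    ok <- any(det$x >= min(sel[, 2]) - 1 & det$x <= max(sel[, 2]) - 1 &
              det$y >= min(sel[, 1]) - 1 & det$y <= max(sel[, 1]) - 1)
    expect_true(ok)
  }
})

test_that("detection is invariant to a constant intensity shift", {
  net <- tiny_net()
  m <- tiny_mosaic(44)
  small <- cone_image(m$image$pixels[1:50, 1:50])
  par <- detection_params(1.3, 0, 0.3)
  d1 <- detect_cones(small, net, par)
  d2 <- detect_cones(cone_image(small$pixels + 123.4), net, par)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  # detected cones lie within image bounds
  expect_true(all(d1$x >= 0 & d1$x <= 49 & d1$y >= 0 & d1$y <= 49))
})
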