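test_that("mosaics plant roughly 100 cones on a 150 px field and are
           reproducible", {
  counts <- vapply(1:8, function(s)
    nrow(generate_mosaic(mosaic_params(seed = s))$cones), numeric(1))
  expect_true(all(counts >= 80 & counts <= 120))
  a <- generate_mosaic(mosaic_params(seed = 3))
  b <- generate_mosaic(mosaic_params(seed = 3))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(as.data.frame(a$cones), as.data.frame(b$cones))
  expect_false(identical(a$image$pixels,
                         generate_mosaic(mosaic_params(seed = 4))$image$pixels))
})

test_that("noiseless, jitter-free confocal blobs peak at the planted
           centres", {
  p <- mosaic_params(seed = 5, jitter_sd = 0, noise_sd = 0,
                     background_lf = 0, cone_amplitude_sd = 0,
                     cone_sigma_sd = 0)
  m <- generate_mosaic(p)
  px <- m$image$pixels
  for (k in seq_len(nrow(m$cones))) {
    x <- m$cones$x[k]; y <- m$cones$y[k]
    win <- px[round(y) + 1 + (-2:2), round(x) + 1 + (-2:2)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - 3)), 1)   # peak within ~0.5 px + rounding
  }
})

test_that("a trivial local-maxima detector recovers nearly all cones from a
           noiseless mosaic (sanity floor)", {
  p <- mosaic_params(seed = 6, noise_sd = 0, background_lf = 0)
  m <- generate_mosaic(p)
  rm_ <- conefinder:::regional_maxima(smooth_map(m$image$pixels, 1))
  det <- localize_cones(rm_, m$image$pixels, t = 60)
  d <- match_radius(m$cones)
  mr <- match_cones(det, m$cones, d, image = m$image, border = 7)
  expect_gte(mr$n_tp / mr$n_manual, 0.99)
})

test_that("split-detector rendering produces signed dipoles flanking each
           centre", {
  p <- mosaic_params(seed = 7, modality = "splitdetector", jitter_sd = 0,
                     noise_sd = 0, background_lf = 0, background = 0,
                     cone_amplitude_sd = 0, cone_sigma_sd = 0)
  m <- generate_mosaic(p)
  px <- m$image$pixels
  s <- p$cone_sigma
  for (k in seq_len(min(20, nrow(m$cones)))) {
    x <- round(m$cones$x[k]); y <- round(m$cones$y[k])
    left <- px[y + 1, x + 1 - round(s)]
    right <- px[y + 1, x + 1 + round(s)]
    expect_gt(left, 0)     # bright lobe on the left
    expect_lt(right, 0)    # dark lobe on the right
  }
})

test_that("fixture suites have disjoint seeds and the documented size", {
  suite <- make_fixture_suite(seed = 2, n_train = 20, n_val = 10)
  expect_equal(length(suite$train), 20L)
  expect_equal(length(suite$val), 10L)
  seeds <- vapply(c(suite$train, suite$val),
                  function(m) m$params$seed, numeric(1))
  expect_false(any(duplicated(seeds)))
  counts <- vapply(c(suite$train, suite$val),
                   function(m) nrow(m$cones), numeric(1))
  expect_true(all(counts >= 80 & counts <= 120))
  # both modalities for a 60-image default set
  sd_suite <- make_fixture_suite(seed = 2, modality = "splitdetector",
                                 n_train = 20, n_val = 10)
  expect_equal(length(sd_suite$train) + length(sd_suite$val) +
               length(suite$train) + length(suite$val), 60L)
})

test_that("parameter invariants are enforced", {
  expect_error(mosaic_params(jitter_sd = 10, lattice_constant = 14), "jitter")
  expect_error(mosaic_params(dropout = 1))
  expect_error(mosaic_params(lattice_constant = 5))
})
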