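test_that("the default grid is built from exact decimal grid points", {
  g <- param_grid()
  expect_true(all(c(1.3, 2, 0.4) %in% unique(g$sigma)))
  expect_true(all(c(0, 0.1, 0.25) %in% unique(g$h)))
  expect_true(all(c(0.3, 0.5, 0.9) %in% unique(g$t)))
  key <- paste(g$sigma, g$h, g$t)
  expect_true(all(c("1.3 0 0.3", "2 0.1 0.5", "0.4 0.25 0.9") %in% key))
  expect_equal(nrow(g), 31 * 11 * 9)
})

# a synthetic "probability map": clean Gaussian bumps at known positions
fake_probmap <- function(centres, H = 80, W = 80, sigma = 2) {
  m <- matrix(0, H, W)
  for (k in seq_len(nrow(centres))) {
    xs <- pmax(0, round(centres$x[k]) - 8):pmin(W - 1, round(centres$x[k]) + 8)
    ys <- pmax(0, round(centres$y[k]) - 8):pmin(H - 1, round(centres$y[k]) + 8)
    m[ys + 1, xs + 1] <- pmax(m[ys + 1, xs + 1],
      0.97 * exp(-(outer((ys - centres$y[k])^2, (xs - centres$x[k])^2, "+")) /
                   (2 * sigma^2)))
  }
  m
}

test_that("a grid point achieving perfect detection is returned with mean
           Dice 1", {
  set.seed(31)
  g <- expand.grid(x = seq(15, 65, 10), y = seq(15, 65, 10))
  man <- marked_cones(g$x + runif(36, -2, 2), g$y + runif(36, -2, 2),
                      "manual")
  pm <- fake_probmap(man)
  opt <- optimize_params(list(pm), list(man), param_grid())
  expect_equal(opt$dice, 1)
  # exhaustiveness: no other grid point scores higher
  expect_true(all(opt$table$mean_dice <= opt$dice + 1e-12))
})

test_that("a single-point grid is returned regardless of score and an empty
           grid errors", {
  man <- marked_cones(c(20, 40, 30), c(20, 20, 45), "manual")
  pm <- matrix(0.01, 60, 60)      # nothing to detect
  g1 <- param_grid(sigma = 1.3, h = 0, t = 0.3)
  opt <- optimize_params(list(pm), list(man), g1)
  expect_equal(unclass(opt$params), list(sigma = 1.3, h = 0, t = 0.3))
  expect_error(optimize_params(list(pm), list(man),
                               param_grid()[integer(0), ]), "empty")
})

test_that("the reported score table matches independent re-evaluation", {
  set.seed(32)
  man <- random_cones(25, 80, 80)
  pm <- fake_probmap(man)
  pm <- pm + matrix(runif(80 * 80, 0, 0.15), 80, 80)   # mild clutter
  grid <- param_grid(sigma = c(0, 1, 2), h = c(0, 0.1), t = c(0.3, 0.6))
  opt <- optimize_params(list(pm), list(man), grid)
  d <- match_radius(man)
  recheck <- apply(opt$table, 1, function(row) {
    sm <- smooth_map(pm, row[["sigma"]])
    mask <- extended_maxima(sm, row[["h"]])
    det <- localize_cones(mask, sm, row[["t"]])
    mr <- match_cones(det, man, d, image = c(80, 80), border = 7)
    compute_metrics(mr)$dice
  })
  expect_equal(opt$table$mean_dice, unname(recheck), tolerance = 1e-12)
  # the winner beats or ties every grid point (already sorted)
  expect_true(all(diff(opt$table$mean_dice) <= 1e-12))
})

test_that("ties break towards smallest sigma, then smallest h, then largest
           t", {
  man <- marked_cones(c(20, 40, 30), c(20, 20, 45), "manual")
  pm <- fake_probmap(man, 60, 60)
  grid <- param_grid(sigma = c(0.5, 1), h = c(0, 0.05), t = c(0.2, 0.4))
  opt <- optimize_params(list(pm), list(man), grid)
  tab <- opt$table
  best <- tab[tab$mean_dice >= max(tab$mean_dice) - 1e-12, ]
  expect_equal(opt$params$sigma, min(best$sigma))
  sub <- best[best$sigma == opt$params$sigma, ]
  expect_equal(opt$params$h, min(sub$h))
  sub2 <- sub[sub$h == opt$params$h, ]
  expect_equal(opt$params$t, max(sub2$t))
})
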