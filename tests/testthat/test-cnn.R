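test_that("forward activation shapes follow the architecture table", {
  net <- init_network(seed = 1)
  sh <- network_activation_shapes(net)
  expect_equal(sh$conv1, c(33L, 33L, 32L))
  expect_equal(sh$pool1, c(16L, 16L, 32L))   # input to layer 4
  expect_equal(sh$conv2, c(16L, 16L, 32L))
  expect_equal(sh$pool2, c(8L, 8L, 32L))     # input to layer 9
  expect_equal(sh$conv3, c(8L, 8L, 64L))
  expect_equal(sh$pool3, c(4L, 4L, 64L))     # input to layer 13
  expect_equal(sh$fc1, c(1L, 1L, 64L))
  expect_equal(sh$softmax, c(1L, 1L, 2L))
})

test_that("soft-max outputs are proper probabilities for random and trained
           weights", {
  net <- init_network(seed = 3)
  p <- predict(net, array(0, c(33, 33, 1)))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  set.seed(8)
  x <- array(runif(33 * 33 * 10) * 255, c(33, 33, 10))
  pt <- predict(tiny_net(), x)
  expect_equal(rowSums(pt), rep(1, 10), tolerance = 1e-6)
  expect_true(all(pt >= 0 & pt <= 1))
})

test_that("initialisation and training are deterministic under a seed", {
  a <- init_network(seed = 5)$par
  b <- init_network(seed = 5)$par
  expect_identical(a, b)
  expect_false(identical(a$conv1_w, init_network(seed = 6)$par$conv1_w))
  ps <- tiny_patchset()
  cfg <- cnn_config(epochs = 1, lr_drop_epochs = integer(0), seed = 12)
  n1 <- cone_cnn(ps, cfg)
  n2 <- cone_cnn(ps, cfg)
  expect_identical(n1$par, n2$par)
})

test_that("analytic gradients match finite differences through every layer
           type", {
  net <- init_network(seed = 2, init_sd = 0.05)
  par <- net$par
  eps <- 1e-5
  set.seed(3)
  N <- 3L
  x <- array(runif(33 * 33 * N) * 255, c(33, 33, 1, N))
  y <- rbind(noncone = c(1, 0, 1), cone = c(0, 1, 0))
  lossfun <- function(p) {
    pr <- conefinder:::cnn_forward(p, x, TRUE, eps)$probs
    -mean(log(colSums(t(pr) * y)))
  }
  fw <- conefinder:::cnn_forward(par, x, TRUE, eps, keep_cache = TRUE)
  g <- conefinder:::cnn_backward(par, fw$cache, fw$probs, y, eps)
  # conv biases feed a batch-norm, whose mean subtraction makes their true
  # gradient ~0; check them for magnitude instead of ratio
  for (nm in c("conv1_w", "bn1_g", "bn1_b", "conv2_w", "conv3_w",
               "fc1_w", "fc1_b", "bn4_g", "fc2_w", "fc2_b")) {
    idx <- sample(length(par[[nm]]), 2)
    for (i in idx) {
      h <- 1e-5 * max(1, abs(par[[nm]][i]))
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + h; f1 <- lossfun(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h; f0 <- lossfun(p2)
      num <- (f1 - f0) / (2 * h)
      expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-4)
    }
  }
  expect_lt(max(abs(g$conv1_b)), 1e-10)
})

test_that("batched evaluation equals one-by-one evaluation", {
  net <- tiny_net()
  set.seed(4)
  x <- array(runif(33 * 33 * 40) * 255, c(33, 33, 40))
  pb <- predict(net, x, batch_size = 40L)
  pl <- t(vapply(seq_len(40),
                 function(k) predict(net, x[, , k], batch_size = 1L)[1, ],
                 numeric(2)))
  expect_lt(max(abs(pb - pl)), 1e-6)
  # duplicated patch in one batch gets identical probabilities
  xd <- x[, , c(1, 1, 2)]
  pd <- predict(net, xd)
  expect_identical(pd[1, ], pd[2, ])
})

test_that("training rejects degenerate inputs and records a learning curve", {
  ps <- tiny_patchset()
  only_cone <- patch_set(ps$patches[, , ps$labels == "cone"],
                         ps$labels[ps$labels == "cone"],
                         ps$provenance[ps$labels == "cone", ])
  expect_error(cone_cnn(only_cone,
               cnn_config(epochs = 1, lr_drop_epochs = integer(0))), "both")
  expect_error(predict(tiny_net(), array(0, c(20, 20, 1))), "33")
  h <- tiny_net()$history
  expect_equal(nrow(h), 3L)
  expect_lt(h$loss[3], h$loss[1])
})

test_that("a reduced-scale network separates held-out cone and non-cone
           patches", {
  net <- fixture_run("confocal")$net
  m <- tiny_mosaic(55)   # image unseen by the fixture suite
  held <- build_training_set(list(m$image), list(m$cones), seed = 20)
  pr <- predict(net, held)[, "cone"]
  cone_idx <- held$labels == "cone"
  expect_gte(mean(pr[cone_idx] > 0.5), 0.9)
  acc <- mean((pr > 0.5) == cone_idx)
  expect_gte(acc, 0.9)
})
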