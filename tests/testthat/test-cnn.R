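test_that("feature-map arithmetic matches the conv/pool recurrence", {
  expect_identical(feature_map_side(49, "valid"), 2L)
  expect_identical(feature_map_side(49, "same"), 12L)
  expect_identical(feature_map_side(43, "valid"), 1L)
  err <- tryCatch(feature_map_side(29, "valid"), error = function(e) e)
  expect_s3_class(err, "mcseg_invalid_config")
  expect_match(conditionMessage(err), "conv 5")
  expect_error(feature_map_side(48, "valid"), "odd")
  expect_error(network_config(N = 29, padding_mode = "valid"),
               class = "mcseg_invalid_config")
})

test_that("the instantiated network reproduces the printed 49 -> 2 x 2 path", {
  cfgs <- list(
    network_config(49, "valid", c(4, 4, 6, 6, 8, 8), fc_units = 8),
    network_config(43, "valid", c(4, 4, 6, 6, 8, 8), fc_units = 8),
    tiny_config(N = 13), tiny_config(N = 21), tiny_config(N = 9)
  )
  for (cfg in cfgs) {
    net <- build_network(cfg, seed = 1)
    expect_identical(mcseg:::forward_feat_side(net),
                     feature_map_side(cfg$N, cfg$padding_mode))
    expect_equal(ncol(net$params$fc1$W),
                 cfg$feat_side^2 * cfg$conv_filters[6])
  }
})

test_that("network construction is deterministic and forward passes are finite", {
  cfg <- tiny_config()
  a <- build_network(cfg, seed = 5)
  b <- build_network(cfg, seed = 5)
  expect_identical(a$params, b$params)
  c <- build_network(cfg, seed = 6)
  expect_false(identical(a$params, c$params))

  pred <- predict_patches(a, matrix(0, 13, 13))
  expect_true(all(is.finite(c(pred$p_negative, pred$p_positive))))
  expect_equal(pred$p_negative + pred$p_positive, 1, tolerance = 1e-6)
})

test_that("softmax posterior matches closed forms and is shift-invariant", {
  expect_equal(softmax_posterior(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_posterior(c(log(3), 0)), c(0.75, 0.25))
  s <- c(1.3, -0.2)
  expect_equal(softmax_posterior(s), softmax_posterior(s + 17.5))
  expect_error(softmax_posterior(c(1, NaN)), "finite")

  set.seed(3)
  m <- matrix(rnorm(2 * 1e4, sd = 50), 2)
  p <- softmax_posterior(m)
  expect_lt(max(abs(colSums(p) - 1)), 1e-12)
  expect_true(all(p > 0))
})

test_that("cross-entropy matches closed forms", {
  expect_identical(crossentropy(c(1, 0), c(1, 0)), 0)
  expect_equal(crossentropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(crossentropy(c(0, 1), c(0.5, 0.5)), log(2))
  expect_equal(crossentropy(c(0, 0, 0, 1, 0), rep(0.2, 5)), log(5))
  expect_gt(crossentropy(c(1, 0), c(1e-20, 1)), 0)
  expect_error(crossentropy(c(1, 0), c(0.2, 0.3, 0.5)), "length")
  expect_error(crossentropy(c(0.5, 0.5), c(0.5, 0.5)), "one-hot")
})

test_that("backpropagated gradients agree with finite differences", {
  set.seed(7)
  net <- build_network(network_config(13, "same", c(3, 3, 4, 4, 5, 5),
                                      fc_units = 8), seed = 3)
  B <- 5
  x <- array(rnorm(13 * 13 * B), dim = c(13, 13, B))
  y <- rbind(c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 0))
  mask <- matrix((runif(8 * B) >= 0.5) / 0.5, 8, B)
  g <- mcseg:::cpp_net_grad(net$params, x, y, 1L, mask, 1e-5)
  expect_true(is.finite(g$loss))

  fd <- function(mod) {
    eps <- 1e-3
    lp <- mcseg:::cpp_net_grad(mod(net$params, eps), x, y, 1L, mask, 1e-5)$loss
    lm <- mcseg:::cpp_net_grad(mod(net$params, -eps), x, y, 1L, mask, 1e-5)$loss
    (lp - lm) / (2 * eps)
  }
  # the engine computes in single precision: allow float-level slack, which
  # still catches structural errors (those are wrong by O(1))
  tol <- function(x) 0.02 + 0.02 * abs(x)
  for (l in c(1, 3, 6)) {
    for (i in c(1, 7)) {
      an <- g$grads$conv[[l]]$W[i]
      nu <- fd(function(p, e) { p$conv[[l]]$W[i] <- p$conv[[l]]$W[i] + e; p })
      expect_lt(abs(an - nu), tol(nu))
    }
    an <- g$grads$conv[[l]]$gamma[2]
    nu <- fd(function(p, e) { p$conv[[l]]$gamma[2] <- p$conv[[l]]$gamma[2] + e; p })
    expect_lt(abs(an - nu), tol(nu))
  }
  for (i in c(1, 9)) {
    an <- g$grads$fc1$W[i]
    nu <- fd(function(p, e) { p$fc1$W[i] <- p$fc1$W[i] + e; p })
    expect_lt(abs(an - nu), tol(nu))
  }
  an <- g$grads$fc2$b[1]
  nu <- fd(function(p, e) { p$fc2$b[1] <- p$fc2$b[1] + e; p })
  expect_lt(abs(an - nu), tol(nu))
})

test_that("models round-trip through the HDF5 container", {
  net <- build_network(tiny_config(), seed = 9)
  net$role <- "detector"
  net$history <- tibble::tibble(step = c(10L, 20L), lr = c(1e-3, 1e-3),
                                train_loss = c(0.7, 0.5),
                                train_acc = c(0.5, 0.7),
                                val_loss = c(0.8, 0.6),
                                val_acc = c(0.5, 0.6))
  path <- withr::local_tempfile(fileext = ".h5")
  write_model(net, path)
  back <- read_model(path)
  expect_equal(back$params, net$params, tolerance = 1e-12)
  expect_identical(back$role, "detector")
  expect_identical(back$config$N, net$config$N)
  expect_identical(back$config$padding_mode, net$config$padding_mode)

  set.seed(1)
  x <- array(rnorm(13 * 13 * 4), dim = c(13, 13, 4))
  expect_equal(predict_patches(back, x), predict_patches(net, x))
})
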