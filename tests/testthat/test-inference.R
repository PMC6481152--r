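test_that("Otsu threshold splits a bimodal image and matches the scan oracle", {
  img <- matrix(c(rep(10, 50), rep(200, 50)) / 255, 10, 10)
  fg <- otsu_foreground(img)
  expect_gt(fg$threshold, 10 / 255)
  expect_lt(fg$threshold, 200 / 255)
  expect_identical(unname(fg$mask), unname(img > 100 / 255))

  set.seed(4)
  for (i in 1:5) {
    x <- matrix(c(rnorm(300, 0.2, 0.05), rnorm(200, 0.7, 0.1)), 25, 20)
    got <- otsu_foreground(x)$threshold
    v <- oracle_otsu_variance(x, got)
    expect_gte(v$at_thr, v$max * (1 - 1e-9))
  }

  expect_error(otsu_foreground(matrix(0.5, 5, 5)), class = "mcseg_no_split")
})

test_that("Otsu foreground recovers the phantom breast support", {
  ph <- small_phantom(seed = 2, side = 192)
  fg <- otsu_foreground(ph$image)
  agreement <- mean((fg$mask & ph$breast_support) |
                      (!fg$mask & !ph$breast_support))
  expect_gte(agreement, 0.99)
  # foreground covers nearly the whole breast and excludes background
  expect_gte(mean(fg$mask[ph$breast_support]), 0.98)
})

test_that("tiling follows the stride/overlap/clamp arithmetic", {
  g1 <- tile_image(c(49, 49), 49)
  expect_identical(nrow(g1$tiles), 1L)
  expect_identical(c(g1$tiles$row0, g1$tiles$col0), c(1L, 1L))

  g2 <- tile_image(c(74, 74), 49)
  expect_identical(g2$row_origins, c(1L, 26L))
  expect_identical(g2$overlap, 24L)

  g3 <- tile_image(c(100, 100), 49)
  expect_identical(g3$row_origins, c(1L, 26L, 51L, 52L))
  expect_identical(g3$col_origins, c(1L, 26L, 51L, 52L))

  expect_error(tile_image(c(48, 100), 49), "smaller")
})

test_that("tiles cover every pixel with the prescribed overlap", {
  set.seed(9)
  for (i in 1:12) {
    shape <- sample(49:400, 2, replace = TRUE)
    g <- tile_image(shape, 49)
    cover <- matrix(0L, shape[1], shape[2])
    for (k in seq_len(nrow(g$tiles))) {
      r <- g$tiles$row0[k]:(g$tiles$row0[k] + 48)
      c <- g$tiles$col0[k]:(g$tiles$col0[k] + 48)
      cover[r, c] <- cover[r, c] + 1L
    }
    expect_true(all(cover >= 1L))
    # consecutive non-clamped origins differ by the stride
    ro <- g$row_origins
    if (length(ro) > 2) expect_true(all(diff(head(ro, -1)) == g$stride))
    # interior pixels see redundant tiles almost everywhere: with stride 25
    # and side 49 the strips covered once per axis are isolated single-pixel
    # lines every 25 px, so their crossings (single total cover) are a
    # vanishing fraction of the interior
    if (all(shape >= 120)) {
      interior <- cover[30:(shape[1] - 30), 30:(shape[2] - 30)]
      expect_gte(mean(interior >= 2L), 0.995)
      expect_true(all(interior >= 1L))
    }
  }
})

test_that("detector screening skips all-background tiles", {
  net <- build_network(network_config(49, "valid", c(4, 4, 6, 6, 8, 8),
                                      fc_units = 8), seed = 1)
  set.seed(5)
  img <- matrix(runif(120 * 120), 120, 120)
  grid <- tile_image(dim(img), 49)

  fg_none <- matrix(FALSE, 120, 120)
  g0 <- detect_rois(net, img, grid, fg_none)
  expect_identical(sum(g0$tiles$evaluated), 0L)
  expect_true(all(!g0$tiles$flagged))

  fg_part <- matrix(FALSE, 120, 120)
  fg_part[1:40, 1:40] <- TRUE
  g1 <- detect_rois(net, img, grid, fg_part)
  touches <- purrr::map2_lgl(g1$tiles$row0, g1$tiles$col0, function(r0, c0) {
    any(fg_part[r0:(r0 + 48), c0:(c0 + 48)])
  })
  expect_identical(g1$tiles$evaluated, touches)
  expect_true(all(!g1$tiles$flagged[!g1$tiles$evaluated]))

  bad <- build_network(network_config(43, "valid", c(4, 4, 6, 6, 8, 8),
                                      fc_units = 8), seed = 1)
  expect_error(detect_rois(bad, img, grid, fg_part), "disagree")
})

test_that("segmentation uses union semantics and grows monotonically", {
  net <- build_network(network_config(49, "valid", c(4, 4, 6, 6, 8, 8),
                                      fc_units = 8), seed = 2)
  set.seed(6)
  img <- matrix(runif(120 * 120), 120, 120)
  fg <- matrix(TRUE, 120, 120)
  grid <- tile_image(dim(img), 49)

  none <- grid; none$tiles$flagged <- FALSE
  expect_true(all(segment_rois(net, img, none, fg) == 0L))

  one <- grid; one$tiles$flagged <- FALSE
  one$tiles$flagged[1] <- TRUE
  m1 <- segment_rois(net, img, one, fg)

  # flagging an overlapping tile pair classifies shared pixels once: the
  # result on the union must agree with the single-tile mask inside tile 1
  two <- grid; two$tiles$flagged <- FALSE
  two$tiles$flagged[c(1, 2)] <- TRUE
  m2 <- segment_rois(net, img, two, fg)
  r1 <- 1:49; c1 <- 1:49
  expect_identical(m2[r1, c1], m1[r1, c1])
  # monotonicity: adding a flagged tile never removes positives
  expect_true(all(m2[m1 == 1L] == 1L))
})

test_that("the full pipeline is deterministic and respects its invariants", {
  ph <- small_phantom(seed = 13, n_mcs = 4, side = 160)
  det <- build_network(network_config(49, "valid", c(4, 4, 6, 6, 8, 8),
                                      fc_units = 8), seed = 3)
  seg <- build_network(network_config(49, "valid", c(4, 4, 6, 6, 8, 8),
                                      fc_units = 8), seed = 4)
  res1 <- run_pipeline(det, seg, ph$image)
  res2 <- run_pipeline(det, seg, ph$image)
  expect_identical(res1$mask, res2$mask)
  expect_identical(res1$grid$tiles$flagged, res2$grid$tiles$flagged)
  if (sum(res1$grid$tiles$flagged) == 0) {
    expect_identical(sum(res1$mask), 0L)
  }
  # positives only inside flagged tiles and the Otsu foreground
  inside <- matrix(FALSE, 160, 160)
  ft <- res1$grid$tiles[res1$grid$tiles$flagged, ]
  for (k in seq_len(nrow(ft))) {
    inside[ft$row0[k]:(ft$row0[k] + 48), ft$col0[k]:(ft$col0[k] + 48)] <- TRUE
  }
  expect_true(all(inside[res1$mask == 1L]))
  expect_true(all(res1$fg$mask[res1$mask == 1L]))

  # a detector that never fires yields an empty mask
  mute <- det
  mute$params$fc2$W[] <- 0
  mute$params$fc2$b <- c(10, -10)
  res3 <- run_pipeline(mute, seg, ph$image)
  expect_identical(sum(res3$grid$tiles$flagged), 0L)
  expect_identical(sum(res3$mask), 0L)
})
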