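test_that("the four-class taxonomy follows the centre-distance rules", {
  w <- matrix(0L, 49, 49)
  expect_identical(classify_patch(w), "C4")

  w1 <- w; w1[25, 25] <- 1L
  expect_identical(classify_patch(w1), "C1")

  w2 <- w; w2[27, 25] <- 1L  # offset (2, 0) from the centre
  expect_identical(classify_patch(w2), "C2")

  w2b <- w; w2b[25, 28] <- 1L  # distance exactly 3
  expect_identical(classify_patch(w2b), "C2")

  w3 <- w; w3[27, 28] <- 1L  # distance sqrt(13) > 3
  expect_identical(classify_patch(w3), "C3")

  wc <- w; wc[1, 1] <- 1L    # peripheral corner pixel
  expect_identical(classify_patch(wc), "C3")

  expect_error(classify_patch(matrix(0L, 8, 8)), "odd")
  expect_error(classify_patch(matrix(2L, 9, 9)), "binary")
})

test_that("indexed classes equal brute-force window classification", {
  ph <- small_phantom(seed = 11, n_mcs = 6)
  fg <- otsu_foreground(ph$image)
  idx <- build_patch_index(ph$image, ph$mask, 49, fg, image_id = "p")
  # every eligible centre is an Otsu-foreground pixel and classes partition
  expect_identical(nrow(idx), sum(fg$mask))
  expect_true(all(idx$patch_class %in% c("C1", "C2", "C3", "C4")))
  expect_true(all(idx$detector_label >= idx$segmentator_label))

  set.seed(1)
  sel <- idx[sample(nrow(idx), 400), ]
  padm <- pad_reflect(ph$mask, 24)
  oracle <- vapply(seq_len(nrow(sel)), function(i) {
    classify_patch(padm[sel$row[i]:(sel$row[i] + 48),
                        sel$col[i]:(sel$col[i] + 48)])
  }, "")
  expect_identical(oracle, sel$patch_class)
})

test_that("degenerate masks index as expected", {
  img <- matrix(runif(81 * 81), 81, 81)
  zero <- matrix(0L, 81, 81)
  fg <- matrix(TRUE, 81, 81)
  idx <- build_patch_index(img, zero, 9, fg)
  expect_true(all(idx$patch_class == "C4"))

  one <- zero; one[40, 41] <- 1L
  idx1 <- build_patch_index(img, one, 49, fg)
  c1 <- idx1[idx1$patch_class == "C1", ]
  expect_identical(nrow(c1), 1L)
  expect_identical(c(c1$row, c1$col), c(40L, 41L))

  expect_error(build_patch_index(img, zero, 9, matrix(FALSE, 81, 81)),
               "no pixels")
})

test_that("dihedral augmentation is a group action that fixes the class", {
  p <- matrix(rnorm(81), 9, 9)
  expect_identical(augment_patch(p, transform_id = 0), p)

  r <- p
  for (i in 1:4) r <- augment_patch(r, transform_id = 1)
  expect_identical(r, p)

  set.seed(42)
  for (rep in 1:25) {
    m <- matrix(rbinom(81, 1, 0.15), 9, 9)
    cls <- classify_patch(m)
    for (tid in 0:7) {
      out <- augment_patch(p, m, transform_id = tid)
      expect_identical(classify_patch(out$label_window), cls)
      expect_identical(dim(out$patch), dim(p))
    }
  }
  expect_error(augment_patch(matrix(0, 2, 3), transform_id = 1), "square")
})

test_that("minibatches are exactly balanced, augmented and reproducible", {
  ds <- generate_dataset(phantom_configs(2, seed = 70, image_height = 96,
                                         image_width = 96, n_mcs = 4,
                                         mc_diameter_range = c(3, 7)),
                         c(0.5, 0.5, 0))
  db <- patch_db(ds, N = 9)
  for (k in 1:10) {
    mb <- sample_minibatch(db, "detector", 64, rng_state = k)
    expect_identical(sum(mb$y["positive", ]), 32)
    expect_identical(sum(mb$y["negative", ]), 32)
  }
  mb1 <- sample_minibatch(db, "segmentator", 32, rng_state = 99)
  mb2 <- sample_minibatch(db, "segmentator", 32, rng_state = 99)
  expect_identical(mb1$x, mb2$x)
  expect_identical(mb1$records, mb2$records)
  expect_true(all(mb1$patch_class[mb1$y["positive", ] == 1] == "C1"))

  mb3 <- sample_minibatch(db, "segmentator", 32, rng_state = 100)
  expect_false(identical(mb3$records, mb1$records))

  expect_error(sample_minibatch(db, "detector", 33, rng_state = 1), "even")
  expect_error(sample_minibatch(db, "detector", 64, rng_state = 1,
                                split = "test"),
               class = "mcseg_empty_pool")
})

test_that("sampling within a class is uniform (chi-square at alpha 0.01)", {
  ds <- generate_dataset(phantom_configs(1, seed = 80, image_height = 96,
                                         image_width = 96, n_mcs = 3,
                                         mc_diameter_range = c(4, 7)),
                         c(1, 0, 0))
  db <- patch_db(ds, N = 9)
  pos <- db$records[db$records$segmentator_label, ]
  draws <- character(0)
  for (k in 1:200) {
    mb <- sample_minibatch(db, "segmentator", 100, rng_state = 1000 + k)
    pos_rec <- mb$records[mb$y["positive", ] == 1, ]
    draws <- c(draws, paste(pos_rec$row, pos_rec$col))
  }
  counts <- table(factor(draws, levels = paste(pos$row, pos$col)))
  expect_identical(sum(counts), 200L * 50L)
  p <- suppressWarnings(stats::chisq.test(as.vector(counts)))$p.value
  expect_gt(p, 0.01)
})

test_that("patch records round-trip through the SQLite database", {
  ds <- generate_dataset(phantom_configs(2, seed = 90, image_height = 96,
                                         image_width = 96, n_mcs = 3,
                                         mc_diameter_range = c(3, 6)),
                         c(0.5, 0, 0.5))
  db <- patch_db(ds, N = 9)
  path <- withr::local_tempfile(fileext = ".db")
  write_patch_db(db, path)
  back <- read_patch_db(path, ds)
  expect_identical(back$N, db$N)
  key <- function(r) r[order(r$image_id, r$row, r$col), ]
  expect_equal(as.data.frame(key(back$records)),
               as.data.frame(key(db$records)))
})

test_that("subsampling caps records per image and class", {
  ds <- generate_dataset(phantom_configs(2, seed = 95, image_height = 96,
                                         image_width = 96, n_mcs = 3,
                                         mc_diameter_range = c(3, 6)),
                         c(0.5, 0.5, 0))
  db <- subsample_patch_db(patch_db(ds, N = 9), 25, seed = 4)
  counts <- dplyr::count(db$records, image_id, patch_class)
  expect_true(all(counts$n <= 25))
})
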