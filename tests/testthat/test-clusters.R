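test_that("component labelling matches the union-find oracle", {
  m <- matrix(0L, 9, 9)
  expect_identical(nrow(label_components(m)), 0L)

  # two pixels touching only diagonally
  d <- matrix(0L, 5, 5); d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_identical(nrow(label_components(d, 8)), 1L)
  expect_identical(nrow(label_components(d, 4)), 2L)

  set.seed(21)
  for (i in 1:30) {
    msk <- matrix(rbinom(400, 1, 0.25), 20, 20)
    for (conn in c(4, 8)) {
      got <- nrow(label_components(msk, conn))
      expect_identical(got, oracle_components(msk, conn))
    }
  }
  expect_error(label_components(matrix(2L, 3, 3)), "binary")
})

test_that("object geometry is reported correctly", {
  m <- matrix(0L, 10, 10)
  m[2:3, 2:4] <- 1L          # 6-pixel rectangle
  m[8, 9] <- 1L              # singleton
  objs <- label_components(m)
  expect_identical(nrow(objs), 2L)
  expect_identical(sum(objs$n_pixels), sum(m))
  rect <- objs[objs$n_pixels == 6, ]
  expect_equal(rect$centroid_row, 2.5)
  expect_equal(rect$centroid_col, 3)
  expect_identical(c(rect$row_min, rect$row_max, rect$col_min, rect$col_max),
                   c(2L, 3L, 2L, 4L))
  # centroid lies inside the bounding box
  expect_true(all(objs$centroid_row >= objs$row_min &
                    objs$centroid_row <= objs$row_max))
})

test_that("the density rule needs strictly more than five MCs per cm^2", {
  # 0.05 mm spacing -> 1 cm = 200 px windows
  mk <- function(n) {
    tibble::tibble(centroid_row = seq(100, 180, length.out = n),
                   centroid_col = seq(120, 190, length.out = n))
  }
  rep6 <- detect_clusters(mk(6), c(400, 400), 0.05, exact = TRUE)
  expect_identical(rep6$window_side, 200L)
  expect_identical(nrow(rep6$regions), 1L)
  expect_identical(rep6$regions$mc_count, 6L)

  rep5 <- detect_clusters(mk(5), c(400, 400), 0.05, exact = TRUE)
  expect_identical(nrow(rep5$regions), 0L)

  rep0 <- detect_clusters(mk(6)[0, ], c(400, 400), 0.05)
  expect_identical(nrow(rep0$regions), 0L)
  expect_identical(nrow(rep0$objects), 0L)
})

test_that("exact sliding windows equal the exhaustive oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:14, 1)
    objs <- tibble::tibble(centroid_row = runif(n, 1, 120),
                           centroid_col = runif(n, 1, 120))
    rep <- detect_clusters(objs, c(120, 120), 0.25, threshold = 3,
                           exact = TRUE)
    ora <- oracle_cluster_windows(objs, c(120, 120), w = 40, threshold = 3)
    got <- rep$qualifying[order(rep$qualifying$row0, rep$qualifying$col0), ]
    if (nrow(ora$qualifying) > 0) {
      ord <- order(ora$qualifying[, 1], ora$qualifying[, 2])
      expect_identical(cbind(got$row0, got$col0, got$count),
                       unname(ora$qualifying[ord, , drop = FALSE]))
      expect_identical(nrow(rep$regions), ora$n_regions)
    } else {
      expect_identical(nrow(got), 0L)
    }
  }
})

test_that("coarser window steps may miss clusters but never invent them", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(8:16, 1)
    objs <- tibble::tibble(centroid_row = runif(n, 1, 150),
                           centroid_col = runif(n, 1, 150))
    exact <- detect_clusters(objs, c(150, 150), 0.25, threshold = 3,
                             exact = TRUE)
    coarse <- detect_clusters(objs, c(150, 150), 0.25, threshold = 3,
                              step = 7)
    key <- function(q) paste(q$row0, q$col0)
    expect_true(all(key(coarse$qualifying) %in% key(exact$qualifying)))
    if (nrow(coarse$regions) > 0) {
      expect_gt(nrow(exact$regions), 0L)
    }
  }
})

test_that("cluster detection is translation-equivariant", {
  objs <- tibble::tibble(centroid_row = c(30, 32, 35, 38, 40, 42),
                         centroid_col = c(50, 52, 55, 57, 59, 60))
  a <- detect_clusters(objs, c(200, 200), 0.25, exact = TRUE)
  shifted <- dplyr::mutate(objs, centroid_row = centroid_row + 11,
                           centroid_col = centroid_col + 23)
  b <- detect_clusters(shifted, c(200, 200), 0.25, exact = TRUE)
  expect_identical(nrow(a$regions), nrow(b$regions))
  expect_identical(b$regions$row_min - a$regions$row_min, 11L)
  expect_identical(b$regions$col_min - a$regions$col_min, 23L)
  expect_identical(a$regions$mc_count, b$regions$mc_count)
})

test_that("adding a centroid never removes a qualifying window", {
  set.seed(51)
  objs <- tibble::tibble(centroid_row = runif(9, 20, 100),
                         centroid_col = runif(9, 20, 100))
  base <- detect_clusters(objs, c(150, 150), 0.25, threshold = 3,
                          exact = TRUE)
  more <- detect_clusters(dplyr::bind_rows(objs, tibble::tibble(
    centroid_row = 60, centroid_col = 60)), c(150, 150), 0.25,
    threshold = 3, exact = TRUE)
  key <- function(q) paste(q$row0, q$col0)
  expect_true(all(key(base$qualifying) %in% key(more$qualifying)))
})

test_that("cluster reports serialize to JSON and CSV", {
  objs <- tibble::tibble(centroid_row = seq(40, 70, length.out = 6),
                         centroid_col = seq(40, 70, length.out = 6))
  rep <- detect_clusters(objs, c(300, 300), 0.05, exact = FALSE, step = 10)
  json <- withr::local_tempfile(fileext = ".json")
  prefix <- withr::local_tempfile()
  write_cluster_report(rep, json, prefix)
  payload <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_identical(payload$window_side_px, rep$window_side)
  expect_identical(nrow(payload$regions), nrow(rep$regions))
  expect_true(file.exists(paste0(prefix, "_objects.csv")))
  expect_true(file.exists(paste0(prefix, "_regions.csv")))
})
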