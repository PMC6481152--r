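#' Classify a mask window into the four-class patch taxonomy
#'
#' A patch is labelled by the position of microcalcification pixels relative
#' to its centre: `C1` if the central pixel itself belongs to an MC, `C2` if
#' the centre is background but an MC pixel lies within `c2_radius_px`
#' (Euclidean) of it, `C3` if MC pixels are present in the window but only
#' peripherally, and `C4` if the window contains no MC at all. The detector
#' treats C1-C3 as positive (an MC is present somewhere in the patch); the
#' segmentator treats only C1 as positive (the centre pixel is MC).
#'
#' @param mask_window square binary matrix with odd side.
#' @param c2_radius_px distance threshold separating C2 from C3 (default 3
#'   pixels; the 1-2 px shell around the centre is folded into C2 so that the
#'   four classes partition all windows).
#' @return one of `"C1"`, `"C2"`, `"C3"`, `"C4"`.
#' @export
classify_patch <- function(mask_window, c2_radius_px = 3) {
  if (!is.matrix(mask_window) || nrow(mask_window) != ncol(mask_window)) {
    abort("mask_window must be a square matrix")
  }
  n <- nrow(mask_window)
  if (n %% 2 == 0) abort("mask_window side must be odd")
  assert_mask(mask_window, "mask_window")
  ctr <- (n + 1) / 2
  if (mask_window[ctr, ctr] == 1) return("C1")
  pos <- which(mask_window == 1, arr.ind = TRUE)
  if (nrow(pos) == 0) return("C4")
  dmin <- min(sqrt((pos[, 1] - ctr)^2 + (pos[, 2] - ctr)^2))
  if (dmin <= c2_radius_px + 1e-9) "C2" else "C3"
}

# exact Euclidean disc kernel: 1 where the offset length is <= radius
disc_kernel <- function(radius) {
  k <- floor(radius)
  off <- -k:k
  d <- sqrt(outer(off^2, off^2, "+"))
  matrix(as.numeric(d <= radius + 1e-9), 2 * k + 1, 2 * k + 1)
}

#' Index all eligible patch centres of one image
#'
#' One record is created for every pixel of the Otsu foreground (windows are
#' completed by reflect padding at image borders, so border pixels are
#' eligible). The patch class is computed for all centres at once with exact
#' Euclidean disc / box dilations of the reflect-padded mask, which is
#' equivalent to calling [classify_patch()] on every window. Records store
#' coordinates only; pixels are re-read from the source image at sampling
#' time.
#'
#' @param image numeric intensity matrix.
#' @param mask 0/1 ground-truth matrix of the same shape.
#' @param N odd patch side, at least 9.
#' @param foreground logical/0-1 matrix of eligible centres (from
#'   [otsu_foreground()]).
#' @param c2_radius_px see [classify_patch()].
#' @param image_id identifier stored with each record.
#' @return tibble with columns `image_id`, `row`, `col`, `patch_class`,
#'   `detector_label`, `segmentator_label`.
#' @export
build_patch_index <- function(image, mask, N, foreground, c2_radius_px = 3,
                              image_id = "image") {
  assert_image(image)
  assert_mask(mask)
  assert_same_shape(image, mask)
  if (N %% 2 == 0 || N < 9) abort("N must be odd and >= 9")
  fg <- foreground
  if (inherits(fg, "foreground_mask")) fg <- fg$mask
  fg <- fg > 0
  assert_same_shape(image, fg, c("image", "foreground"))
  if (!any(fg)) abort("foreground contains no pixels")

  k <- (N - 1) / 2
  padm <- pad_reflect(mask, k)
  near <- as.matrix(EBImage::dilate(EBImage::Image(padm),
                                    disc_kernel(c2_radius_px)))
  present <- as.matrix(EBImage::dilate(EBImage::Image(padm),
                                       matrix(1, N, N)))
  keep <- seq_len(nrow(mask)) + k
  keepc <- seq_len(ncol(mask)) + k
  near <- near[keep, keepc] > 0
  present <- present[keep, keepc] > 0

  cls <- matrix("C4", nrow(mask), ncol(mask))
  cls[present] <- "C3"
  cls[near] <- "C2"
  cls[mask == 1] <- "C1"

  idx <- which(fg, arr.ind = TRUE)
  cl <- cls[fg]
  tibble(
    image_id = image_id,
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    patch_class = cl,
    detector_label = cl %in% c("C1", "C2", "C3"),
    segmentator_label = cl == "C1"
  )
}

#' Assemble a patch database over a phantom dataset
#'
#' Runs Otsu foreground extraction and [build_patch_index()] on every image of
#' a dataset and bundles the records with normalized, reflect-padded copies of
#' the source images for fast patch sampling.
#'
#' @param dataset tibble from [generate_dataset()] (or [read_dataset()]).
#' @param N odd patch side.
#' @param c2_radius_px see [classify_patch()].
#' @return object of class `patch_db`: list with `records` (tibble including
#'   `split`), `N`, `c2_radius_px`, and named lists `images`, `masks`,
#'   `padded` (z-scored, reflect-padded images).
#' @export
patch_db <- function(dataset, N, c2_radius_px = 3) {
  if (nrow(dataset) == 0) abort("dataset is empty")
  k <- (N - 1) / 2
  recs <- purrr::pmap(
    list(dataset$image, dataset$mask, dataset$image_id, dataset$split),
    function(img, msk, id, split) {
      fg <- otsu_foreground(img)
      build_patch_index(img, msk, N, fg, c2_radius_px, image_id = id) |>
        dplyr::mutate(split = split)
    }) |>
    dplyr::bind_rows()
  images <- rlang::set_names(dataset$image, dataset$image_id)
  masks <- rlang::set_names(dataset$mask, dataset$image_id)
  padded <- purrr::map(images, function(img) pad_reflect(normalize_image(img), k))
  structure(list(records = recs, N = as.integer(N),
                 c2_radius_px = c2_radius_px,
                 images = images, masks = masks, padded = padded),
            class = "patch_db")
}

#' @export
print.patch_db <- function(x, ...) {
  cat(sprintf("<patch_db> N = %d, %d records over %d image(s)\n",
              x$N, nrow(x$records), length(x$images)))
  print(class_counts(x))
  invisible(x)
}

#' Tabulate patch counts by class and split
#'
#' @param db a `patch_db`.
#' @return tibble with one row per split and one column per class.
#' @export
class_counts <- function(db) {
  db$records |>
    dplyr::count(.data$split, .data$patch_class) |>
    tidyr::pivot_wider(names_from = "patch_class", values_from = "n",
                       values_fill = 0L)
}

#' Subsample a patch database, capping records per image and class
#'
#' Training a patch classifier does not need every eligible centre (a
#' 256 x 256 phantom yields tens of thousands of C4 records); this keeps at
#' most `n_per_class` records per image and class, drawn uniformly.
#'
#' @param db a `patch_db`.
#' @param n_per_class cap per (image, class): either one number applied to
#'   every class or a named vector like `c(C1 = 50, C2 = 50, C3 = 50,
#'   C4 = 150)`, which lets the retained pool mirror the strong natural
#'   imbalance of the full index (C4 vastly outnumbers the other classes).
#' @param seed integer seed.
#' @return a `patch_db` with thinned records.
#' @export
subsample_patch_db <- function(db, n_per_class, seed = 1L) {
  caps <- if (length(n_per_class) == 1) {
    c(C1 = n_per_class, C2 = n_per_class, C3 = n_per_class, C4 = n_per_class)
  } else {
    stopifnot(all(c("C1", "C2", "C3", "C4") %in% names(n_per_class)))
    n_per_class
  }
  recs <- withr::with_seed(seed, {
    db$records |>
      dplyr::group_by(.data$image_id, .data$patch_class) |>
      dplyr::group_modify(function(g, key) {
        dplyr::slice_sample(g, n = min(nrow(g), caps[[key$patch_class]]))
      }) |>
      dplyr::ungroup()
  })
  db$records <- recs
  db
}

#' Apply one of the eight dihedral symmetries to a patch
#'
#' The transforms are the four right-angle rotations optionally composed with
#' a horizontal flip (`transform_id` 0-7; 0 is the identity). Image and label
#' window are transformed identically, and because patches have odd side the
#' centre pixel is fixed, so the patch class is invariant.
#'
#' @param patch square numeric matrix.
#' @param label_window optional square matrix transformed identically.
#' @param transform_id integer 0-7.
#' @return the transformed patch, or a list `(patch, label_window)` when a
#'   label window is supplied.
#' @export
augment_patch <- function(patch, label_window = NULL, transform_id) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch)) {
    abort("patch must be a square matrix")
  }
  if (!transform_id %in% 0:7) abort("transform_id must be in 0..7")
  tf <- function(m) {
    for (i in seq_len(transform_id %% 4)) m <- t(m[nrow(m):1, , drop = FALSE])
    if (transform_id >= 4) m <- m[, ncol(m):1, drop = FALSE]
    m
  }
  if (is.null(label_window)) return(tf(patch))
  if (!is.matrix(label_window) || !identical(dim(label_window), dim(patch))) {
    abort("label_window must match the patch dimensions")
  }
  list(patch = tf(patch), label_window = tf(label_window))
}

#' Extract one N x N patch centred on a pixel (reflect-padded at borders)
#'
#' @param image numeric matrix.
#' @param row,col centre coordinates (1-based).
#' @param N odd patch side.
#' @return an `N x N` matrix.
#' @export
extract_patch <- function(image, row, col, N) {
  if (N %% 2 == 0) abort("N must be odd")
  k <- (N - 1) / 2
  padded <- pad_reflect(image, k)
  padded[row:(row + N - 1), col:(col + N - 1)]
}

# fast path: pull many patches out of the pre-padded images of a patch_db
gather_patches <- function(db, recs, transform_id = NULL) {
  N <- db$N
  x <- array(0, dim = c(N, N, nrow(recs)))
  for (id in unique(recs$image_id)) {
    sel <- which(recs$image_id == id)
    cube <- cpp_extract_patches(db$padded[[id]],
                                as.integer(recs$row[sel]),
                                as.integer(recs$col[sel]), N)
    x[, , sel] <- cube
  }
  if (!is.null(transform_id)) {
    for (i in seq_along(transform_id)) {
      if (transform_id[i] != 0) {
        x[, , i] <- augment_patch(x[, , i], transform_id = transform_id[i])
      }
    }
  }
  x
}

role_label <- function(records, network_role) {
  switch(network_role,
         detector = records$detector_label,
         segmentator = records$segmentator_label,
         abort("network_role must be 'detector' or 'segmentator'"))
}

#' Sample a balanced, augmented minibatch from a patch database
#'
#' Draws exactly `batch_size / 2` positive and `batch_size / 2` negative
#' patches for the requested network role, uniformly from the records of the
#' requested split (without replacement inside a batch whenever the pool is
#' large enough; across batches draws are independent, so minibatches are
#' always different). Every patch receives a random dihedral augmentation.
#' Deterministic given `rng_state`.
#'
#' @param db a `patch_db`.
#' @param network_role `"detector"` (positive = C1, C2, C3) or
#'   `"segmentator"` (positive = C1).
#' @param batch_size even number of patches.
#' @param rng_state integer seed driving record selection and augmentation.
#' @param split which split to draw from (default `"train"`).
#' @return object of class `minibatch`: list with `x` (`N x N x batch_size`
#'   array of normalized intensities), `y` (`2 x batch_size` one-hot matrix,
#'   row 1 = negative, row 2 = positive), `patch_class` (provenance),
#'   `transform_id`, `role`.
#' @export
sample_minibatch <- function(db, network_role, batch_size, rng_state,
                             split = "train") {
  if (batch_size %% 2 != 0 || batch_size < 2) abort("batch_size must be even and >= 2")
  recs <- db$records[db$records$split == split, ]
  lab <- role_label(recs, network_role)
  ipos_all <- which(lab)
  ineg_all <- which(!lab)
  if (length(ipos_all) == 0 || length(ineg_all) == 0) {
    abort(sprintf("no %s records for role '%s' in split '%s'",
                  if (length(ipos_all) == 0) "positive" else "negative",
                  network_role, split),
          class = "mcseg_empty_pool")
  }
  half <- batch_size / 2
  sel <- withr::with_seed(rng_state, {
    ipos <- sample(ipos_all, half, replace = half > length(ipos_all))
    ineg <- sample(ineg_all, half, replace = half > length(ineg_all))
    tid <- sample(0:7, batch_size, replace = TRUE)
    list(idx = c(ipos, ineg), tid = tid)
  })
  chosen <- recs[sel$idx, ]
  x <- gather_patches(db, chosen, transform_id = sel$tid)
  y <- rbind(negative = as.numeric(seq_len(batch_size) > half),
             positive = as.numeric(seq_len(batch_size) <= half))
  structure(list(x = x, y = y, patch_class = chosen$patch_class,
                 transform_id = sel$tid, role = network_role,
                 records = chosen[, c("image_id", "row", "col")]),
            class = "minibatch")
}

#' Build a fixed evaluation patch set
#'
#' Validation/test pools are balanced either per label (equal positives and
#' negatives for the role) or per class (equal C1-C4 counts, capped by the
#' rarest class); both variants are reported by the evaluation module since
#' either reading of "balanced" is defensible.
#'
#' @param db a `patch_db`.
#' @param network_role `"detector"` or `"segmentator"`.
#' @param n target number of patches (rounded down to a multiple of the
#'   number of strata).
#' @param split split to draw from.
#' @param balance `"label"` or `"class"`.
#' @param seed integer seed.
#' @return a `minibatch` (no augmentation applied).
#' @export
make_eval_set <- function(db, network_role, n = 256, split = "validation",
                          balance = c("label", "class"), seed = 1L) {
  balance <- match.arg(balance)
  recs <- db$records[db$records$split == split, ]
  if (nrow(recs) == 0) abort(sprintf("split '%s' has no records", split))
  chosen <- withr::with_seed(seed, {
    if (balance == "label") {
      lab <- role_label(recs, network_role)
      half <- floor(n / 2)
      npos <- min(half, sum(lab))
      nneg <- min(half, sum(!lab))
      if (npos == 0 || nneg == 0) abort("both labels must be present",
                                        class = "mcseg_empty_pool")
      rbind(recs[sample(which(lab), npos), ], recs[sample(which(!lab), nneg), ])
    } else {
      per <- min(floor(n / 4), min(table(recs$patch_class)))
      if (per == 0) abort("every class must be present", class = "mcseg_empty_pool")
      recs |>
        dplyr::group_by(.data$patch_class) |>
        dplyr::slice_sample(n = per) |>
        dplyr::ungroup()
    }
  })
  lab <- role_label(chosen, network_role)
  x <- gather_patches(db, chosen)
  y <- rbind(negative = as.numeric(!lab), positive = as.numeric(lab))
  structure(list(x = x, y = y, patch_class = chosen$patch_class,
                 transform_id = rep(0L, nrow(chosen)), role = network_role,
                 records = chosen[, c("image_id", "row", "col")]),
            class = "minibatch")
}

#' Persist patch records to a SQLite database file
#'
#' Writes the coordinate/class records to a single-file relational database
#' (table `patches(image_id, row, col, class, split)` with an index on
#' `(split, class)`, plus a `meta` table holding `N` and `c2_radius_px`).
#' Pixel data stay in the source images.
#'
#' @param db a `patch_db`.
#' @param path file path for the SQLite database.
#' @return `path`, invisibly.
#' @export
write_patch_db <- function(db, path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  recs <- db$records |>
    dplyr::select("image_id", "row", "col", class = "patch_class", "split")
  DBI::dbWriteTable(con, "patches", as.data.frame(recs), overwrite = TRUE)
  DBI::dbExecute(con, "CREATE INDEX idx_split_class ON patches(split, class)")
  DBI::dbWriteTable(con, "meta",
                    data.frame(N = db$N, c2_radius_px = db$c2_radius_px),
                    overwrite = TRUE)
  invisible(path)
}

#' Load patch records from SQLite and re-attach source images
#'
#' @param path SQLite file written by [write_patch_db()].
#' @param dataset the dataset tibble providing the images/masks referenced by
#'   the records.
#' @return a `patch_db`.
#' @export
read_patch_db <- function(path, dataset) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  recs <- as_tibble(DBI::dbReadTable(con, "patches"))
  meta <- DBI::dbReadTable(con, "meta")
  recs <- recs |>
    dplyr::rename(patch_class = "class") |>
    dplyr::mutate(
      row = as.integer(.data$row), col = as.integer(.data$col),
      detector_label = .data$patch_class %in% c("C1", "C2", "C3"),
      segmentator_label = .data$patch_class == "C1") |>
    dplyr::select("image_id", "row", "col", "patch_class",
                  "detector_label", "segmentator_label", "split")
  k <- (meta$N - 1) / 2
  images <- rlang::set_names(dataset$image, dataset$image_id)
  masks <- rlang::set_names(dataset$mask, dataset$image_id)
  padded <- purrr::map(images, function(img) pad_reflect(normalize_image(img), k))
  structure(list(records = recs, N = as.integer(meta$N),
                 c2_radius_px = meta$c2_radius_px,
                 images = images, masks = masks, padded = padded),
            class = "patch_db")
}
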