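#' Otsu foreground extraction
#'
#' Thresholds the intensity histogram (256 bins) at the value maximizing the
#' between-class variance and keeps the pixels above it; on a mammogram-like
#' image this separates the breast from the dark background so that
#' background pixels can be excluded from all further evaluation.
#'
#' @param image numeric intensity matrix with at least two distinct values.
#' @return object of class `foreground_mask`: list with `mask` (logical
#'   matrix) and `threshold` (intensity value on the image scale).
#' @export
otsu_foreground <- function(image) {
  assert_image(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    abort("cannot threshold a constant image (no intensity split exists)",
          class = "mcseg_no_split")
  }
  x01 <- (image - lo) / (hi - lo)
  thr01 <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1), levels = 256)
  thr <- lo + thr01 * (hi - lo)
  structure(list(mask = image > thr, threshold = thr),
            class = "foreground_mask")
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf("<foreground_mask> threshold %.4g, %d / %d pixels foreground\n",
              x$threshold, sum(x$mask), length(x$mask)))
  invisible(x)
}

axis_origins <- function(extent, N) {
  stride <- N - floor(N / 2)
  o <- seq(1L, extent - N + 1L, by = stride)
  if (max(o) + N - 1L < extent) o <- c(o, extent - N + 1L)
  as.integer(o)
}

#' Overlapped tiling of an image
#'
#' Tiles of side `N` are laid out with stride `N - floor(N/2)`, i.e.
#' consecutive tiles overlap by `floor(N/2)` pixels along each axis (24 px
#' for N = 49). A final tile per axis is clamped flush to the image edge so
#' that every pixel is covered; the overlap gives redundant looks at every
#' interior pixel, limiting detection misses.
#'
#' @param image_shape integer length-2 (rows, cols).
#' @param N odd tile side.
#' @return object of class `tile_grid`: list with `N`, `stride`, `overlap`,
#'   `row_origins`, `col_origins` (1-based) and `tiles` (tibble: `tile_id`,
#'   `row0`, `col0`, `flagged`, `evaluated`).
#' @export
tile_image <- function(image_shape, N) {
  if (length(image_shape) != 2) abort("image_shape must be (rows, cols)")
  if (any(image_shape < N)) abort(sprintf("image smaller than one %d x %d tile", N, N))
  ro <- axis_origins(image_shape[1], N)
  co <- axis_origins(image_shape[2], N)
  tiles <- tidyr::expand_grid(row0 = ro, col0 = co) |>
    dplyr::mutate(tile_id = dplyr::row_number(), flagged = NA,
                  evaluated = FALSE, .before = 1)
  structure(list(N = as.integer(N), stride = as.integer(N - floor(N / 2)),
                 overlap = as.integer(floor(N / 2)),
                 image_shape = as.integer(image_shape),
                 row_origins = ro, col_origins = co, tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d tiles of %d px (stride %d, overlap %d) on %d x %d\n",
              nrow(x$tiles), x$N, x$stride, x$overlap,
              x$image_shape[1], x$image_shape[2]))
  if (!all(is.na(x$tiles$flagged))) {
    cat(sprintf("  evaluated %d, flagged %d\n", sum(x$tiles$evaluated),
                sum(x$tiles$flagged, na.rm = TRUE)))
  }
  invisible(x)
}

#' Screen tiles with the detector network
#'
#' Tiles whose pixels are entirely background are marked negative without a
#' network evaluation; the remaining tiles are classified in one batched
#' forward pass. Decisions are deterministic given the weights.
#'
#' @param detector trained `mc_cnn` with role-compatible patch side.
#' @param image intensity matrix (unnormalized; per-image z-scoring is
#'   applied internally).
#' @param grid a [tile_image()] grid with matching `N`.
#' @param fg a [otsu_foreground()] result (or logical matrix).
#' @param threshold posterior cut for flagging (default 0.5; ties go
#'   negative).
#' @return the grid with `tiles$flagged` and `tiles$evaluated` filled in.
#' @export
detect_rois <- function(detector, image, grid, fg, threshold = 0.5) {
  if (grid$N != detector$config$N) abort("grid and detector disagree on N")
  fgm <- if (inherits(fg, "foreground_mask")) fg$mask else fg > 0
  assert_same_shape(image, fgm, c("image", "foreground"))
  norm <- normalize_image(image)
  N <- grid$N
  tiles <- grid$tiles
  has_fg <- purrr::map2_lgl(tiles$row0, tiles$col0, function(r0, c0) {
    any(fgm[r0:(r0 + N - 1), c0:(c0 + N - 1)])
  })
  tiles$flagged <- FALSE
  tiles$evaluated <- has_fg
  if (any(has_fg)) {
    idx <- which(has_fg)
    x <- array(0, dim = c(N, N, length(idx)))
    for (i in seq_along(idx)) {
      r0 <- tiles$row0[idx[i]]; c0 <- tiles$col0[idx[i]]
      x[, , i] <- norm[r0:(r0 + N - 1), c0:(c0 + N - 1)]
    }
    pred <- predict_patches(detector, x)
    tiles$flagged[idx] <- pred$p_positive > threshold
  }
  grid$tiles <- tiles
  grid
}

#' Segment flagged regions of interest pixel by pixel
#'
#' Every foreground pixel lying in at least one flagged tile is classified
#' exactly once (union semantics over overlapping tiles) by the segmentator,
#' using the `N x N` patch centred on it; patches crossing the image border
#' are completed by reflect padding. Pixels outside all flagged tiles, and
#' background pixels, are 0 in the returned mask.
#'
#' @param segmentator trained `mc_cnn`.
#' @param image intensity matrix.
#' @param flagged a `tile_grid` with decisions (from [detect_rois()]).
#' @param fg foreground mask.
#' @param threshold posterior cut for a positive pixel (default 0.5).
#' @param chunk pixels per forward pass.
#' @return a 0/1 integer matrix, the predicted MC mask.
#' @export
segment_rois <- function(segmentator, image, flagged, fg, threshold = 0.5,
                         chunk = 2048L) {
  if (flagged$N != segmentator$config$N) {
    abort("tile grid and segmentator disagree on N")
  }
  fgm <- if (inherits(fg, "foreground_mask")) fg$mask else fg > 0
  assert_same_shape(image, fgm, c("image", "foreground"))
  N <- flagged$N
  mask <- matrix(0L, nrow(image), ncol(image))
  ft <- flagged$tiles[which(flagged$tiles$flagged), ]
  if (nrow(ft) == 0) return(mask)

  sel <- matrix(FALSE, nrow(image), ncol(image))
  for (i in seq_len(nrow(ft))) {
    r <- ft$row0[i]:(ft$row0[i] + N - 1)
    c <- ft$col0[i]:(ft$col0[i] + N - 1)
    sel[r, c] <- sel[r, c] | fgm[r, c]
  }
  centers <- which(sel, arr.ind = TRUE)
  if (nrow(centers) == 0) return(mask)

  k <- (N - 1) / 2
  padded <- pad_reflect(normalize_image(image), k)
  for (start in seq(1, nrow(centers), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(centers))
    x <- cpp_extract_patches(padded, as.integer(centers[idx, 1]),
                             as.integer(centers[idx, 2]), N)
    pred <- predict_patches(segmentator, x, chunk = chunk)
    pos <- idx[pred$p_positive > threshold]
    mask[centers[pos, , drop = FALSE]] <- 1L
  }
  mask
}

#' Run the full two-stage pipeline on one image
#'
#' Composition of Otsu foreground extraction, overlapped tiling, detector
#' screening of the tiles and per-pixel segmentation of the flagged regions,
#' returning the predicted microcalcification mask together with the
#' intermediate products and bookkeeping statistics.
#'
#' @param detector,segmentator trained `mc_cnn` models sharing the same `N`.
#' @param image intensity matrix.
#' @param threshold posterior cut used by both stages.
#' @return object of class `mc_segmentation`: list with `mask`, `grid`, `fg`
#'   and `stats` (tibble: tiles, evaluated, flagged, positive pixels,
#'   runtime seconds).
#' @export
run_pipeline <- function(detector, segmentator, image, threshold = 0.5) {
  if (detector$config$N != segmentator$config$N) {
    abort("detector and segmentator must share the same patch side N")
  }
  t0 <- proc.time()[["elapsed"]]
  fg <- otsu_foreground(image)
  grid <- tile_image(dim(image), detector$config$N)
  grid <- detect_rois(detector, image, grid, fg, threshold)
  mask <- segment_rois(segmentator, image, grid, fg, threshold)
  stats <- tibble(
    n_tiles = nrow(grid$tiles),
    n_evaluated = sum(grid$tiles$evaluated),
    n_flagged = sum(grid$tiles$flagged),
    n_positive_px = sum(mask),
    runtime_s = proc.time()[["elapsed"]] - t0)
  structure(list(mask = mask, grid = grid, fg = fg, stats = stats),
            class = "mc_segmentation")
}

#' @export
print.mc_segmentation <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<mc_segmentation> %d/%d tiles flagged (%d evaluated), %d positive px, %.2fs\n",
    s$n_flagged, s$n_tiles, s$n_evaluated, s$n_positive_px, s$runtime_s))
  invisible(x)
}

#' Write a predicted mask and a JSON sidecar of pipeline statistics
#'
#' @param result an `mc_segmentation`.
#' @param mask_path output PNG (mask stored as 0/255).
#' @param json_path optional sidecar path (default: mask path with
#'   `.json`).
#' @return `mask_path`, invisibly.
#' @export
write_segmentation <- function(result, mask_path,
                               json_path = sub("\\.png$", ".json", mask_path)) {
  png::writePNG(result$mask * 1.0, mask_path)
  side <- c(list(threshold = result$fg$threshold),
            as.list(result$stats),
            list(flagged_tiles = result$grid$tiles[
              which(result$grid$tiles$flagged), c("row0", "col0")]))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(mask_path)
}
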