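#' Label connected microcalcification objects in a binary mask
#'
#' Standard connected-component decomposition (8-connectivity by default, so
#' diagonally touching pixels belong to one object) with component ids
#' contiguous from 1 in raster order; centroids are the arithmetic means of
#' the member pixel coordinates.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return tibble with one row per object: `id`, `n_pixels`, `centroid_row`,
#'   `centroid_col`, `row_min`, `row_max`, `col_min`, `col_max`. The label
#'   matrix is attached as attribute `"labels"`.
#' @export
label_components <- function(mask, connectivity = 8) {
  assert_mask(mask)
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                              as.integer(connectivity))
  n <- max(lab)
  if (n == 0) {
    out <- tibble(id = integer(), n_pixels = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  row_min = integer(), row_max = integer(),
                  col_min = integer(), col_max = integer())
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  out <- tibble(id = ids, row = idx[, 1], col = idx[, 2]) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      centroid_row = mean(.data$row), centroid_col = mean(.data$col),
      row_min = min(.data$row), row_max = max(.data$row),
      col_min = min(.data$col), col_max = max(.data$col)) |>
    dplyr::arrange(.data$id)
  attr(out, "labels") <- lab
  out
}

#' Identify microcalcification clusters by the radiological density rule
#'
#' A square window of physical side 10 mm (200 px at 0.05 mm/pixel) slides
#' over the image; a window is a cluster candidate when strictly more than
#' `threshold` (default 5) distinct MC centroids fall inside it, following
#' the radiological definition of more than 5 MCs per square centimetre.
#' Overlapping qualifying windows are merged into maximal cluster regions
#' reported as bounding boxes. An object counts toward a window iff its
#' centroid lies inside.
#'
#' @param objects tibble from [label_components()] (or any tibble with
#'   `centroid_row`/`centroid_col`).
#' @param image_shape integer (rows, cols).
#' @param pixel_spacing_mm pixel size; the window side is
#'   `round(10 / pixel_spacing_mm)` pixels.
#' @param step window step in pixels (default 25); `exact = TRUE` forces
#'   step 1, the exhaustive scan. Coarser steps can only miss clusters,
#'   never invent them.
#' @param threshold strict count threshold (`> threshold` qualifies).
#' @param exact logical, evaluate every window origin.
#' @return object of class `cluster_report`: list with `objects`, `regions`
#'   (tibble: `region_id`, `row_min`, `col_min`, `row_max`, `col_max`,
#'   `n_windows`, `mc_count`), `qualifying` (tibble of window origins and
#'   counts), `pixel_spacing_mm`, `window_side`, `threshold`, `step`.
#' @export
detect_clusters <- function(objects, image_shape, pixel_spacing_mm,
                            step = 25L, threshold = 5L, exact = FALSE) {
  if (pixel_spacing_mm <= 0) abort("pixel_spacing_mm must be positive")
  if (exact) step <- 1L
  w <- as.integer(round(10 / pixel_spacing_mm))
  H <- image_shape[1]; W <- image_shape[2]
  empty <- tibble(region_id = integer(), row_min = integer(),
                  col_min = integer(), row_max = integer(),
                  col_max = integer(), n_windows = integer(),
                  mc_count = integer())
  mk <- function(regions, qual) {
    structure(list(objects = objects, regions = regions, qualifying = qual,
                   pixel_spacing_mm = pixel_spacing_mm, window_side = w,
                   threshold = threshold, step = as.integer(step)),
              class = "cluster_report")
  }
  qual0 <- tibble(row0 = integer(), col0 = integer(), count = integer())
  if (nrow(objects) == 0) return(mk(empty, qual0))

  ro <- window_origins(H, w, step)
  co <- window_origins(W, w, step)
  # count centroids per window: a centroid at (r, c) is inside windows with
  # origin in [r - w + 1, r]; accumulate rectangles on the origin grid
  counts <- matrix(0L, length(ro), length(co))
  for (i in seq_len(nrow(objects))) {
    rin <- which(ro >= objects$centroid_row[i] - w + 1 &
                   ro <= objects$centroid_row[i])
    cin <- which(co >= objects$centroid_col[i] - w + 1 &
                   co <= objects$centroid_col[i])
    counts[rin, cin] <- counts[rin, cin] + 1L
  }
  qidx <- which(counts > threshold, arr.ind = TRUE)
  if (nrow(qidx) == 0) return(mk(empty, qual0))
  qual <- tibble(row0 = ro[qidx[, 1]], col0 = co[qidx[, 2]],
                 count = counts[qidx])

  # merge overlapping qualifying windows: components of the pixel union
  cov <- matrix(0L, H, W)
  for (i in seq_len(nrow(qual))) {
    cov[qual$row0[i]:min(qual$row0[i] + w - 1, H),
        qual$col0[i]:min(qual$col0[i] + w - 1, W)] <- 1L
  }
  lab <- cpp_label_components(cov, 8L)
  qual$region_id <- lab[cbind(qual$row0, qual$col0)]

  cen_reg <- lab[cbind(pmin(pmax(round(objects$centroid_row), 1), H),
                       pmin(pmax(round(objects$centroid_col), 1), W))]
  regions <- qual |>
    dplyr::group_by(region_id = .data$region_id) |>
    dplyr::summarise(
      row_min = min(.data$row0), col_min = min(.data$col0),
      row_max = min(max(.data$row0) + w - 1L, H),
      col_max = min(max(.data$col0) + w - 1L, W),
      n_windows = dplyr::n()) |>
    dplyr::mutate(mc_count = purrr::map_int(
      .data$region_id, function(id) sum(cen_reg == id, na.rm = TRUE))) |>
    dplyr::arrange(.data$region_id) |>
    dplyr::mutate(region_id = dplyr::row_number())
  mk(regions, qual[, c("row0", "col0", "count")])
}

window_origins <- function(extent, w, step) {
  last <- max(1L, extent - w + 1L)
  o <- seq(1L, last, by = step)
  if (max(o) < last) o <- c(o, last)
  as.integer(o)
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "<cluster_report> %d MC object(s); %d cluster region(s) (window %d px = 10 mm, > %d MCs)\n",
    nrow(x$objects), nrow(x$regions), x$window_side, x$threshold))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Write a cluster report as JSON and CSV tables
#'
#' @param report a `cluster_report`.
#' @param json_path output JSON path.
#' @param csv_prefix optional prefix; writes `<prefix>_objects.csv` and
#'   `<prefix>_regions.csv`.
#' @return `json_path`, invisibly.
#' @export
write_cluster_report <- function(report, json_path, csv_prefix = NULL) {
  payload <- list(
    pixel_spacing_mm = report$pixel_spacing_mm,
    window_side_px = report$window_side,
    threshold = report$threshold,
    objects = report$objects,
    regions = report$regions)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_prefix)) {
    write.csv(report$objects, paste0(csv_prefix, "_objects.csv"),
              row.names = FALSE)
    write.csv(report$regions, paste0(csv_prefix, "_regions.csv"),
              row.names = FALSE)
  }
  invisible(json_path)
}

#' Plot MC objects and detected cluster regions
#'
#' @param object a `cluster_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cluster_report <- function(object, ...) {
  p <- ggplot2::ggplot(object$objects,
                       ggplot2::aes(x = .data$centroid_col,
                                    y = .data$centroid_row)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row")
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$col_min, xmax = .data$col_max,
                   ymin = .data$row_min, ymax = .data$row_max),
      inherit.aes = FALSE, colour = "red", fill = NA)
  }
  p
}
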