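#' Configuration for a synthetic mammogram phantom
#'
#' Describes one phantom: a breast-shaped region with textured tissue over a
#' dark background, into which small high-intensity blobs (microcalcifications,
#' MCs) are injected with a pixel-exact ground-truth mask. Defaults emulate a
#' scaled-down digital mammogram at 0.05 mm/pixel: MC diameters of 3-12 px
#' correspond to 0.15-0.6 mm lesions, and contrasts are fractions of the local
#' tissue intensity so that MCs are locally bright but not saturated.
#'
#' @param image_height,image_width phantom size in pixels.
#' @param pixel_spacing_mm physical pixel size (mm/pixel).
#' @param n_mcs number of microcalcifications to inject.
#' @param mc_diameter_range length-2 numeric, MC diameter bounds in pixels.
#' @param mc_contrast_range length-2 numeric, peak added intensity as a
#'   fraction of the local background intensity.
#' @param mc_shape_irregularity scalar in `[0, 1]`; 0 gives near-elliptical
#'   blobs, larger values produce increasingly irregular contours.
#' @param n_clusters number of spatial clusters; 0 places MCs uniformly over
#'   the breast interior.
#' @param cluster_radius_px maximal distance of a clustered MC from its
#'   cluster centre.
#' @param tissue_texture_scale correlation length (pixels) of the smoothed
#'   random field used as tissue texture.
#' @param noise_sigma standard deviation of additive white noise (intensity
#'   units on the `[0, 1]` scale); raise it to mimic the widespread noise of
#'   digitized film.
#' @param seed integer seed; the same configuration always generates the same
#'   phantom, bit for bit.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 256L, image_width = 256L,
                           pixel_spacing_mm = 0.05, n_mcs = 12L,
                           mc_diameter_range = c(3, 12),
                           mc_contrast_range = c(0.25, 0.75),
                           mc_shape_irregularity = 0.3,
                           n_clusters = 0L, cluster_radius_px = 60,
                           tissue_texture_scale = 12, noise_sigma = 0.01,
                           seed = 1L) {
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_spacing_mm = pixel_spacing_mm,
    n_mcs = as.integer(n_mcs),
    mc_diameter_range = as.numeric(mc_diameter_range),
    mc_contrast_range = as.numeric(mc_contrast_range),
    mc_shape_irregularity = mc_shape_irregularity,
    n_clusters = as.integer(n_clusters),
    cluster_radius_px = cluster_radius_px,
    tissue_texture_scale = tissue_texture_scale,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  )
  if (cfg$image_height < 32 || cfg$image_width < 32) {
    abort("phantom images must be at least 32 x 32 pixels")
  }
  if (cfg$pixel_spacing_mm <= 0) abort("pixel_spacing_mm must be positive")
  if (cfg$n_mcs < 0) abort("n_mcs must be non-negative")
  if (length(cfg$mc_diameter_range) != 2 ||
      any(cfg$mc_diameter_range <= 0) ||
      diff(cfg$mc_diameter_range) < 0) {
    abort("mc_diameter_range must be an increasing positive pair")
  }
  if (max(cfg$mc_diameter_range) >= min(cfg$image_height, cfg$image_width) / 4) {
    abort("largest MC diameter must be below a quarter of the image side")
  }
  if (any(cfg$mc_contrast_range <= 0) || diff(cfg$mc_contrast_range) < 0) {
    abort("mc_contrast_range must be an increasing positive pair")
  }
  if (cfg$mc_shape_irregularity < 0 || cfg$mc_shape_irregularity > 1) {
    abort("mc_shape_irregularity must lie in [0, 1]")
  }
  if (cfg$tissue_texture_scale <= 0 || cfg$noise_sigma < 0 ||
      cfg$cluster_radius_px <= 0) {
    abort("texture scale and cluster radius must be positive; noise_sigma >= 0")
  }
  structure(cfg, class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "<phantom_config> %d x %d px @ %.3g mm/px, %d MCs (d %.3g-%.3g px), %d cluster(s), seed %d\n",
    x$image_height, x$image_width, x$pixel_spacing_mm, x$n_mcs,
    x$mc_diameter_range[1], x$mc_diameter_range[2], x$n_clusters, x$seed))
  invisible(x)
}

# smoothed angular wobble used to deform blob contours; amplitude <= 0.35*irr
# so the deformed radius stays within [0.74, 1.54] of nominal
blob_wobble <- function(phi, irregularity) {
  a <- runif(3)
  a <- a / sum(a)
  psi <- runif(3, 0, 2 * pi)
  w <- 0
  for (m in 1:3) w <- w + a[m] * sin((m + 1) * phi + psi[m])
  0.35 * irregularity * w
}

#' Generate a synthetic mammogram phantom with ground-truth MC mask
#'
#' Builds a half-elliptical breast region against the left image edge with a
#' smoothed tissue-to-background transition, adds low-pass-filtered random
#' texture (emulating the variability of connective, glandular and adipose
#' tissue) and white noise, then injects `n_mcs` bright blobs: thresholded
#' anisotropic Gaussian bumps whose contour is warped by the irregularity
#' parameter, with a sub-threshold shoulder giving soft contours. Every mask
#' pixel is exactly the set where the warped radial coordinate is below the
#' contour threshold, so masks are pixel-exact by construction.
#'
#' @param config a [phantom_config()].
#' @return a list of class `mc_phantom` with elements `image` (numeric matrix
#'   in `[0, 1]`), `mask` (0/1 integer matrix of the same shape),
#'   `pixel_spacing_mm`, `breast_support` (logical matrix of the hard breast
#'   ellipse), `mc_info` (tibble: row, col, diameter_px, contrast, cluster)
#'   and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  H <- cfg$image_height
  W <- cfg$image_width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)

  # half-ellipse anchored to the left edge
  cr <- (H + 1) / 2
  ar <- 0.46 * H
  ac <- 0.82 * W
  val <- ((rr - cr) / ar)^2 + ((cc - 1) / ac)^2
  support <- val <= 1

  # smooth tissue-to-background transition + gentle chest-wall gradient
  edge <- stats::plogis((1 - val) * 120)
  base <- 0.35 + 0.25 * pmax(1 - val, 0)^0.5

  noise <- matrix(rnorm(H * W), H, W)
  texture <- as.matrix(EBImage::gblur(EBImage::Image(noise),
                                      sigma = cfg$tissue_texture_scale / 3))
  texture <- 0.06 * texture / stats::sd(texture)

  img <- edge * (base + texture) + 0.015
  if (cfg$noise_sigma > 0) img <- img + cfg$noise_sigma * matrix(rnorm(H * W), H, W)

  mask <- matrix(0L, H, W)
  placed <- tibble(row = integer(), col = integer(), diameter_px = numeric(),
                   contrast = numeric(), cluster = integer())

  cluster_centers <- NULL
  if (cfg$n_mcs > 0 && cfg$n_clusters > 0) {
    cluster_centers <- place_points(
      n = cfg$n_clusters, val = val, margin = max(cfg$mc_diameter_range) + 6,
      H = H, W = W, min_sep = 0, retries = 400)
  }

  if (cfg$n_mcs > 0) {
    diam <- runif(cfg$n_mcs, cfg$mc_diameter_range[1], cfg$mc_diameter_range[2])
    ctr <- runif(cfg$n_mcs, cfg$mc_contrast_range[1], cfg$mc_contrast_range[2])
    for (k in seq_len(cfg$n_mcs)) {
      margin <- ceiling(0.8 * diam[k]) + 4
      cl <- if (is.null(cluster_centers)) 0L else ((k - 1L) %% cfg$n_clusters) + 1L
      pos <- NULL
      for (try in seq_len(200)) {
        if (cl > 0L) {
          ang <- runif(1, 0, 2 * pi)
          rad <- cfg$cluster_radius_px * sqrt(runif(1))
          r0 <- round(cluster_centers$row[cl] + rad * sin(ang))
          c0 <- round(cluster_centers$col[cl] + rad * cos(ang))
        } else {
          r0 <- sample.int(H, 1)
          c0 <- sample.int(W, 1)
        }
        if (r0 <= margin || r0 > H - margin || c0 <= margin || c0 > W - margin) next
        if (val[r0, c0] > 0.8) next
        if (nrow(placed) > 0) {
          sep <- 0.8 * (placed$diameter_px + diam[k]) + 2
          d <- sqrt((placed$row - r0)^2 + (placed$col - c0)^2)
          if (any(d < sep)) next
        }
        pos <- c(r0, c0)
        break
      }
      if (is.null(pos)) {
        abort(
          sprintf("could not place MC %d without overlap after 200 retries", k),
          class = "mcseg_placement_error")
      }
      blob <- render_blob(img, pos[1], pos[2], diam[k], ctr[k],
                          cfg$mc_shape_irregularity)
      img <- blob$image
      mask[blob$rows, blob$cols][blob$inside] <- 1L
      placed <- dplyr::bind_rows(placed, tibble(
        row = pos[1], col = pos[2], diameter_px = diam[k],
        contrast = ctr[k], cluster = cl))
    }
  }

  img[img < 0] <- 0
  img[img > 1] <- 1

  structure(list(
    image = img, mask = mask, pixel_spacing_mm = cfg$pixel_spacing_mm,
    breast_support = support, mc_info = placed, config = cfg
  ), class = "mc_phantom")
}

# rejection-sample points in the breast interior
place_points <- function(n, val, margin, H, W, min_sep, retries) {
  rows <- integer(0); cols <- integer(0)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(retries)) {
      r0 <- sample.int(H, 1); c0 <- sample.int(W, 1)
      if (r0 <= margin || r0 > H - margin || c0 <= margin || c0 > W - margin) next
      if (val[r0, c0] > 0.7) next
      if (min_sep > 0 && length(rows) > 0 &&
          any(sqrt((rows - r0)^2 + (cols - c0)^2) < min_sep)) next
      rows <- c(rows, r0); cols <- c(cols, c0); ok <- TRUE
      break
    }
    if (!ok) abort("could not place cluster centre inside the breast interior",
                   class = "mcseg_placement_error")
  }
  tibble(row = rows, col = cols)
}

# add one blob to the image and return its mask footprint; the footprint is
# star-shaped around the centre (the warped radius is monotone along each
# direction) hence always a single connected component
render_blob <- function(img, r0, c0, diameter, contrast, irregularity) {
  R <- ceiling(0.8 * diameter) + 4
  rows <- (r0 - R):(r0 + R)
  cols <- (c0 - R):(c0 + R)
  theta <- runif(1, 0, pi)
  q <- runif(1, 0.65, 1)            # axis ratio
  soft <- runif(1, 0.45, 0.75)      # shoulder width: larger = softer contour
  ra <- diameter / 2
  rb <- q * diameter / 2

  dr <- matrix(rows - r0, length(rows), length(cols))
  dc <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
  u <- cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  rho <- sqrt((u / ra)^2 + (v / rb)^2)
  phi <- atan2(dc, dr)
  rho_eff <- rho * (1 + blob_wobble(phi, irregularity))

  inside <- rho_eff <= 1
  local_bg <- mean(img[rows, cols])
  bump <- contrast * local_bg * exp(-rho_eff^2 / (2 * soft^2))
  img[rows, cols] <- img[rows, cols] + bump
  list(image = img, rows = rows, cols = cols, inside = inside)
}

#' Build a list of phantom configurations with consecutive seeds
#'
#' @param n number of phantoms.
#' @param seed seed of the first phantom; phantom `i` uses `seed + i - 1`.
#' @param ... passed on to [phantom_config()].
#' @return list of `phantom_config` objects.
#' @export
phantom_configs <- function(n, seed = 1L, ...) {
  purrr::map(seq_len(n), function(i) phantom_config(seed = seed + i - 1L, ...))
}

#' Generate a labelled phantom dataset with an image-level split
#'
#' Generates one phantom per configuration and partitions the images (never
#' individual patches) into train/validation/test so that no image contributes
#' samples to two splits.
#'
#' @param config_list list of [phantom_config()] objects.
#' @param split_fractions length-3 numeric summing to 1 (train, validation,
#'   test); counts are apportioned by largest remainder.
#' @return a tibble with columns `image_id`, `split`, `seed`,
#'   `pixel_spacing_mm` and list-columns `image`, `mask`, `breast_support`,
#'   `mc_info`.
#' @export
generate_dataset <- function(config_list, split_fractions = c(0.8, 0.1, 0.1)) {
  if (length(config_list) == 0) abort("config_list must not be empty")
  if (length(split_fractions) != 3 || abs(sum(split_fractions) - 1) > 1e-8 ||
      any(split_fractions < 0)) {
    abort("split_fractions must be three non-negative numbers summing to 1")
  }
  n <- length(config_list)
  counts <- floor(split_fractions * n)
  rem <- split_fractions * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[order_rem] <- counts[order_rem] + 1
  }
  split <- rep(c("train", "validation", "test"), times = counts)

  phantoms <- purrr::map(config_list, generate_phantom)
  tibble(
    image_id = sprintf("phantom_%03d", seq_len(n)),
    split = split,
    seed = purrr::map_int(config_list, "seed"),
    pixel_spacing_mm = purrr::map_dbl(config_list, "pixel_spacing_mm"),
    image = purrr::map(phantoms, "image"),
    mask = purrr::map(phantoms, "mask"),
    breast_support = purrr::map(phantoms, "breast_support"),
    mc_info = purrr::map(phantoms, "mc_info")
  )
}

#' Write a phantom dataset to disk
#'
#' Images are written as 16-bit grayscale TIFF, masks as 8-bit PNG (0/255),
#' plus a `manifest.csv` (image_id, image_path, mask_path, split, seed,
#' pixel_spacing_mm).
#'
#' @param dataset a tibble from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- dataset |>
    dplyr::mutate(
      image_path = file.path(dir, paste0(.data$image_id, ".tif")),
      mask_path = file.path(dir, paste0(.data$image_id, "_mask.png"))
    )
  purrr::pwalk(list(manifest$image, manifest$image_path), function(img, p) {
    tiff::writeTIFF(img, p, bits.per.sample = 16L)
  })
  purrr::pwalk(list(manifest$mask, manifest$mask_path), function(m, p) {
    png::writePNG(m * 1.0, p)
  })
  out <- manifest |>
    dplyr::select("image_id", "image_path", "mask_path", "split", "seed",
                  "pixel_spacing_mm")
  write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return a tibble with the same image/mask list-columns as
#'   [generate_dataset()] (without `breast_support`/`mc_info`, which are not
#'   serialized).
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  as_tibble(man) |>
    dplyr::mutate(
      image = purrr::map(.data$image_path, function(p) {
        img <- tiff::readTIFF(p)
        if (length(dim(img)) == 3) img <- img[, , 1]
        img
      }),
      mask = purrr::map(.data$mask_path, function(p) {
        m <- png::readPNG(p)
        if (length(dim(m)) == 3) m <- m[, , 1]
        matrix(as.integer(m > 0.5), nrow(m), ncol(m))
      })
    )
}

#' @export
print.mc_phantom <- function(x, ...) {
  cat(sprintf(
    "<mc_phantom> %d x %d px @ %.3g mm/px, %d MC pixels in %d lesion(s)\n",
    nrow(x$image), ncol(x$image), x$pixel_spacing_mm, sum(x$mask),
    nrow(x$mc_info)))
  invisible(x)
}

#' Plot a phantom (or any image/mask pair) as a ggplot raster
#'
#' @param object an `mc_phantom`.
#' @param show_mask overlay ground-truth MC pixels in red.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mc_phantom <- function(object, show_mask = TRUE, ...) {
  # row varies fastest, matching R's column-major as.vector()
  df <- tidyr::expand_grid(col = seq_len(ncol(object$image)),
                           row = seq_len(nrow(object$image)))
  df$intensity <- as.vector(object$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "I")
  if (show_mask && sum(object$mask) > 0) {
    idx <- which(object$mask == 1L, arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = tibble(row = idx[, 1], col = idx[, 2]),
      ggplot2::aes(x = .data$col, y = .data$row), inherit.aes = FALSE,
      colour = "red", size = 0.1)
  }
  p
}
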