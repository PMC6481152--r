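# shared fixtures and independent oracles

# small, cheap network configuration for unit tests
tiny_config <- function(N = 13, padding = "same") {
  network_config(N = N, padding_mode = padding,
                 conv_filters = c(4L, 4L, 8L, 8L, 8L, 8L), fc_units = 16L)
}

small_phantom <- function(seed = 1, n_mcs = 7, side = 160) {
  generate_phantom(phantom_config(
    image_height = side, image_width = side, n_mcs = n_mcs,
    mc_diameter_range = c(3, 9), seed = seed))
}

# independent connected-components oracle: union of pixel-adjacency edges
# via igraph, nothing shared with the package's flood fill
oracle_components <- function(mask, connectivity = 8) {
  idx <- which(mask == 1, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  key <- paste(idx[, 1], idx[, 2])
  lookup <- stats::setNames(seq_len(n), key)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- paste(idx[, 1] + offs[k, 1], idx[, 2] + offs[k, 2])
    hit <- !is.na(lookup[nb])
    edges <- c(edges, rbind(seq_len(n)[hit], lookup[nb[hit]]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$no)
}

# exhaustive Otsu oracle: scan every histogram threshold, compute the
# between-class variance, and report the variance achieved by splitting at
# `thr` together with the global maximum. Several thresholds can attain the
# maximum exactly (empty bins between modes form a tie plateau), so the
# check is membership in the argmax plateau, not equality with one
# particular tie-break.
oracle_otsu_variance <- function(image, thr, levels = 256) {
  lo <- min(image); hi <- max(image)
  x <- (image - lo) / (hi - lo)
  bin <- pmin(pmax(ceiling(x * levels), 1), levels)
  p <- tabulate(bin, nbins = levels) / length(x)
  mids <- (seq_len(levels) - 0.5) / levels
  v <- rep(NA_real_, levels - 1)
  for (t in 1:(levels - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v[t] <- w0 * w1 * (mu0 - mu1)^2
  }
  thr01 <- (thr - lo) / (hi - lo)
  # the returned threshold is a bin midpoint, which sits between the two
  # histogram splits floor and floor+1; the induced split is one of them
  t_lo <- min(max(floor(thr01 * levels), 1), levels - 1)
  t_hi <- min(t_lo + 1, levels - 1)
  list(at_thr = max(v[t_lo], v[t_hi], na.rm = TRUE),
       max = max(v, na.rm = TRUE))
}

# brute-force cluster-window oracle: evaluate every origin, then merge
# overlapping qualifying windows with an igraph over pairwise overlaps
oracle_cluster_windows <- function(objects, image_shape, w, threshold) {
  ro <- 1:max(1, image_shape[1] - w + 1)
  co <- 1:max(1, image_shape[2] - w + 1)
  qual <- list()
  for (r0 in ro) {
    inr <- objects$centroid_row >= r0 & objects$centroid_row <= r0 + w - 1
    if (sum(inr) <= threshold) next
    for (c0 in co) {
      cnt <- sum(inr & objects$centroid_col >= c0 &
                   objects$centroid_col <= c0 + w - 1)
      if (cnt > threshold) qual[[length(qual) + 1]] <- c(r0, c0, cnt)
    }
  }
  if (length(qual) == 0) {
    return(list(qualifying = matrix(numeric(0), ncol = 3), n_regions = 0L))
  }
  q <- do.call(rbind, qual)
  n <- nrow(q)
  adj <- which(outer(q[, 1], q[, 1], function(a, b) abs(a - b) < w) &
                 outer(q[, 2], q[, 2], function(a, b) abs(a - b) < w),
               arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(adj))
  list(qualifying = q, n_regions = as.integer(igraph::components(g)$no))
}

make_minibatch_pool <- function(x, classes, role) {
  list(x = x, patch_class = classes, role = role)
}
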