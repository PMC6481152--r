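#' Spatial side of the last convolutional feature map
#'
#' Tracks the patch side through the shared detector/segmentator architecture:
#' six 3x3 stride-1 convolutions with a 2x2 max-pool (floor division on odd
#' sides) after convolutions 1 and 2. A `valid` convolution shrinks the side
#' by 2, a `same` convolution preserves it. For the published 49 x 49 valid
#' configuration the recurrence is 49 > 47 > 23 > 21 > 10 > 8 > 6 > 4 > 2, so
#' 2 x 2 features enter the first fully connected layer.
#'
#' @param N odd input patch side, at least 9.
#' @param padding_mode `"same"` or `"valid"`.
#' @return integer side length after the convolutional stack.
#' @export
feature_map_side <- function(N, padding_mode = c("valid", "same")) {
  padding_mode <- match.arg(padding_mode)
  if (N %% 2 == 0 || N < 9) abort("N must be odd and >= 9")
  s <- N
  for (l in 1:6) {
    if (padding_mode == "valid") {
      if (s < 3) {
        abort(sprintf(
          "invalid config: feature map side %d underflows at conv %d (needs >= 3)",
          s, l), class = "mcseg_invalid_config")
      }
      s <- s - 2
    }
    if (l <= 2) {
      s <- floor(s / 2)
      if (s < 1) {
        abort(sprintf(
          "invalid config: feature map side underflows at pool %d", l),
          class = "mcseg_invalid_config")
      }
    }
  }
  if (s < 1) abort("invalid config: empty feature map", class = "mcseg_invalid_config")
  as.integer(s)
}

#' Network architecture configuration
#'
#' The detector and the segmentator share one architecture: six 3x3 stride-1
#' convolutions (max-pool 2x2 after the first and second), two fully
#' connected layers of 64 and K = 2 units, ReLU activations, batch
#' normalization after every layer except the final one, 50% dropout on the
#' 64-unit layer, He initialization. Filter counts are configurable (they are
#' not architectural constants); the default keeps CPU training of both
#' networks on phantom data in the minutes range.
#'
#' @param N odd patch side.
#' @param padding_mode `"valid"` (unpadded, shrinking) or `"same"`
#'   (zero-padded, size-preserving) convolutions.
#' @param conv_filters integer vector of 6 filter counts.
#' @param fc_units width of the penultimate fully connected layer.
#' @param n_classes number of output classes (K = 2: negative/positive).
#' @param dropout_rate dropout probability on the FC layer.
#' @return object of class `network_config`.
#' @export
network_config <- function(N = 49L, padding_mode = c("valid", "same"),
                           conv_filters = c(16L, 16L, 32L, 32L, 64L, 64L),
                           fc_units = 64L, n_classes = 2L,
                           dropout_rate = 0.5) {
  padding_mode <- match.arg(padding_mode)
  if (length(conv_filters) != 6 || any(conv_filters < 1)) {
    abort("conv_filters must be 6 positive counts")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  side <- feature_map_side(N, padding_mode)  # validates the geometry
  structure(list(
    N = as.integer(N), padding_mode = padding_mode,
    conv_filters = as.integer(conv_filters), fc_units = as.integer(fc_units),
    n_classes = as.integer(n_classes), dropout_rate = dropout_rate,
    feat_side = side, flat_size = side^2 * as.integer(conv_filters[6])
  ), class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config> N = %d (%s), filters %s, %d x %d x %d -> FC%d -> FC%d\n",
    x$N, x$padding_mode, paste(x$conv_filters, collapse = "-"),
    x$feat_side, x$feat_side, x$conv_filters[6], x$fc_units, x$n_classes))
  invisible(x)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an untrained network
#'
#' Weights are He-initialized (Gaussian with variance 2/fan-in, the standard
#' choice for ReLU networks); batch-norm scales start at 1, offsets at 0,
#' running statistics at (0, 1). Deterministic given `seed`.
#'
#' @param config a [network_config()].
#' @param seed integer seed.
#' @return object of class `mc_cnn` with elements `config`, `params`,
#'   `bn_stats`, `history` (empty tibble), `role` (unset).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  withr::with_seed(seed, {
    fin <- c(1L, config$conv_filters[-6]) * 9L
    conv <- purrr::map(1:6, function(l) {
      f <- config$conv_filters[l]
      list(W = he_init(f, fin[l], fin[l]), b = numeric(f),
           gamma = rep(1, f), beta = numeric(f))
    })
    params <- list(
      conv = conv,
      fc1 = list(W = he_init(config$fc_units, config$flat_size, config$flat_size),
                 b = numeric(config$fc_units),
                 gamma = rep(1, config$fc_units),
                 beta = numeric(config$fc_units)),
      fc2 = list(W = he_init(config$n_classes, config$fc_units, config$fc_units),
                 b = numeric(config$n_classes))
    )
    bn <- c(purrr::map(config$conv_filters, function(f) {
      list(mean = numeric(f), var = rep(1, f))
    }), list(list(mean = numeric(config$fc_units),
                  var = rep(1, config$fc_units))))
    structure(list(config = config, params = params, bn_stats = bn,
                   history = tibble(), role = NA_character_,
                   stopped_at = NA_integer_),
              class = "mc_cnn")
  })
}

#' @export
print.mc_cnn <- function(x, ...) {
  np <- sum(purrr::map_dbl(unlist(x$params, recursive = FALSE), function(p) {
    sum(purrr::map_dbl(p, length))
  }))
  cat(sprintf("<mc_cnn> role = %s, N = %d (%s), %d parameters, %s\n",
              x$role, x$config$N, x$config$padding_mode, np,
              if (nrow(x$history)) sprintf("trained %d steps", max(x$history$step))
              else "untrained"))
  invisible(x)
}

#' Softmax posterior over the K class scores
#'
#' Maps unnormalized class scores s to posteriors
#' `p(y = l | X) = exp(s_l) / sum_k exp(s_k)`, computed with max-subtraction
#' for overflow safety (the result is invariant to adding a constant to all
#' scores).
#'
#' @param s numeric vector of finite scores, or a matrix with one score
#'   vector per column.
#' @return probabilities with the same shape as `s`; each vector is strictly
#'   positive and sums to 1.
#' @export
softmax_posterior <- function(s) {
  if (any(!is.finite(s))) abort("scores must be finite")
  if (is.matrix(s)) {
    z <- sweep(s, 2, apply(s, 2, max))
    e <- exp(z)
    return(sweep(e, 2, colSums(e), "/"))
  }
  e <- exp(s - max(s))
  e / sum(e)
}

#' Categorical cross-entropy
#'
#' `H(y, p) = -sum_j y_j log p_j` for a one-hot ground-truth vector `y` and a
#' predicted probability vector `p`; the log argument is clamped at `eps` so
#' a confident wrong prediction yields a large finite loss.
#'
#' @param y one-hot numeric vector.
#' @param y_pred probability vector of the same length.
#' @param eps clamp for the logarithm (default 1e-12).
#' @return non-negative scalar; zero iff the prediction puts mass 1 on the
#'   true class.
#' @export
crossentropy <- function(y, y_pred, eps = 1e-12) {
  if (length(y) != length(y_pred)) abort("y and y_pred must have equal length")
  if (abs(sum(y) - 1) > 1e-9 || !all(y %in% c(0, 1))) abort("y must be one-hot")
  -sum(y * log(pmax(y_pred, eps)))
}

#' Class posteriors for a batch of patches
#'
#' Runs the inference forward pass (batch-norm running statistics, no
#' dropout) in chunks. Decision rule: positive iff the positive-class
#' posterior strictly exceeds `threshold`; an exact tie goes to negative,
#' favouring specificity.
#'
#' @param model a trained `mc_cnn`.
#' @param x `N x N x B` array (or a single `N x N` matrix) of normalized
#'   patches.
#' @param chunk maximal patches per forward pass.
#' @return tibble with `p_negative`, `p_positive`, `predicted` (logical).
#' @export
predict_patches <- function(model, x, chunk = 2048L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3)
  if (dim(x)[1] != model$config$N || dim(x)[2] != model$config$N) {
    abort(sprintf("patches must be %d x %d for this model", model$config$N,
                  model$config$N))
  }
  pad <- if (model$config$padding_mode == "same") 1L else 0L
  B <- dim(x)[3]
  out <- matrix(0, 2, B)
  for (start in seq(1, B, by = chunk)) {
    idx <- start:min(start + chunk - 1, B)
    res <- cpp_net_predict(model$params, model$bn_stats,
                           x[, , idx, drop = FALSE], pad, 1e-5)
    out[, idx] <- res$prob
  }
  tibble(p_negative = out[1, ], p_positive = out[2, ],
         predicted = out[2, ] > 0.5)
}

# forward-pass oracle for the architecture arithmetic: spatial side of the
# final conv feature map actually produced by the instantiated network
forward_feat_side <- function(model) {
  x <- array(0, dim = c(model$config$N, model$config$N, 1L))
  pad <- if (model$config$padding_mode == "same") 1L else 0L
  cpp_net_predict(model$params, model$bn_stats, x, pad, 1e-5)$feat_side
}

#' Serialize a model to an HDF5 container
#'
#' All learnable parameters, batch-norm running statistics, the architecture
#' configuration and the training history are stored in one portable HDF5
#' file.
#'
#' @param model an `mc_cnn`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(model$params, path, "params")
  rhdf5::h5write(model$bn_stats, path, "bn_stats")
  cfg <- model$config
  cfg$padding_mode <- cfg$padding_mode  # character scalar, stored as-is
  rhdf5::h5write(cfg[c("N", "padding_mode", "conv_filters", "fc_units",
                       "n_classes", "dropout_rate")], path, "config")
  rhdf5::h5write(model$role, path, "role")
  if (nrow(model$history) > 0) {
    rhdf5::h5write(as.data.frame(model$history), path, "history")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load a model written by [write_model()]
#'
#' @param path HDF5 file.
#' @return an `mc_cnn`.
#' @export
read_model <- function(path) {
  raw <- rhdf5::h5read(path, "/")
  rhdf5::h5closeAll()
  cfgl <- raw$config
  config <- network_config(
    N = as.integer(cfgl$N), padding_mode = as.character(cfgl$padding_mode),
    conv_filters = as.integer(cfgl$conv_filters),
    fc_units = as.integer(cfgl$fc_units),
    n_classes = as.integer(cfgl$n_classes),
    dropout_rate = as.numeric(cfgl$dropout_rate))
  # HDF5 lists come back alphabetized; restore the canonical field order
  fix_layer <- function(p) {
    ord <- intersect(c("W", "b", "gamma", "beta"), names(p))
    purrr::map(p[ord], function(v) {
      if (is.array(v) && length(dim(v)) == 2) v else as.numeric(v)
    })
  }
  params <- list(
    conv = unname(purrr::map(raw$params$conv, fix_layer)),
    fc1 = fix_layer(raw$params$fc1),
    fc2 = fix_layer(raw$params$fc2))
  bn <- unname(purrr::map(raw$bn_stats, function(s) {
    list(mean = as.numeric(s$mean), var = as.numeric(s$var))
  }))
  history <- if (!is.null(raw$history)) as_tibble(raw$history) else tibble()
  structure(list(config = config, params = params, bn_stats = bn,
                 history = history,
                 role = as.character(raw$role), stopped_at = NA_integer_),
            class = "mc_cnn")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training history of a fitted network, one row per logged step
#'
#' @param x an `mc_cnn`.
#' @param ... unused.
#' @return tibble with `step`, `lr`, `train_loss`, `train_acc`, `val_loss`,
#'   `val_acc`.
#' @export
tidy.mc_cnn <- function(x, ...) x$history

#' One-row summary of a fitted network
#'
#' @param x an `mc_cnn`.
#' @param ... unused.
#' @return tibble with role, padding mode, steps trained, best validation
#'   loss/accuracy and the number of learning-rate halvings.
#' @export
glance.mc_cnn <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    return(tibble(role = x$role, padding_mode = x$config$padding_mode,
                  steps = 0L, best_val_loss = NA_real_,
                  best_val_acc = NA_real_, lr_halvings = 0L))
  }
  hv <- h[!is.na(h$val_loss), ]
  tibble(
    role = x$role, padding_mode = x$config$padding_mode,
    steps = max(h$step),
    best_val_loss = if (nrow(hv)) min(hv$val_loss) else NA_real_,
    best_val_acc = if (nrow(hv)) max(hv$val_acc) else NA_real_,
    lr_halvings = length(unique(h$lr)) - 1L)
}

#' Plot training curves
#'
#' @param object a trained `mc_cnn`.
#' @param ... unused.
#' @return a ggplot object (loss and accuracy vs step).
#' @export
autoplot.mc_cnn <- function(object, ...) {
  h <- object$history
  if (nrow(h) == 0) abort("model has no training history")
  long <- h |>
    dplyr::select("step", "train_loss", "val_loss", "train_acc", "val_acc") |>
    tidyr::pivot_longer(-"step", names_to = "series", values_to = "value") |>
    tidyr::drop_na() |>
    dplyr::mutate(
      metric = ifelse(grepl("loss", .data$series), "loss", "accuracy"),
      set = ifelse(grepl("train", .data$series), "train", "validation"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "step", y = NULL, colour = NULL)
}
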