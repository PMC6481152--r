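#' Per-class patch error rates and overall accuracy
#'
#' Evaluates a patch classifier on a pool of labelled patches grouped by the
#' four-class taxonomy. Under the role's label mapping (detector: C1-C3
#' positive; segmentator: C1 positive) the error rate of a class is the
#' misclassified fraction of its patches, in percent; the overall accuracy is
#' computed on the pool as given (build the pool with [make_eval_set()],
#' balanced per label or per class).
#'
#' @param model a trained `mc_cnn`, or a function `f(x_array)` returning a
#'   logical vector of positive predictions (useful for hand-built
#'   fixtures).
#' @param patches a `minibatch`-like list with elements `x` (N x N x B
#'   array), `patch_class` (character) and `role`.
#' @param role overrides `patches$role` when given.
#' @return tibble of class rows: `role`, `padding_mode`, `patch_class`, `n`,
#'   `n_wrong`, `error_pct`, plus the overall accuracy in attribute
#'   `"overall_accuracy_pct"` and as an `"overall"` row.
#' @export
patch_error_table <- function(model, patches, role = NULL) {
  role <- role %||% patches$role
  cls <- patches$patch_class
  if (!all(c("C1", "C2", "C3", "C4") %in% cls)) {
    abort("every class C1-C4 must be represented in the evaluation pool")
  }
  truth <- if (role == "detector") cls %in% c("C1", "C2", "C3") else cls == "C1"
  if (is.function(model)) {
    predicted <- model(patches$x)
    padding <- NA_character_
  } else {
    predicted <- predict_patches(model, patches$x)$predicted
    padding <- model$config$padding_mode
  }
  wrong <- predicted != truth
  per_class <- tibble(patch_class = cls, wrong = wrong) |>
    dplyr::group_by(.data$patch_class) |>
    dplyr::summarise(n = dplyr::n(), n_wrong = sum(.data$wrong)) |>
    dplyr::mutate(error_pct = 100 * .data$n_wrong / .data$n)
  overall <- 100 * (1 - mean(wrong))
  out <- per_class |>
    dplyr::mutate(role = role, padding_mode = padding, .before = 1)
  attr(out, "overall_accuracy_pct") <- overall
  out
}

#' Overall accuracy of a patch pool
#'
#' @param table a [patch_error_table()] result.
#' @return overall accuracy in percent.
#' @export
overall_accuracy <- function(table) attr(table, "overall_accuracy_pct")

#' Table of per-class error rates for both balancing conventions
#'
#' Builds label-balanced and class-balanced test pools and evaluates the
#' model on both, since "a balanced number of samples" can be read per label
#' or per class.
#'
#' @param model trained `mc_cnn`.
#' @param db a `patch_db` with a test split.
#' @param role `"detector"` or `"segmentator"`.
#' @param n pool size.
#' @param split split to evaluate on.
#' @param seed integer seed for pool sampling.
#' @return tibble combining both pools, with a `balance` column; overall
#'   accuracies in attribute `"overall"` (named vector).
#' @export
patch_error_tables <- function(model, db, role, n = 512, split = "test",
                               seed = 1L) {
  res <- purrr::map(c(label = "label", class = "class"), function(bal) {
    pool <- make_eval_set(db, role, n = n, split = split, balance = bal,
                          seed = seed)
    patch_error_table(model, pool, role = role)
  })
  out <- dplyr::bind_rows(res, .id = "balance")
  attr(out, "overall") <- purrr::map_dbl(res, overall_accuracy)
  out
}

#' Pixel-level confusion counts, accuracy and false-positive rate
#'
#' Compares a predicted MC mask against the ground truth. The false-positive
#' rate is `FP / (FP + TN) * 100` and the accuracy `(TP + TN) / total * 100`;
#' both are reported over all pixels (the headline numbers for a mostly
#' background image) and restricted to the Otsu foreground, since the
#' evaluation domain materially changes the denominators.
#'
#' @param pred predicted 0/1 mask.
#' @param truth ground-truth 0/1 mask of the same shape.
#' @param fg foreground mask (`foreground_mask` or logical matrix).
#' @return tibble with rows `all` and `foreground`: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy_pct`, `fpr_pct`.
#' @export
pixel_metrics <- function(pred, truth, fg) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_shape(pred, truth, c("pred", "truth"))
  fgm <- if (inherits(fg, "foreground_mask")) fg$mask else fg > 0
  assert_same_shape(pred, fgm, c("pred", "foreground"))
  count <- function(keep) {
    p <- pred[keep] == 1; t <- truth[keep] == 1
    tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
    tibble(tp = tp, fp = fp, tn = tn, fn = fn,
           accuracy_pct = 100 * (tp + tn) / (tp + fp + tn + fn),
           fpr_pct = if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_)
  }
  dplyr::bind_rows(
    all = count(matrix(TRUE, nrow(pred), ncol(pred))),
    foreground = count(fgm),
    .id = "domain")
}

#' Lesionwise recall
#'
#' Fraction of ground-truth MC components (8-connectivity) overlapped by at
#' least one predicted positive pixel: a per-lesion detection measure that is
#' insensitive to boundary-pixel disagreement.
#'
#' @param pred predicted 0/1 mask.
#' @param truth ground-truth 0/1 mask, or a [label_components()] tibble with
#'   the `"labels"` attribute.
#' @return value in `[0, 1]`; `NA` when the truth contains no lesion.
#' @export
lesionwise_recall <- function(pred, truth) {
  assert_mask(pred, "pred")
  if (is.matrix(truth)) truth <- label_components(truth, connectivity = 8)
  lab <- attr(truth, "labels")
  assert_same_shape(pred, lab, c("pred", "truth"))
  if (nrow(truth) == 0) return(NA_real_)
  hit <- purrr::map_lgl(truth$id, function(id) any(pred[lab == id] == 1))
  mean(hit)
}

#' Whole-image metrics over a set of phantoms
#'
#' Runs the pipeline on each image of a dataset split and aggregates pixel
#' metrics and lesionwise recall. Counts are pooled over images (a single
#' confusion matrix), recall is the fraction of all true lesions hit.
#'
#' @param detector,segmentator trained models.
#' @param dataset dataset tibble; only rows with `split == split` are used.
#' @param split which split to evaluate (default `"test"`).
#' @return list with `per_image` (tibble), `pixel` (pooled [pixel_metrics()]
#'   tibble) and `lesion_recall`.
#' @export
evaluate_pipeline <- function(detector, segmentator, dataset, split = "test") {
  rows <- dataset[dataset$split == split, ]
  if (nrow(rows) == 0) {
    abort(sprintf("no images in split '%s'; evaluation refuses to run", split))
  }
  acc <- purrr::pmap(list(rows$image, rows$mask, rows$image_id),
                     function(img, truth, id) {
    res <- run_pipeline(detector, segmentator, img)
    pm <- pixel_metrics(res$mask, truth, res$fg)
    objs <- label_components(truth)
    lab <- attr(objs, "labels")
    hits <- sum(purrr::map_lgl(objs$id, function(i) any(res$mask[lab == i] == 1)))
    list(counts = pm, image_id = id, n_lesions = nrow(objs), n_hit = hits,
         n_flagged = res$stats$n_flagged)
  })
  per_image <- purrr::map_dfr(acc, function(a) {
    allrow <- a$counts[a$counts$domain == "all", ]
    tibble(image_id = a$image_id, n_lesions = a$n_lesions, n_hit = a$n_hit,
           n_flagged = a$n_flagged, fp = allrow$fp,
           accuracy_pct = allrow$accuracy_pct, fpr_pct = allrow$fpr_pct)
  })
  pooled <- purrr::map_dfr(acc, "counts") |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(dplyr::across(c("tp", "fp", "tn", "fn"), sum)) |>
    dplyr::mutate(
      accuracy_pct = 100 * (.data$tp + .data$tn) /
        (.data$tp + .data$fp + .data$tn + .data$fn),
      fpr_pct = 100 * .data$fp / (.data$fp + .data$tn))
  list(per_image = per_image, pixel = pooled,
       lesion_recall = sum(per_image$n_hit) / sum(per_image$n_lesions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
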