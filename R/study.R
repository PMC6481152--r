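#' Run a complete phantom study: generate, train both networks, evaluate
#'
#' Orchestrates the full experiment on synthetic phantoms: generates an
#' image-level train/validation/test split, indexes patches, trains the
#' detector and the segmentator, and evaluates the two-stage pipeline on the
#' held-out phantoms. Default problem sizes (30 phantoms of 192 x 192 px,
#' roughly 5,000 training patch records after per-class capping, a few
#' hundred optimization steps per network) keep a full study on a single CPU
#' core in the minutes range while leaving the learning problem non-trivial;
#' they are deliberately far below a clinical-scale training run.
#'
#' @param seed master seed; phantom seeds, patch subsampling, network
#'   initialization and both training runs all derive from it.
#' @param n_train,n_val,n_test phantom counts per split.
#' @param phantom_args named list of overrides for [phantom_config()]; the
#'   default study images are 192 x 192 px with 8 MCs each, a lesion density
#'   far above the clinical one so that every phantom exercises all four
#'   patch classes.
#' @param N patch side.
#' @param padding_mode convolution padding for both networks.
#' @param conv_filters filter counts for both networks.
#' @param n_per_class patch records kept per image and class; the default
#'   keeps 250 records per image (5,000 over a 20-phantom training+validation
#'   pool), weighted toward C4 to echo the natural dominance of plain tissue.
#' @param detector_schedule,segmentator_schedule [train_schedule()] objects;
#'   both default to 256-sized minibatches, with the detector trained briefly
#'   (tile screening is the easier task) and the segmentator longer
#'   (per-pixel boundaries are harder).
#' @param compute_tables also compute per-class patch error tables on the
#'   test split (adds two balanced-pool evaluations).
#' @param verbose print training progress.
#' @return list with `detector`, `segmentator`, `dataset`, `db`,
#'   `evaluation` (from [evaluate_pipeline()]) and `patch_tables`
#'   (per-class error tables for both networks on the test split).
#' @export
run_phantom_study <- function(seed = 1L, n_train = 16L, n_val = 4L,
                              n_test = 10L,
                              phantom_args = list(image_height = 192L,
                                                  image_width = 192L,
                                                  n_mcs = 8L),
                              N = 49L, padding_mode = "valid",
                              conv_filters = c(8L, 8L, 24L, 24L, 48L, 48L),
                              n_per_class = c(C1 = 60L, C2 = 40L, C3 = 40L,
                                              C4 = 110L),
                              detector_schedule = NULL,
                              segmentator_schedule = NULL,
                              compute_tables = TRUE,
                              verbose = FALSE) {
  seed <- as.integer(seed)
  n <- n_train + n_val + n_test
  cfgs <- purrr::map(seq_len(n), function(i) {
    do.call(phantom_config,
            c(list(seed = (seed * 1000L + i) %% 2147483629L), phantom_args))
  })
  dataset <- generate_dataset(cfgs, c(n_train, n_val, n_test) / n)
  db <- patch_db(dataset, N = N)
  db <- subsample_patch_db(db, n_per_class, seed = seed + 17L)

  nc <- network_config(N, padding_mode, conv_filters)
  if (is.null(detector_schedule)) {
    detector_schedule <- train_schedule(
      batch_size = 256L, max_steps = 250L, eval_every = 25L,
      plateau_patience = 3L, early_stop_patience = 10L, seed = seed + 1L)
  }
  if (is.null(segmentator_schedule)) {
    segmentator_schedule <- train_schedule(
      batch_size = 256L, max_steps = 650L, eval_every = 25L,
      plateau_patience = 4L, early_stop_patience = 12L, seed = seed + 2L)
  }

  val_det <- make_eval_set(db, "detector", 512, "validation",
                           seed = seed + 3L)
  detector <- train_network(build_network(nc, seed = seed + 4L), db,
                            "detector", detector_schedule, val_det,
                            verbose = verbose)
  val_seg <- make_eval_set(db, "segmentator", 2048, "validation",
                           seed = seed + 5L)
  segmentator <- train_network(build_network(nc, seed = seed + 6L), db,
                               "segmentator", segmentator_schedule, val_seg,
                               verbose = verbose)

  evaluation <- evaluate_pipeline(detector, segmentator, dataset, "test")
  patch_tables <- NULL
  if (compute_tables) {
    patch_tables <- list(
      detector = patch_error_tables(detector, db, "detector", n = 512,
                                    split = "test", seed = seed + 7L),
      segmentator = patch_error_tables(segmentator, db, "segmentator",
                                       n = 512, split = "test",
                                       seed = seed + 8L))
  }
  list(detector = detector, segmentator = segmentator, dataset = dataset,
       db = db, evaluation = evaluation, patch_tables = patch_tables)
}
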