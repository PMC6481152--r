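#' Training schedule
#'
#' Optimization follows stochastic gradient descent with the Adam optimizer
#' on the categorical cross-entropy, minibatches of 256 balanced patches, an
#' initial learning rate of 1e-3 that is halved whenever the validation loss
#' plateaus, and early stopping that returns the weights seen before any
#' evidence of overfitting. Plateau detection is automated with a patience
#' counter on the validation loss.
#'
#' @param initial_lr initial learning rate.
#' @param batch_size even minibatch size.
#' @param max_steps maximal number of optimization steps.
#' @param eval_every validation interval in steps.
#' @param plateau_patience validation evaluations without improvement before
#'   the learning rate is multiplied by `plateau_factor`.
#' @param plateau_factor learning-rate multiplier on plateau, in (0, 1).
#' @param early_stop_patience evaluations without improvement before training
#'   stops.
#' @param min_delta minimal validation-loss decrease that counts as an
#'   improvement.
#' @param bn_momentum update rate of the batch-norm running statistics.
#' @param seed integer seed driving minibatch sampling, augmentation and
#'   dropout.
#' @return object of class `train_schedule`.
#' @export
train_schedule <- function(initial_lr = 1e-3, batch_size = 256L,
                           max_steps = 400L, eval_every = 25L,
                           plateau_patience = 5L, plateau_factor = 0.5,
                           early_stop_patience = 10L, min_delta = 1e-4,
                           bn_momentum = 0.1, seed = 1L) {
  stopifnot(initial_lr > 0, batch_size >= 2, batch_size %% 2 == 0,
            max_steps >= 1, eval_every >= 1,
            plateau_patience >= 1, plateau_factor > 0, plateau_factor < 1,
            early_stop_patience >= 1, bn_momentum > 0, bn_momentum <= 1)
  structure(list(initial_lr = initial_lr, batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 eval_every = as.integer(eval_every),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, bn_momentum = bn_momentum,
                 seed = as.integer(seed)),
            class = "train_schedule")
}

# recursive helpers over the nested parameter list
param_map <- function(p, f) {
  if (is.list(p)) purrr::map(p, param_map, f = f) else f(p)
}
param_map2 <- function(a, b, f) {
  if (is.list(a)) purrr::map2(a, b, param_map2, f = f) else f(a, b)
}
param_map3 <- function(a, b, c, f) {
  if (is.list(a)) purrr::pmap(list(a, b, c), param_map3, f = f) else f(a, b, c)
}

#' Train a detector or segmentator network
#'
#' Minibatches are balanced and augmented on the fly from the patch database
#' (see [sample_minibatch()]); every source of randomness derives from
#' `schedule$seed`, so training is fully reproducible. The validation loss is
#' monitored every `eval_every` steps: the learning rate is halved when it
#' plateaus, training stops early when it keeps rising, and the returned
#' model carries the weights of the best validation loss seen.
#'
#' @param model an untrained `mc_cnn` from [build_network()].
#' @param db a `patch_db` with training records.
#' @param role `"detector"` or `"segmentator"`.
#' @param schedule a [train_schedule()].
#' @param val_set a fixed validation `minibatch` (see [make_eval_set()]).
#' @param verbose print progress lines every evaluation.
#' @return the trained `mc_cnn`, with `history` (one row per evaluation) and
#'   `stopped_at`.
#' @export
train_network <- function(model, db, role, schedule, val_set,
                          verbose = FALSE) {
  stopifnot(inherits(model, "mc_cnn"), inherits(db, "patch_db"),
            inherits(schedule, "train_schedule"))
  if (missing(val_set) || is.null(val_set) || dim(val_set$x)[3] == 0) {
    abort("a non-empty val_set is required")
  }
  if (db$N != model$config$N) abort("db and model disagree on patch side N")
  pad <- if (model$config$padding_mode == "same") 1L else 0L
  p_drop <- model$config$dropout_rate
  fc <- model$config$fc_units
  bn_eps <- 1e-5

  params <- model$params
  bn <- model$bn_stats
  adam_m <- param_map(params, function(x) x * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  lr <- schedule$initial_lr

  best <- list(loss = Inf, params = params, bn = bn, step = 0L)
  plateau_bad <- 0L; stop_bad <- 0L
  history <- list()
  recent_loss <- c(); recent_acc <- c()
  stopped_at <- schedule$max_steps

  val_true <- apply(val_set$y, 2, which.max)

  for (step in seq_len(schedule$max_steps)) {
    rng <- (schedule$seed * 1009L + step * 7919L) %% 2147483629L
    batch <- sample_minibatch(db, role, schedule$batch_size, rng_state = rng)
    B <- dim(batch$x)[3]
    mask <- withr::with_seed((rng + 1L) %% 2147483629L, {
      if (p_drop > 0) {
        matrix((runif(fc * B) >= p_drop) / (1 - p_drop), fc, B)
      } else {
        matrix(1, fc, B)
      }
    })
    res <- cpp_net_grad(params, batch$x, batch$y, pad, mask, bn_eps)
    if (!is.finite(res$loss)) {
      abort(sprintf("training diverged at step %d (loss = %g, lr = %g)",
                    step, res$loss, lr), class = "mcseg_divergence")
    }
    recent_loss <- c(recent_loss, res$loss)
    recent_acc <- c(recent_acc, res$acc)

    # batch-norm running statistics (exponential moving average)
    bn <- purrr::map2(bn, res$bn_batch, function(run, bat) {
      list(mean = (1 - schedule$bn_momentum) * run$mean +
             schedule$bn_momentum * bat$mean,
           var = (1 - schedule$bn_momentum) * run$var +
             schedule$bn_momentum * bat$var)
    })

    # Adam
    adam_m <- param_map2(adam_m, res$grads, function(m, g) beta1 * m + (1 - beta1) * g)
    adam_v <- param_map2(adam_v, res$grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
    bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
    params <- param_map3(params, adam_m, adam_v, function(p, m, v) {
      p - lr * (m / bc1) / (sqrt(v / bc2) + adam_eps)
    })

    if (step %% schedule$eval_every == 0 || step == schedule$max_steps) {
      vp <- cpp_net_predict(params, bn, val_set$x, pad, bn_eps)$prob
      val_loss <- -mean(log(pmax(vp[cbind(val_true, seq_along(val_true))], 1e-12)))
      val_acc <- mean(apply(vp, 2, which.max) == val_true)
      history[[length(history) + 1]] <- tibble(
        step = step, lr = lr,
        train_loss = mean(recent_loss), train_acc = mean(recent_acc),
        val_loss = val_loss, val_acc = val_acc)
      recent_loss <- c(); recent_acc <- c()
      if (verbose) {
        cat(sprintf("step %4d lr %.2g train %.4f/%.3f val %.4f/%.3f\n",
                    step, lr, history[[length(history)]]$train_loss,
                    history[[length(history)]]$train_acc, val_loss, val_acc))
      }
      if (val_loss < best$loss - schedule$min_delta) {
        best <- list(loss = val_loss, params = params, bn = bn, step = step)
        plateau_bad <- 0L; stop_bad <- 0L
      } else {
        plateau_bad <- plateau_bad + 1L
        stop_bad <- stop_bad + 1L
        if (plateau_bad >= schedule$plateau_patience) {
          lr <- lr * schedule$plateau_factor
          plateau_bad <- 0L
        }
        if (stop_bad >= schedule$early_stop_patience) {
          stopped_at <- step
          break
        }
      }
    }
  }

  model$params <- best$params
  model$bn_stats <- best$bn
  model$history <- dplyr::bind_rows(history)
  model$role <- role
  model$stopped_at <- as.integer(stopped_at)
  model
}
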