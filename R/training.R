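#' Masked mean squared error over value sequences
#'
#' Per sample, the squared error is averaged over the first `M` steps
#' (where `M` is that sample's mask length); the result is the mean over
#' samples.
#'
#' @param truth,pred numeric vectors (one sample) or matrices (one sample
#'   per row).
#' @param mask 0/1 vector or matrix of the same shape.
#' @return Scalar loss.
#' @export
masked_mse <- function(truth, pred, mask) {
  if (is.null(dim(truth))) {
    truth <- matrix(truth, 1L); pred <- matrix(pred, 1L)
    mask <- matrix(mask, 1L)
  }
  per_sample <- vapply(seq_len(nrow(truth)), function(j) {
    m <- mask[j, ] > 0
    if (!any(m)) stop("empty mask for sample ", j)
    mean((truth[j, m] - pred[j, m])^2)
  }, numeric(1))
  mean(per_sample)
}

#' Categorical cross-entropy over class sequences
#'
#' Mean over samples and all time steps (unmasked, so the ended class is
#' forced on the repeated tail) of the negative log predicted probability
#' of the true class. Probabilities are clipped at `eps` before the log.
#'
#' @param truth one-hot matrix (`T x K`) or list of such matrices.
#' @param pred predicted-probability matrix (`T x K`) or list.
#' @param eps clipping floor.
#' @return Scalar loss (non-negative).
#' @export
class_ce <- function(truth, pred, eps = 1e-12) {
  if (!is.list(truth)) { truth <- list(truth); pred <- list(pred) }
  per_sample <- vapply(seq_along(truth), function(j) {
    p <- pmax(pred[[j]], eps)
    mean(-rowSums(truth[[j]] * log(p)))
  }, numeric(1))
  mean(per_sample)
}

#' Combined multitask training loss
#'
#' @param mse masked value loss.
#' @param ce class loss.
#' @param lambda class-loss weight (0.01).
#' @return `mse + lambda * ce`.
#' @export
total_loss <- function(mse, ce, lambda = 0.01) mse + lambda * ce

#' Learning-rate schedule with patience
#'
#' Improvement means a strictly lower loss than the best seen so far.
#' After `patience_decay` consecutive epochs without improvement the
#' learning rate is halved; after `patience_stop` such epochs training
#' stops. Any improvement resets the counter.
#'
#' @param losses numeric vector of per-epoch monitored losses so far.
#' @param lr0 initial learning rate.
#' @param patience_decay,patience_stop patience thresholds in epochs.
#' @return list with `lr`, `stop`, `since_improvement`.
#' @export
lr_schedule <- function(losses, lr0 = 1e-3, patience_decay = 25L,
                        patience_stop = 50L) {
  stopifnot(patience_stop > patience_decay)
  best <- Inf; since <- 0L; lr <- lr0; halt <- FALSE
  for (l in losses) {
    if (l < best) {
      best <- l; since <- 0L
    } else {
      since <- since + 1L
      if (since == patience_decay) lr <- lr * 0.5
      if (since >= patience_stop) { halt <- TRUE; break }
    }
  }
  list(lr = lr, stop = halt, since_improvement = since)
}

#' Cross-validated scenario splits
#'
#' `Mixno` and `Mixno+DI` splits are subject-disjoint: the subjects are
#' shuffled and dealt into 5 folds, and a fold's test set is all segments
#' of its subjects (about 20% of subjects per fold). `Mixyes+DI` deals the
#' segments themselves into 5 folds regardless of subject.
#'
#' @param manifest tibble with `subject_id` and `segment_id`.
#' @param scenario `"Mixno"`, `"Mixno+DI"`, or `"Mixyes+DI"`.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return The manifest with an integer `fold` column: the fold in which
#'   that segment is part of the test set. The scenario is kept as
#'   attribute `"scenario"`.
#' @export
make_splits <- function(manifest, scenario = c("Mixno", "Mixno+DI", "Mixyes+DI"),
                        n_folds = 5L, seed = 1L) {
  scenario <- match.arg(scenario)
  set.seed(as.integer(seed))
  if (scenario %in% c("Mixno", "Mixno+DI")) {
    subjects <- unique(manifest$subject_id)
    if (length(subjects) < n_folds) {
      stop("need at least ", n_folds, " subjects for subject-disjoint folds")
    }
    fold_of <- stats::setNames(rep_len(seq_len(n_folds), length(subjects)),
                               sample(subjects))
    out <- dplyr::mutate(manifest, fold = unname(fold_of[.data$subject_id]))
  } else {
    n <- nrow(manifest)
    out <- dplyr::mutate(manifest,
                         fold = sample(rep_len(seq_len(n_folds), n)))
  }
  attr(out, "scenario") <- scenario
  out
}

#' Scenario-aware use of demographics
#' @param scenario scenario name.
#' @return `TRUE` when the scenario feeds age/gender to the model.
#' @export
scenario_uses_di <- function(scenario) grepl("DI$", scenario)

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the seq2seq model
#'
#' Teacher-forced training under the masked multitask objective: per
#' epoch, a fresh random 5-s window is drawn for every segment (seeded per
#' epoch for reproducibility), samples are shuffled into batches, and Adam
#' updates follow the patience learning-rate schedule. The monitored
#' quantity is the training loss. The best parameter set is kept.
#'
#' @param model a `bp_seq2seq` from [init_weights()].
#' @param dataset a `bp_dataset` (see [build_model_dataset()]) or plain
#'   list of samples, each holding `prepared` (13-s two-channel tibble),
#'   `target` (scaled homogenized target), and optionally `x_di`.
#' @param epochs maximum epochs.
#' @param batch_size samples per Adam update.
#' @param lr0 initial learning rate.
#' @param lambda class-loss weight.
#' @param patience_decay,patience_stop schedule patience in epochs.
#' @param seed integer seed driving shuffling and window draws.
#' @param verbose print per-epoch losses.
#' @return The model with updated parameters, `history` (tibble of epoch,
#'   loss, mse, ce, lr), and `best_loss`.
#' @export
train_seq2seq <- function(model, dataset, epochs = 10L, batch_size = 48L,
                          lr0 = 1e-3, lambda = 0.01, patience_decay = 25L,
                          patience_stop = 50L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "bp_seq2seq"))
  samples_raw <- if (inherits(dataset, "bp_dataset")) dataset$samples else dataset
  if (model$arch$use_di && any(purrr::map_lgl(samples_raw, ~ is.null(.x$x_di))))
    stop("DI-enabled model but dataset lacks demographic vectors")
  cfg <- arch_cfg(model$arch)
  params <- model$params
  opt <- adam_init(params)
  history <- list()
  losses <- numeric(0)
  best <- list(loss = Inf, params = params)
  n <- length(samples_raw)
  for (epoch in seq_len(epochs)) {
    sched <- lr_schedule(losses, lr0, patience_decay, patience_stop)
    if (sched$stop) break
    set.seed((as.integer(seed) * 7919L + epoch) %% .Machine$integer.max)
    cpp_samples <- purrr::map(samples_raw, function(s) {
      X <- if (!is.null(s$window)) s$window
           else sample_window(s$prepared)
      make_model_sample(model$arch, as.matrix(X), s$target, s$x_di)
    })
    order_idx <- sample.int(n)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / batch_size))
    ep_loss <- ep_mse <- ep_ce <- 0
    for (b in batches) {
      out <- s2s_batch_cpp(params, cfg, cpp_samples[b], lambda, TRUE)
      if (!is.finite(out$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      upd <- adam_step(params, out$grads, opt, sched$lr)
      params <- upd$params; opt <- upd$state
      w <- length(b) / n
      ep_loss <- ep_loss + out$loss * w
      ep_mse <- ep_mse + out$mse * w
      ep_ce <- ep_ce + out$ce * w
    }
    losses <- c(losses, ep_loss)
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss,
                                       mse = ep_mse, ce = ep_ce,
                                       lr = sched$lr)
    if (ep_loss < best$loss) best <- list(loss = ep_loss, params = params)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  mse %.5f  ce %.4f  lr %.2e",
                      epoch, ep_loss, ep_mse, ep_ce, sched$lr))
    }
  }
  model$params <- best$params
  model$history <- dplyr::bind_rows(history)
  model$best_loss <- best$loss
  model
}

#' Teacher-forced loss of a model over a dataset
#'
#' @param model a `bp_seq2seq`.
#' @param dataset a `bp_dataset` or list of samples.
#' @param lambda class-loss weight.
#' @param seed seed for the 5-s window draws.
#' @return list with `loss`, `mse`, `ce`.
#' @export
dataset_loss <- function(model, dataset, lambda = 0.01, seed = 1L) {
  samples_raw <- if (inherits(dataset, "bp_dataset")) dataset$samples else dataset
  set.seed(as.integer(seed))
  cpp_samples <- purrr::map(samples_raw, function(s) {
    X <- if (!is.null(s$window)) s$window else sample_window(s$prepared)
    make_model_sample(model$arch, as.matrix(X), s$target, s$x_di)
  })
  out <- s2s_batch_cpp(model$params, arch_cfg(model$arch), cpp_samples,
                       lambda, FALSE)
  out[c("loss", "mse", "ce")]
}
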