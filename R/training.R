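# Dice-loss training, subject-level validation split, the fine-tuning
# (transfer) protocol with a catastrophic-forgetting guard, and slice-wise
# volume prediction.

#' Training configuration
#'
#' Two presets ship: `"full_scale"` keeps the clinical full-scale protocol
#' (Adam lr 1e-6, 300 pretraining / 150 fine-tuning epochs, batch 6) for
#' users with real data and accelerator hardware; `"desk_scale"` raises the
#' learning rate and shrinks the epoch budget so the full two-domain study
#' runs on one CPU core in minutes. Provenance (config used) is recorded in
#' checkpoints.
#'
#' @param epochs_max Maximum epochs.
#' @param batch_size Slices per optimization step.
#' @param learning_rate Adam step size.
#' @param val_fraction Fraction of subjects held out for internal
#'   validation (subject-level, never slice-level).
#' @param seed Seed controlling the split, shuffling and initialization.
#' @param smooth Soft-Dice smoothing constant (stabilizes empty-mask
#'   slices).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (the guard against over-fitting to a small new
#'   cohort, i.e. catastrophic forgetting during fine-tuning).
#' @param threshold Binarization threshold for predicted probabilities.
#' @param include_empty Keep tumour-free slices in the training stream.
#' @return An object of class `gtv_train_config`.
#' @export
train_config <- function(epochs_max = 300L, batch_size = 6L,
                         learning_rate = 1e-6, val_fraction = 0.10,
                         seed = 1L, smooth = 1, early_stop_patience = 15L,
                         threshold = 0.5, include_empty = TRUE) {
  stopifnot(val_fraction > 0, val_fraction < 0.5, batch_size >= 1,
            learning_rate >= 0, smooth > 0)
  structure(list(epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 smooth = smooth,
                 early_stop_patience = as.integer(early_stop_patience),
                 threshold = threshold,
                 include_empty = isTRUE(include_empty)),
            class = "gtv_train_config")
}

#' Preset training configurations
#'
#' @param preset `"full_scale"` or `"desk_scale"`.
#' @param stage `"pretrain"` or `"finetune"`.
#' @param seed Seed stored in the config.
#' @return A [train_config()].
#' @export
train_config_preset <- function(preset = c("desk_scale", "full_scale"),
                                stage = c("pretrain", "finetune"),
                                seed = 1L) {
  preset <- match.arg(preset); stage <- match.arg(stage)
  if (preset == "full_scale") {
    train_config(epochs_max = if (stage == "pretrain") 300L else 150L,
                 batch_size = 6L, learning_rate = 1e-6, seed = seed)
  } else {
    if (stage == "pretrain")
      train_config(epochs_max = 10L, batch_size = 6L, learning_rate = 1e-3,
                   early_stop_patience = 4L, seed = seed)
    else
      train_config(epochs_max = 10L, batch_size = 6L, learning_rate = 3e-4,
                   early_stop_patience = 3L, seed = seed)
  }
}

#' Soft Dice loss
#'
#' The complement of the soft Dice index,
#' `1 - (2 * sum(p*t) + smooth) / (sum(p) + sum(t) + smooth)`,
#' computed per image and averaged over the batch. Always in `[0, 1]`.
#'
#' @param pred Probability map(s): a 2D matrix or a `(H, W, 1, N)` batch.
#' @param target Binary map(s) of the same shape.
#' @param smooth Smoothing constant; as it tends to zero the loss tends to
#'   the exact Dice complement (stays 0 for a pair of empty masks).
#' @return Scalar loss.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  if (is.null(dim(pred)) || length(dim(pred)) <= 2) {
    num <- 2 * sum(pred * target) + smooth
    den <- sum(pred) + sum(target) + smooth
    return(1 - num / den)
  }
  N <- dim(pred)[length(dim(pred))]
  hw <- length(pred) / N
  p <- matrix(pred, hw, N); t <- matrix(target, hw, N)
  num <- 2 * colSums(p * t) + smooth
  den <- colSums(p) + colSums(t) + smooth
  mean(1 - num / den)
}

# Gradient of the batch-averaged soft Dice loss w.r.t. pred.
dice_loss_grad <- function(pred, target, smooth = 1) {
  d <- dim(pred); N <- d[4]; hw <- length(pred) / N
  p <- matrix(pred, hw, N); t <- matrix(target, hw, N)
  num <- 2 * colSums(p * t) + smooth
  den <- colSums(p) + colSums(t) + smooth
  g <- -(2 * t * rep(den, each = hw) - rep(num, each = hw)) /
    rep(den^2, each = hw) / N
  array(g, d)
}

#' Subject-level train/validation split
#'
#' Splitting is always at subject level so no subject contributes slices to
#' both sides (no leakage).
#'
#' @param cohort A `gtv_cohort` with at least 2 subjects.
#' @param val_fraction Validation fraction; at least one subject is always
#'   held out.
#' @param seed Split seed.
#' @return List with elements `train` and `val` (both `gtv_cohort`).
#' @export
split_subjects <- function(cohort, val_fraction = 0.10, seed = 1L) {
  n <- length(cohort)
  if (n < 2) stop("cohort too small to split")
  set.seed(as.integer(seed))
  n_val <- max(1L, round(val_fraction * n))
  vi <- sort(sample(n, n_val))
  list(train = structure(cohort[-vi], class = "gtv_cohort"),
       val = structure(cohort[vi], class = "gtv_cohort"))
}

# Stack a cohort's (windowed) slices into batch arrays.
cohort_slice_arrays <- function(cohort, include_empty = TRUE) {
  tabs <- lapply(cohort, function(s) {
    v <- window_normalize(s$volume)
    to_slices(v, s$truth_mask, subject_id = s$id,
              include_empty = include_empty)
  })
  tab <- dplyr::bind_rows(tabs)
  if (nrow(tab) == 0) stop("no slices available for training")
  hw <- dim(tab$image[[1]])
  X <- array(0, c(hw[1], hw[2], 1L, nrow(tab)))
  Y <- array(0, c(hw[1], hw[2], 1L, nrow(tab)))
  for (i in seq_len(nrow(tab))) {
    X[, , 1L, i] <- tab$image[[i]]
    Y[, , 1L, i] <- tab$mask[[i]]
  }
  list(X = X, Y = Y, subject_id = tab$subject_id)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Hard Dice per slice batch (empty-vs-empty counts as 1), averaged.
batch_hard_dice <- function(prob, target, threshold) {
  d <- dim(prob); N <- d[4]; hw <- length(prob) / N
  p <- matrix(prob >= threshold, hw, N); t <- matrix(target != 0, hw, N)
  num <- 2 * colSums(p & t)
  den <- colSums(p) + colSums(t)
  mean(ifelse(den == 0, 1, num / pmax(den, 1)))
}

eval_slices <- function(model, X, Y, cfg) {
  n <- dim(X)[4]
  loss <- 0; dice <- 0; nb <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / (4 * cfg$batch_size)))) {
    xb <- X[, , , b, drop = FALSE]; yb <- Y[, , , b, drop = FALSE]
    pr <- net_forward(model, xb)$prob
    loss <- loss + dice_loss(pr, yb, cfg$smooth) * length(b)
    dice <- dice + batch_hard_dice(pr, yb, cfg$threshold) * length(b)
    nb <- nb + length(b)
  }
  list(loss = loss / nb, dice = dice / nb)
}

# Shared optimization loop for pretraining and fine-tuning.
train_loop <- function(model, train_arr, val_arr, cfg, source_val = NULL,
                       stage = "pretrain") {
  n <- dim(train_arr$X)[4]
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, running = model$running,
               epoch = 0L)
  hist <- list()
  wait <- 0L
  set.seed(cfg$seed)
  as_history <- function(h) structure(h, class = c("gtv_history", class(h)))
  if (cfg$epochs_max < 1L) {
    history <- tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                              val_loss = numeric(0), val_dice = numeric(0),
                              source_val_dice = numeric(0))
    return(list(model = model, history = as_history(history),
                stopped = "max_epochs"))
  }
  stopped <- "max_epochs"
  for (ep in seq_len(cfg$epochs_max)) {
    ord <- sample(n)
    ep_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      xb <- train_arr$X[, , , b, drop = FALSE]
      yb <- train_arr$Y[, , , b, drop = FALSE]
      fw <- net_forward(model, xb, training = TRUE, keep_cache = TRUE)
      model$running <- fw$running
      loss <- dice_loss(fw$prob, yb, cfg$smooth)
      if (!is.finite(loss)) stop("non-finite training loss (divergence)")
      gp <- dice_loss_grad(fw$prob, yb, cfg$smooth)
      grads <- net_backward(model, fw$cache, gp)
      up <- adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- up$params; state <- up$state
      ep_loss <- ep_loss + loss * length(b)
    }
    vm <- eval_slices(model, val_arr$X, val_arr$Y, cfg)
    sv <- if (!is.null(source_val))
      eval_slices(model, source_val$X, source_val$Y, cfg)$dice else NA_real_
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / n,
                                 val_loss = vm$loss, val_dice = vm$dice,
                                 source_val_dice = sv)
    if (vm$loss < best$loss - 1e-6) {
      best <- list(loss = vm$loss, params = model$params,
                   running = model$running, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) { stopped <- "early_stop"; break }
    }
  }
  model$params <- best$params
  model$running <- best$running
  model$provenance <- c(model$provenance,
                        list(stage = stage, best_epoch = best$epoch,
                             learning_rate = cfg$learning_rate,
                             seed = cfg$seed))
  list(model = model, history = as_history(dplyr::bind_rows(hist)),
       stopped = stopped)
}

#' Train a segmentation model
#'
#' Adam optimization of the soft Dice loss over shuffled slice batches,
#' with a subject-level internal validation split; the checkpoint with the
#' lowest validation loss is retained. Fully seeded (split, shuffling).
#'
#' @param model A `gtv_model` (freshly built or pretrained).
#' @param cohort A `gtv_cohort` with HU volumes; windowing is applied
#'   internally.
#' @param cfg A [train_config()].
#' @return List: `model` (best checkpoint), `history` (per-epoch tibble of
#'   train loss, validation loss, validation Dice), `stopped`
#'   (`"max_epochs"` or `"early_stop"`).
#' @export
train <- function(model, cohort, cfg) {
  if (length(cohort) == 0) stop("empty training cohort")
  sp <- split_subjects(cohort, cfg$val_fraction, cfg$seed)
  tr <- cohort_slice_arrays(sp$train, cfg$include_empty)
  va <- cohort_slice_arrays(sp$val, include_empty = TRUE)
  train_loop(model, tr, va, cfg, stage = "pretrain")
}

#' Fine-tune a pretrained model on a new cohort
#'
#' Continues training of the whole model (no layer freezing) from the
#' pretrained weights on the new-domain cohort. Early stopping on the
#' new-domain validation loss plateau guards against catastrophic
#' forgetting; when `source_val` is supplied, source-domain validation Dice
#' is also recorded per epoch so forgetting is measurable.
#'
#' @param model Pretrained `gtv_model` (e.g. from [train()] or
#'   [load_checkpoint()]).
#' @param new_cohort Target-domain `gtv_cohort`.
#' @param cfg A [train_config()]; `epochs_max = 0` returns the input model
#'   unchanged.
#' @param source_val Optional source-domain `gtv_cohort` used only for
#'   monitoring.
#' @return As [train()], with a `source_val_dice` history column.
#' @export
fine_tune <- function(model, new_cohort, cfg, source_val = NULL) {
  if (cfg$epochs_max < 1L)
    return(train_loop(model, NULL, NULL, cfg, stage = "finetune"))
  sp <- split_subjects(new_cohort, cfg$val_fraction, cfg$seed)
  tr <- cohort_slice_arrays(sp$train, cfg$include_empty)
  va <- cohort_slice_arrays(sp$val, include_empty = TRUE)
  sv <- if (!is.null(source_val))
    cohort_slice_arrays(source_val, include_empty = TRUE) else NULL
  train_loop(model, tr, va, cfg, source_val = sv, stage = "finetune")
}

#' Predict a full volume slice-wise
#'
#' Runs the model on every axial slice and restacks the thresholded
#' probability maps in slice order. No inter-slice post-processing is
#' applied.
#'
#' @param model A trained `gtv_model`.
#' @param v Normalized `gtv_volume`.
#' @param threshold Probability threshold (default 0.5).
#' @return Integer 3D mask array matching the volume grid.
#' @export
predict_volume <- function(model, v, threshold = 0.5) {
  stopifnot(inherits(v, "gtv_volume"))
  if (v$intensity_state != "normalized")
    stop("predict_volume expects a normalized volume")
  d <- dim(v$data)
  if (d[1] != model$config$input_size || d[2] != model$config$input_size)
    stop("slice size ", d[1], "x", d[2],
         " does not match model input size ", model$config$input_size)
  x <- v$data; dim(x) <- c(d[1], d[2], 1L, d[3])
  prob <- net_forward(model, x)$prob
  array(as.integer(prob >= threshold), d)
}
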