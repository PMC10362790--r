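# Dataset splitting, unsupervised masked-reconstruction pre-training, and
# per-patient chronological fine-tuning with early stopping.

#' Training configuration
#'
#' @param epochs Maximum epochs (default 200).
#' @param lr Learning rate (default 3e-3).
#' @param decay_start_epoch Epoch after which the learning rate decays
#'   multiplicatively (default 50).
#' @param decay_beta Per-epoch decay factor after `decay_start_epoch`
#'   (default 0.98).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param batch_size Mini-batch size (default 64).
#' @param seed Integer seed governing shuffling, masking and dropout.
#' @param min_slices_per_patient Minimum qualified slices for a patient to
#'   enter the splits (default 10, i.e. 200 s of signal).
#' @param mlm_ratio,mlm_mean_span Masking ratio and mean span for
#'   pre-training.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 200, lr = 3e-3, decay_start_epoch = 50,
                         decay_beta = 0.98, patience = 20, batch_size = 64,
                         seed = 1, min_slices_per_patient = 10,
                         mlm_ratio = 0.15, mlm_mean_span = 3) {
  stopifnot(patience >= 1, lr > 0, epochs >= 1, batch_size >= 1)
  structure(as.list(environment()), class = "train_config")
}

# ---- splitting -------------------------------------------------------------

#' Patient-level random split
#'
#' Shuffles eligible patients (those with at least
#' `min_slices_per_patient` slices when counts are supplied) into disjoint
#' train/validation/test sets. Validation and test sizes are
#' `floor(fraction * n)`; training receives the remainder.
#'
#' @param patient_ids Character vector of patient identifiers.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @param slice_counts Optional named vector of per-patient slice counts.
#' @param min_slices Minimum slices per eligible patient (default 10).
#' @return A list of class `split_spec`: `train`, `val`, `test` (identifier
#'   vectors) and `excluded` (data.frame with reasons).
#' @export
split_patients <- function(patient_ids, fractions = c(0.70, 0.10, 0.20),
                           seed = 1, slice_counts = NULL, min_slices = 10) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  patient_ids <- as.character(patient_ids)
  excluded <- data.frame(patient_id = character(0), reason = character(0))
  if (!is.null(slice_counts)) {
    low <- patient_ids[slice_counts[patient_ids] < min_slices]
    if (length(low)) {
      excluded <- data.frame(patient_id = low, reason = "too_few_slices")
      patient_ids <- setdiff(patient_ids, low)
    }
  }
  n <- length(patient_ids)
  if (n < 3) stop("need at least 3 eligible patients to split", call. = FALSE)
  shuffled <- with_seed(seed, sample(patient_ids))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  test <- shuffled[seq_len(n_test)]
  val <- shuffled[n_test + seq_len(n_val)]
  train <- shuffled[-seq_len(n_test + n_val)]
  structure(list(train = train, val = val, test = test, excluded = excluded),
            class = "split_spec")
}

slice_sort_key <- function(slices) {
  order(vapply(slices, function(s) s$record_id, character(1)),
        vapply(slices, function(s) s$start_sample, numeric(1)))
}

#' Chronological fine-tune / evaluation split of one patient's slices
#'
#' Sorts the slices by acquisition time (record, then start sample) and
#' assigns the first `floor(finetune_frac * n)` (at least 1) to the
#' fine-tuning set and the remainder to evaluation, so no evaluation slice
#' ever precedes a fine-tuning slice.
#'
#' @param slices List of (qualified or channelized) slices of one patient.
#' @param finetune_frac Fraction used for fine-tuning (default 0.2).
#' @return List with `finetune` and `eval` slice lists, both chronological.
#' @export
chronological_split <- function(slices, finetune_frac = 0.2) {
  n <- length(slices)
  if (n < 2) stop("need at least 2 slices to split", call. = FALSE)
  slices <- slices[slice_sort_key(slices)]
  n_ft <- max(1L, floor(finetune_frac * n))
  list(finetune = slices[seq_len(n_ft)], eval = slices[(n_ft + 1L):n])
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(params) {
  flat <- unlist(params, use.names = FALSE)
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  p <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  p <- p - lr * mh / (sqrt(vh) + eps)
  list(params = utils::relist(p, params), state = state)
}

# ---- label handling --------------------------------------------------------

slice_labels <- function(slices, targets) {
  out <- vapply(slices, function(s) {
    c(ASBP = s$asbp, ADBP = s$adbp, SpO2 = s$spo2)[targets]
  }, numeric(length(targets)))
  matrix(out, nrow = length(targets),
         dimnames = list(targets, NULL))
}

compute_label_stats <- function(y) {
  mu <- rowMeans(y)
  sdv <- apply(y, 1, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1] <- 1  # floor keeps single-slice fits sane
  list(mean = mu, sd = sdv)
}

slice_matrix <- function(s) if (inherits(s, "channelized_slice")) s$channels else s

lr_at_epoch <- function(cfg, epoch) {
  if (epoch <= cfg$decay_start_epoch) cfg$lr
  else cfg$lr * cfg$decay_beta^(epoch - cfg$decay_start_epoch)
}

# ---- pre-training ----------------------------------------------------------

#' Unsupervised masked-reconstruction pre-training
#'
#' Trains the encoder plus reconstruction head to predict randomly masked
#' spans of standardized input slices (mean squared error over masked
#' positions only). Fully seeded: identical inputs and configuration give
#' identical loss histories. Returns the best-by-training-loss parameters.
#'
#' @param slices Nonempty list of `channelized_slice` objects (or w x l
#'   matrices).
#' @param model_config A [tst_config()].
#' @param config A [train_config()]; `epochs`, `lr`, `batch_size`, `seed`,
#'   `mlm_ratio`, `mlm_mean_span` and the decay fields are used.
#' @return A `tst` model; attribute `"history"` holds the per-epoch mean
#'   training loss.
#' @export
tst_pretrain <- function(slices, model_config, config = train_config()) {
  if (length(slices) == 0) stop("empty training set", call. = FALSE)
  xs <- lapply(slices, function(s) standardize(slice_matrix(s))$x)
  model <- tst_init(model_config, seed = config$seed)
  state <- adam_init(model$params)
  history <- numeric(config$epochs)
  best_loss <- Inf; best_params <- model$params
  n <- length(xs)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, epoch), sample.int(n))
    lr_e <- lr_at_epoch(config, epoch)
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(n, b0 + config$batch_size - 1L)]
      grads <- NULL; bl <- 0
      for (k in seq_along(idx)) {
        i <- idx[k]
        ms <- mask_for_mlm(xs[[i]], config$mlm_ratio, config$mlm_mean_span,
                           seed = derive_seed(config$seed,
                                              epoch * 1000003 + i))
        if (!any(ms$mask)) next
        fw <- with_seed(derive_seed(config$seed, epoch * 2000003 + i),
                        tst_forward(model, ms$x, head = "mlm",
                                    training = TRUE, want_cache = TRUE))
        diff <- fw$out - xs[[i]]
        nm <- sum(ms$mask) * nrow(xs[[i]])
        loss <- sum(diff[, ms$mask, drop = FALSE]^2) / nm
        d_out <- matrix(0, nrow(diff), ncol(diff))
        d_out[, ms$mask] <- 2 * diff[, ms$mask, drop = FALSE] / nm
        g <- tst_backward(model, fw$cache, d_out)
        grads <- if (is.null(grads)) g else tree_axpy(grads, g)
        bl <- bl + loss
      }
      if (is.null(grads)) next
      grads <- tree_map2(function(x, y) x / length(idx), grads, grads)
      upd <- adam_step(model$params, grads, state, lr_e)
      model$params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl / length(idx); nb <- nb + 1L
    }
    history[epoch] <- ep_loss / max(nb, 1L)
    if (history[epoch] < best_loss) {
      best_loss <- history[epoch]
      best_params <- model$params
    }
  }
  model$params <- best_params
  attr(model, "history") <- history
  model
}

#' Masked-reconstruction error of a model on held-out slices
#'
#' Deterministically masks each slice (seeded) and measures the mean
#' squared reconstruction error over the masked positions.
#'
#' @param model A `tst` model.
#' @param slices List of `channelized_slice` objects or matrices.
#' @param config A [train_config()] providing masking parameters.
#' @param seed Seed for the evaluation masks.
#' @return Mean masked-reconstruction MSE across slices.
#' @export
mlm_eval_loss <- function(model, slices, config = train_config(),
                          seed = 99) {
  losses <- vapply(seq_along(slices), function(i) {
    x <- standardize(slice_matrix(slices[[i]]))$x
    ms <- mask_for_mlm(x, config$mlm_ratio, config$mlm_mean_span,
                       seed = derive_seed(seed, i))
    pred <- tst_forward(model, ms$x, head = "mlm")$out
    mlm_loss(pred, x, ms$mask)
  }, numeric(1))
  mean(losses)
}

# ---- supervised fine-tuning ------------------------------------------------

#' Supervised regression fine-tuning
#'
#' Trains the full encoder plus regression head on labelled slices by mean
#' squared error (labels standardized internally; statistics stored in the
#' returned model). Learning-rate decay after `decay_start_epoch`; early
#' stopping when the validation loss fails to improve for `patience`
#' consecutive epochs; the best-validation checkpoint is returned.
#'
#' @param model A `tst` model (typically pretrained) to initialize from.
#' @param slices Training slices (`channelized_slice` objects).
#' @param val_slices Validation slices; when `NULL`, the training loss
#'   drives checkpoint selection and early stopping.
#' @param config A [train_config()].
#' @param label_stats Optional precomputed label statistics
#'   (`list(mean, sd)` per target); default computed from `slices`.
#' @return The fine-tuned `tst` model; attribute `"history"` holds a
#'   data.frame of train/validation losses, attribute `"epochs_run"` the
#'   number of epochs executed.
#' @export
tst_finetune <- function(model, slices, val_slices = NULL,
                         config = train_config(), label_stats = NULL) {
  if (length(slices) == 0) stop("empty fine-tuning set", call. = FALSE)
  targets <- model$config$targets
  y <- slice_labels(slices, targets)
  if (is.null(label_stats)) label_stats <- compute_label_stats(y)
  y_std <- (y - label_stats$mean) / label_stats$sd
  xs <- lapply(slices, function(s) standardize(slice_matrix(s))$x)
  val_xy <- if (!is.null(val_slices) && length(val_slices) > 0) {
    yv <- (slice_labels(val_slices, targets) - label_stats$mean) / label_stats$sd
    list(xs = lapply(val_slices, function(s) standardize(slice_matrix(s))$x),
         y = yv)
  } else NULL

  model$label_stats <- label_stats
  state <- adam_init(model$params)
  n <- length(xs)
  best_loss <- Inf; best_params <- model$params
  since_best <- 0L
  hist_train <- numeric(0); hist_val <- numeric(0)
  epochs_run <- 0L
  for (epoch in seq_len(config$epochs)) {
    epochs_run <- epoch
    ord <- with_seed(derive_seed(config$seed, 500000 + epoch), sample.int(n))
    lr_e <- lr_at_epoch(config, epoch)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(n, b0 + config$batch_size - 1L)]
      grads <- NULL; bl <- 0
      for (i in idx) {
        fw <- with_seed(derive_seed(config$seed, epoch * 3000017 + i),
                        tst_forward(model, xs[[i]], head = "regress",
                                    training = TRUE, want_cache = TRUE))
        err <- fw$out - y_std[, i]
        loss <- mean(err^2)
        d_out <- 2 * err / length(err)
        g <- tst_backward(model, fw$cache, d_out)
        grads <- if (is.null(grads)) g else tree_axpy(grads, g)
        bl <- bl + loss
      }
      grads <- tree_map2(function(x, y) x / length(idx), grads, grads)
      upd <- adam_step(model$params, grads, state, lr_e)
      model$params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl / length(idx); nb <- nb + 1L
    }
    hist_train[epoch] <- ep_loss / max(nb, 1L)
    crit <- if (is.null(val_xy)) hist_train[epoch] else {
      ve <- vapply(seq_along(val_xy$xs), function(i) {
        mean((tst_forward(model, val_xy$xs[[i]], head = "regress")$out -
                val_xy$y[, i])^2)
      }, numeric(1))
      mean(ve)
    }
    hist_val[epoch] <- crit
    if (crit < best_loss - 1e-12) {
      best_loss <- crit; best_params <- model$params; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  model$params <- best_params
  attr(model, "history") <- data.frame(epoch = seq_len(epochs_run),
                                       train = hist_train, val = hist_val)
  attr(model, "epochs_run") <- epochs_run
  model
}

#' Per-patient personalization
#'
#' Splits one patient's slices chronologically (first `finetune_frac` for
#' fine-tuning, rest for evaluation), holds out the chronological tail of
#' the fine-tuning portion as the validation set, fine-tunes the pretrained
#' model with early stopping, and returns the best checkpoint's predictions
#' on the evaluation slices only.
#'
#' @param pretrained A pretrained `tst` model.
#' @param slices The patient's `channelized_slice` list.
#' @param config A [train_config()].
#' @param finetune_frac Chronological fine-tuning fraction (default 0.2).
#' @param val_frac Fraction of the fine-tuning portion held out for
#'   validation (chronological tail, default 0.2; at least one slice when
#'   the portion has two or more).
#' @param label_stats Optional label statistics override.
#' @return List with `model`, `predictions` (data.frame: subject, record,
#'   start sample, target, truth `y`, prediction `yhat`), `split`, and
#'   `epochs_run`.
#' @export
finetune_personalize <- function(pretrained, slices,
                                 config = train_config(),
                                 finetune_frac = 0.2, val_frac = 0.2,
                                 label_stats = NULL) {
  sp <- chronological_split(slices, finetune_frac)
  ft <- sp$finetune
  n_ft <- length(ft)
  if (n_ft >= 2) {
    n_val <- max(1L, floor(val_frac * n_ft))
    train_sl <- ft[seq_len(n_ft - n_val)]
    val_sl <- ft[(n_ft - n_val + 1L):n_ft]
  } else {
    train_sl <- ft; val_sl <- ft
  }
  fitted <- tst_finetune(pretrained, train_sl, val_sl, config, label_stats)
  preds <- predict(fitted, sp$eval)
  targets <- fitted$config$targets
  y <- t(slice_labels(sp$eval, targets))
  pred_df <- do.call(rbind, lapply(seq_along(targets), function(j) {
    data.frame(subject_id = vapply(sp$eval, function(s) s$subject_id, character(1)),
               record_id = vapply(sp$eval, function(s) s$record_id, character(1)),
               start_sample = vapply(sp$eval, function(s) s$start_sample, numeric(1)),
               target = targets[j], y = y[, j], yhat = preds[, j],
               stringsAsFactors = FALSE)
  }))
  list(model = fitted, predictions = pred_df, split = sp,
       epochs_run = attr(fitted, "epochs_run"))
}
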