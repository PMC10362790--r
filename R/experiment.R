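# End-to-end cohort experiment: synthesis -> QC -> EMD -> pre-training ->
# pooled fine-tuning -> per-patient personalization -> paired predictions.
# This is the driver behind the acceptance script and the package's worked
# examples; it exercises every pipeline stage on data with known ground
# truth.

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a patient cohort, runs every record through quality control,
#' channelizes the qualified slices by EMD, splits patients 70/10/20,
#' pre-trains the transformer by masked reconstruction on the training
#' patients, fits a pooled (non-personalized) regression model, and then
#' personalizes the pretrained model for each test patient on the
#' chronologically earliest fifth of their slices. Predictions of both the
#' pooled and the personalized models on the per-patient evaluation slices
#' are returned together with compliance reports.
#'
#' @param n_patients Cohort size.
#' @param duration_s Record duration per patient (seconds).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed driving synthesis, splitting and training.
#' @param targets Regression targets (subset of ASBP/ADBP/SpO2).
#' @param decimate Model-side subsampling factor for the slices (see
#'   [channelize_slice()]).
#' @param model_config A [tst_config()]; `NULL` for the desk-scale default
#'   (3 layers, D = 32, 4 heads).
#' @param pretrain_epochs,pooled_epochs,personal_epochs Epoch budgets of the
#'   three training stages.
#' @param offset_sd,noise_sd Cohort generator parameters (see
#'   [generate_cohort()]).
#' @return A list with `predictions` (data.frame: subject, target, truth,
#'   personalized and pooled predictions), `per_patient` (data.frame of
#'   per-patient MAEs and the personalization win indicator), `reports`
#'   (per-target [compliance_report()]s of the personalized model),
#'   `pretrained`, `pooled`, `split`, and `n_slices`.
#' @export
run_cohort_experiment <- function(n_patients = 30, duration_s = 300,
                                  fs = 125, seed = 1,
                                  targets = c("ASBP", "ADBP"),
                                  decimate = 10,
                                  model_config = NULL,
                                  pretrain_epochs = 6,
                                  pooled_epochs = 8,
                                  personal_epochs = 60,
                                  offset_sd = 10, noise_sd = 0.02) {
  cohort <- generate_cohort(n_patients, duration_s = duration_s, fs = fs,
                            seed = seed, offset_sd = offset_sd,
                            noise_sd = noise_sd)
  by_patient <- lapply(cohort, function(p) {
    sl <- preprocess_record(p$record)$slices
    lapply(sl, channelize_slice, decimate = decimate)
  })
  names(by_patient) <- vapply(cohort, function(p) p$spec$patient_id,
                              character(1))
  counts <- vapply(by_patient, length, integer(1))
  l_model <- if (length(by_patient[[1]])) ncol(by_patient[[1]][[1]]$channels)
             else round(20 * fs / decimate)
  if (is.null(model_config)) {
    model_config <- tst_config(n_layers = 3, d_model = 32, n_heads = 4,
                               d_ff = 64, head_hidden = 128, dropout = 0,
                               max_len = l_model, n_channels = 4,
                               targets = targets)
  }
  split <- split_patients(names(by_patient), seed = derive_seed(seed, 101),
                          slice_counts = counts)
  train_slices <- unlist(by_patient[split$train], recursive = FALSE)
  val_slices <- unlist(by_patient[split$val], recursive = FALSE)

  pre_cfg <- train_config(epochs = pretrain_epochs, lr = 1e-3,
                          batch_size = 1, seed = derive_seed(seed, 202))
  pretrained <- tst_pretrain(train_slices, model_config, pre_cfg)

  pooled_cfg <- train_config(epochs = pooled_epochs, lr = 1e-3,
                             patience = pooled_epochs, batch_size = 4,
                             seed = derive_seed(seed, 303))
  pooled <- tst_finetune(pretrained, train_slices, val_slices, pooled_cfg)

  pp_cfg <- train_config(epochs = personal_epochs, lr = 3e-3, patience = 20,
                         batch_size = 2, seed = derive_seed(seed, 404))
  rows <- list(); per_patient <- list()
  for (pid in split$test) {
    res <- finetune_personalize(pretrained, by_patient[[pid]], pp_cfg)
    eval_slices <- res$split$eval
    y_pool <- predict(pooled, eval_slices)
    truth <- t(slice_labels(eval_slices, targets))
    for (j in seq_along(targets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = pid, target = targets[j],
        start_sample = vapply(eval_slices, function(s) s$start_sample,
                              numeric(1)),
        y = truth[, j],
        yhat_personal = res$predictions$yhat[res$predictions$target ==
                                               targets[j]],
        yhat_pooled = y_pool[, j], stringsAsFactors = FALSE)
    }
    mae_p <- mean(abs(truth[, 1] -
                        res$predictions$yhat[res$predictions$target ==
                                               targets[1]]))
    mae_g <- mean(abs(truth[, 1] - y_pool[, 1]))
    per_patient[[pid]] <- data.frame(
      subject_id = pid, n_eval = nrow(truth), mae_personal = mae_p,
      mae_pooled = mae_g, personal_wins = mae_p < mae_g,
      stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, rows)
  reports <- lapply(stats::setNames(targets, targets), function(tg) {
    d <- predictions[predictions$target == tg, ]
    compliance_report(paired_predictions(d$y, d$yhat_personal,
                                         subject_id = d$subject_id,
                                         target = tg))
  })
  list(predictions = predictions,
       per_patient = do.call(rbind, per_patient),
       reports = reports, pretrained = pretrained, pooled = pooled,
       split = split, n_slices = sum(counts), val_slices = val_slices)
}
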