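test_that("patient splits are sized, seeded, and leak-free", {
  ids <- sprintf("P%03d", 1:100)
  sp <- split_patients(ids, seed = 4)
  expect_equal(length(sp$train), 70)
  expect_equal(length(sp$val), 10)
  expect_equal(length(sp$test), 20)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(length(intersect(sp$train, sp$val)), 0)
  expect_equal(length(intersect(sp$val, sp$test)), 0)
  expect_identical(split_patients(ids, seed = 4), sp)
  expect_false(identical(split_patients(ids, seed = 5)$test, sp$test))
  # patients under the slice minimum are excluded with a logged reason
  counts <- setNames(rep(20L, 100), ids)
  counts["P007"] <- 9L
  sp2 <- split_patients(ids, seed = 4, slice_counts = counts)
  expect_false("P007" %in% c(sp2$train, sp2$val, sp2$test))
  expect_equal(sp2$excluded$patient_id, "P007")
  expect_equal(sp2$excluded$reason, "too_few_slices")
  expect_error(split_patients(c("a", "b"), seed = 1), "at least 3")
})

test_that("chronological splits take the earliest fifth, minimum one", {
  for (n in c(100, 10, 7, 2)) {
    sl <- stub_slices(n)
    cs <- chronological_split(sl)
    expect_equal(length(cs$finetune), max(1, floor(0.2 * n)))
    expect_equal(length(cs$finetune) + length(cs$eval), n)
    max_ft <- max(vapply(cs$finetune, function(s) s$start_sample, numeric(1)))
    min_ev <- min(vapply(cs$eval, function(s) s$start_sample, numeric(1)))
    expect_lt(max_ft, min_ev)
  }
  expect_equal(length(chronological_split(stub_slices(100))$finetune), 20)
  expect_equal(length(chronological_split(stub_slices(7))$finetune), 1)
  expect_error(chronological_split(stub_slices(1)), "at least 2")
  # ordering is by record then start sample, not list order
  sl <- stub_slices(10)[c(3, 1, 7, 5, 9, 2, 8, 4, 10, 6)]
  cs <- chronological_split(sl)
  expect_equal(vapply(cs$finetune, function(s) s$start_sample, numeric(1)),
               c(2500, 5000))
})

make_tiny_channel_slices <- function(n, seed, subject = "S1", beta = 0) {
  # small synthetic channelized slices with a label tied to channel 1 mean
  with_seed2 <- ppgvitals:::with_seed
  with_seed2(seed, lapply(seq_len(n), function(i) {
    ch <- matrix(rnorm(3 * 24), 3, 24)
    structure(list(channels = ch, asbp = 120 + beta * mean(ch[1, ]) + rnorm(1),
                   adbp = 70, spo2 = 97, subject_id = subject,
                   record_id = "R1", start_sample = i * 2500, fs = 125),
              class = "channelized_slice")
  }))
}

tiny3 <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 1, d_model = 8, n_heads = 2, d_ff = 12,
         head_hidden = 8, dropout = 0, max_len = 24, n_channels = 3,
         targets = "ASBP"),
    list(...))
  do.call(tst_config, args)
}

test_that("pre-training is seeded and reduces the masked loss it optimizes", {
  sl <- make_tiny_channel_slices(6, seed = 2)
  tc <- train_config(epochs = 4, lr = 3e-3, batch_size = 3, seed = 11,
                     mlm_ratio = 0.2, mlm_mean_span = 2)
  m1 <- tst_pretrain(sl, tiny3(), tc)
  m2 <- tst_pretrain(sl, tiny3(), tc)
  h1 <- attr(m1, "history")
  expect_identical(h1, attr(m2, "history"))
  expect_identical(m1$params, m2$params)
  expect_equal(length(h1), 4)
  expect_lt(min(h1), h1[1])
  expect_error(tst_pretrain(list(), tiny3(), tc), "empty training set")
})

test_that("early stopping fires after `patience` stagnant epochs", {
  sl <- make_tiny_channel_slices(4, seed = 3)
  val <- make_tiny_channel_slices(2, seed = 4)
  # a vanishing learning rate freezes the validation loss from epoch 1
  tc <- train_config(epochs = 200, lr = 1e-30, patience = 20, batch_size = 4,
                     seed = 1)
  m <- tst_finetune(tst_init(tiny3(), seed = 1), sl, val, tc)
  expect_equal(attr(m, "epochs_run"), 21)
  # and a short patience stops proportionally earlier
  tc5 <- train_config(epochs = 200, lr = 1e-30, patience = 5, batch_size = 4,
                      seed = 1)
  m5 <- tst_finetune(tst_init(tiny3(), seed = 1), sl, val, tc5)
  expect_equal(attr(m5, "epochs_run"), 6)
})

test_that("fine-tuning learns a recoverable linear signal", {
  sl <- make_tiny_channel_slices(30, seed = 5, beta = 15)
  cs <- chronological_split(sl, 0.5)
  tc <- train_config(epochs = 60, lr = 3e-3, patience = 60, batch_size = 5,
                     seed = 2)
  m <- tst_finetune(tst_init(tiny3(max_len = 24), seed = 3), cs$finetune,
                    val_slices = NULL, config = tc)
  preds <- predict(m, cs$eval)
  truth <- vapply(cs$eval, function(s) s$asbp, numeric(1))
  expect_lt(mean(abs(preds[, "ASBP"] - truth)), 4)
})

test_that("personalization predicts only on the held-out chronological tail", {
  sl <- make_tiny_channel_slices(10, seed = 6)
  tc <- train_config(epochs = 3, lr = 1e-3, patience = 3, batch_size = 2,
                     seed = 1)
  res <- finetune_personalize(tst_init(tiny3(), seed = 1), sl, tc)
  expect_equal(nrow(res$predictions), 8)  # eval = 10 - floor(0.2*10)
  ft_ids <- vapply(res$split$finetune, function(s) s$start_sample, numeric(1))
  ev_ids <- res$predictions$start_sample
  expect_equal(length(intersect(ft_ids, ev_ids)), 0)
  expect_lt(max(ft_ids), min(ev_ids))
  expect_error(finetune_personalize(tst_init(tiny3(), seed = 1),
                                    sl[1], tc), "at least 2")
})
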