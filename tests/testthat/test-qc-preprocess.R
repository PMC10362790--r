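test_that("flat runs are maximal, sorted, and thresholded", {
  r <- detect_flat_runs(c(1, 2, 2, 2, 3))
  expect_equal(r$start, 2)
  expect_equal(r$length, 3)
  expect_equal(nrow(detect_flat_runs(c(1, 2, 2, 3))), 0)
  rc <- detect_flat_runs(rep(5, 10))
  expect_equal(rc$start, 1)
  expect_equal(rc$length, 10)
  # two separated runs, non-overlapping and sorted
  x <- c(1, 1, 1, 5, 7, 7, 7, 7, 9)
  r2 <- detect_flat_runs(x)
  expect_equal(r2$start, c(1, 5))
  expect_equal(r2$length, c(3, 4))
  # eps tolerance groups near-equal values
  xe <- c(0, 1, 1.005, 1.009, 2)
  expect_equal(nrow(detect_flat_runs(xe, eps = 0)), 0)
  expect_equal(detect_flat_runs(xe, eps = 0.01)$length, 3)
})

test_that("flat fraction is run coverage over length", {
  x <- rnorm(2500)
  expect_equal(flat_fraction(x, detect_flat_runs(x)), 0)
  expect_equal(flat_fraction(rep(1, 40), detect_flat_runs(rep(1, 40))), 1)
  y <- rnorm(2500)
  y[101:225] <- y[101]          # one 125-sample run
  expect_equal(flat_fraction(y, detect_flat_runs(y)), 0.05)
})

test_that("the 5% flat rule discards or sutures records", {
  base <- generate_record(test_spec(noise_sd = 0.03), 20, 125, seed = 5)
  # 6% flat in ABP: rejected outright
  rec6 <- base
  rec6$channels$ABP[1:150] <- rec6$channels$ABP[1]
  out <- drop_or_suture(rec6)
  expect_s3_class(out, "qc_rejection")
  expect_equal(out$reason, "flat_fraction")
  # clean record passes through unchanged
  expect_identical(drop_or_suture(base)$channels, base$channels)
  # 100 flat samples in 2500: sutured to 2400, all channels together
  rec4 <- base
  rec4$channels$PLETH[201:300] <- rec4$channels$PLETH[201]
  sut <- drop_or_suture(rec4)
  expect_equal(unique(lengths(sut$channels)), 2400)
})

test_that("hampel filter matches a brute-force median/MAD oracle exactly", {
  hampel_oracle <- function(x, window, n_sigmas) {
    n <- length(x); k <- floor(window / 2); out <- x
    for (i in seq_len(n)) {
      w <- x[max(1, i - k):min(n, i + k)]
      med <- median(w)
      sig <- 1.4826 * median(abs(w - med))
      if (abs(x[i] - med) > n_sigmas * sig) out[i] <- med
    }
    out
  }
  expect_identical(hampel_filter(rep(7, 50)), rep(7, 50))
  spiky <- rep(100, 200); spiky[77] <- 300
  expect_equal(hampel_filter(spiky)[77], 100)
  set.seed(11)
  for (rep_i in 1:15) {
    n <- sample(20:500, 1)
    x <- rnorm(n)
    x[sample(n, 3)] <- x[sample(n, 3)] + 20
    w <- sample(c(5, 20, 100), 1)
    expect_identical(hampel_filter(x, w, 3), hampel_oracle(x, w, 3))
  }
})

test_that("band-pass filter passes 2 Hz, kills DC and 20 Hz", {
  fs <- 125
  t <- (0:2499) / fs
  mid <- 500:2000
  s2 <- sin(2 * pi * 2 * t)
  y2 <- butterworth_bandpass(s2, fs)
  expect_equal(stats::sd(y2[mid]) / stats::sd(s2[mid]), 1, tolerance = 0.02)
  # design response is exactly zero at DC; the finite-signal zero-phase
  # application leaves only a slow transient well below -40 dB mid-signal
  bf <- signal::butter(4, c(0.5, 8) / (fs / 2), type = "pass")
  z0 <- exp(-1i * 2 * pi * 1e-9 / fs * (seq_along(bf$b) - 1))
  expect_lt(Mod(sum(bf$b * z0) / sum(bf$a * z0)), 1e-6)
  dc <- butterworth_bandpass(rep(3, 2500), fs)
  expect_lt(max(abs(dc[mid])), 0.01 * 3)
  s20 <- sin(2 * pi * 20 * t)
  y20 <- butterworth_bandpass(s20, fs)
  expect_lt(stats::sd(y20[mid]) / stats::sd(s20[mid]), 0.01)  # >= 40 dB
  expect_error(butterworth_bandpass(s2, fs, low = 0, high = 8), "low/high")
  expect_error(butterworth_bandpass(s2, fs, low = 1, high = 70), "low/high")
})

test_that("cycle detection finds interleaved peaks and valleys", {
  rec <- generate_record(test_spec(hr = 60, noise_sd = 0), 20, 125, seed = 1)
  cyc <- detect_cycles(butterworth_bandpass(get_channel(rec, "PLETH"), 125), 125)
  expect_equal(length(cyc$peaks), 20)
  expect_equal(length(cyc$valleys), length(cyc$peaks) + 1)
  expect_true(all(diff(cyc$peaks) > 0))
  expect_true(all(cyc$valleys[-length(cyc$valleys)] < cyc$peaks))
  expect_true(all(cyc$peaks < cyc$valleys[-1]))
  # flat line: no cycles
  flat <- detect_cycles(rep(0.5, 2500), 125)
  expect_equal(length(flat$peaks), 0)
  expect_equal(length(flat$valleys), 0)
  # the dicrotic bump is not detected as a separate beat at low heart rate
  rec40 <- generate_record(test_spec(hr = 45, noise_sd = 0), 20, 125, seed = 1)
  cyc40 <- detect_cycles(butterworth_bandpass(get_channel(rec40, "PLETH"), 125), 125)
  expect_true(abs(length(cyc40$peaks) - 15) <= 1)
})

test_that("segment gating counts anomalous cycles with a <=3 tolerance", {
  mk_cycles <- function(amps, fs = 125, period_s = 1) {
    nv <- length(amps) + 1
    valleys <- round(seq(1, by = period_s * fs, length.out = nv))
    peaks <- valleys[-nv] + round(period_s * fs / 3)
    ppgvitals:::cycle_index(peaks, valleys, amps, rep(0, nv))
  }
  clean <- mk_cycles(rep(1, 18) + rnorm(18, 0, 0.005))
  qa <- assess_segment(clean, clean, 125)
  expect_true(qa$qualified)
  expect_equal(qa$n_anomalous_ppg, 0)
  three <- mk_cycles(c(rep(1, 15), 10, 10, 10))
  expect_true(assess_segment(three, clean, 125)$qualified)       # boundary
  four <- mk_cycles(c(rep(1, 14), 10, 10, 10, 10))
  expect_false(assess_segment(four, clean, 125)$qualified)
  # cycle lengths outside 20-200 bpm are anomalous
  slow <- mk_cycles(rep(1, 6), period_s = 3.2)
  expect_false(assess_segment(slow, clean, 125)$qualified)
})

test_that("labels average the pressure extrema over detected beats", {
  abp <- rep(0, 300)
  peaks <- c(50, 150, 250); valleys <- c(10, 110, 210, 295)
  abp[peaks] <- c(120, 122, 118)
  abp[valleys] <- c(80, 79, 81, 80)
  cyc <- ppgvitals:::cycle_index(peaks, valleys, abp[peaks], abp[valleys])
  lab <- extract_labels(abp, cyc, spo2 = rep(97.5, 300))
  expect_equal(lab$asbp, 120)
  expect_equal(lab$adbp, 80)
  expect_equal(lab$spo2, 97.5)
  empty <- ppgvitals:::cycle_index(integer(0), integer(0), numeric(0), numeric(0))
  expect_error(extract_labels(abp, empty), "empty cycles")
  # degenerate constant pressure violates the asbp > adbp invariant
  expect_error(qualified_slice("s", "r", 1, 125, rep(0, 100), rep(100, 100),
                               asbp = 100, adbp = 100), "asbp/adbp")
})

test_that("a clean 10-minute record yields the full slice complement", {
  rec <- generate_record(test_spec(hr = 72, noise_sd = 0.02), 600, 125, seed = 9)
  pp <- preprocess_record(rec)
  # cycle-aligned segmentation consumes the samples before the first beat,
  # so a record of exactly 600 s yields 29 or 30 complete 20-s windows
  expect_gte(length(pp$slices), 29)
  expect_equal(sum(pp$report$counts[c("too_few_cycles", "anomalous_cycles",
                                      "label_invariant")]), 0)
  expect_true(all(vapply(pp$slices, function(s) length(s$ppg) == 2500, logical(1))))
  expect_true(all(vapply(pp$slices, function(s) s$asbp > s$adbp, logical(1))))
  # determinism
  pp2 <- preprocess_record(rec)
  expect_identical(lapply(pp$slices, function(s) s$ppg),
                   lapply(pp2$slices, function(s) s$ppg))
})

test_that("a corrupted 20-s region rejects exactly that slice", {
  spec <- synthetic_patient_spec(
    "T9", heart_rate_bpm = 70, noise_sd = 0.02,
    artifact_plan = lapply(c(41, 44, 47, 50, 53), function(s) {
      list(kind = "motion_spike", start_s = s, duration_s = 0.4)
    }))
  pp <- preprocess_record(generate_record(spec, 120, 125, seed = 4))
  expect_equal(unname(pp$report$counts["anomalous_cycles"]), 1)
  expect_equal(length(pp$slices), 4)
})

test_that("a record beyond the flat budget produces no slices", {
  spec <- synthetic_patient_spec(
    "T10", heart_rate_bpm = 70, noise_sd = 0.02,
    artifact_plan = list(list(kind = "flat_line", start_s = 10, duration_s = 8)))
  pp <- preprocess_record(generate_record(spec, 120, 125, seed = 4))
  expect_equal(length(pp$slices), 0)
  expect_equal(pp$report$record_rejected, "flat_fraction")
})

test_that("noiseless slices recover the generator's blood pressure exactly", {
  rec <- generate_record(test_spec(hr = 64, noise_sd = 0), 200, 125, seed = 2)
  pp <- preprocess_record(rec)
  expect_gt(length(pp$slices), 7)
  spec <- attr(rec, "spec")
  for (s in pp$slices) {
    mid_t <- (s$start_sample + 1250) / 125
    gt <- ground_truth_vitals(spec, mid_t)
    expect_lt(abs(s$asbp - gt$asbp), 1)
    expect_lt(abs(s$adbp - gt$adbp), 1)
  }
})
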