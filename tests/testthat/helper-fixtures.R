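# Shared fixture builders. Everything is generated in code at test time.

# A clean synthetic patient spec with controllable noise.
test_spec <- function(id = "T01", hr = 60, noise_sd = 0, ...) {
  synthetic_patient_spec(id, heart_rate_bpm = hr, noise_sd = noise_sd, ...)
}

# Qualified slices from a short clean record run through the real pipeline.
test_slices <- function(n_patients = 2, duration_s = 120, seed = 7,
                        noise_sd = 0.02) {
  cohort <- generate_cohort(n_patients, duration_s = duration_s, fs = 125,
                            seed = seed, noise_sd = noise_sd)
  unlist(lapply(cohort, function(p) preprocess_record(p$record)$slices),
         recursive = FALSE)
}

# Lightweight stand-in slices for split logic (no waveforms needed).
stub_slices <- function(n, subject = "S1", record = "R1") {
  lapply(seq_len(n), function(i) {
    list(subject_id = subject, record_id = record,
         start_sample = i * 2500L, fs = 125,
         asbp = 120 + i, adbp = 70, spo2 = 97)
  })
}

# A tiny model configuration that keeps tests fast; any field can be
# overridden.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 2, d_model = 16, n_heads = 2, d_ff = 24,
         head_hidden = 8, dropout = 0, max_len = 64, n_channels = 3,
         targets = "ASBP"),
    list(...))
  do.call(tst_config, args)
}
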