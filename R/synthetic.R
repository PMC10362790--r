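#' Beat morphology template
#'
#' One cardiac cycle is modelled as an asymmetric Gaussian systolic upstroke
#' with a smaller dicrotic bump on the downslope — the simplest shape with a
#' single unambiguous peak and a valley at the cycle boundary, qualitatively
#' matching a PPG/arterial pulse. The template is periodic and continuous
#' across beat boundaries; sampled cycles place their minimum at the first
#' sample.
#'
#' @param systolic_amplitude Peak-to-valley amplitude in signal units (> 0).
#' @param dicrotic_ratio Relative height of the dicrotic bump in `[0, 1)`.
#' @param systolic_fraction Fraction of the cycle before the systolic peak,
#'   in (0, 1).
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(systolic_amplitude = 1, dicrotic_ratio = 0.3,
                          systolic_fraction = 0.3) {
  assert_scalar_num(systolic_amplitude, "systolic_amplitude",
                    lower = 0, strict_lower = TRUE)
  assert_scalar_num(dicrotic_ratio, "dicrotic_ratio", lower = 0, upper = 1,
                    strict_upper = TRUE)
  assert_scalar_num(systolic_fraction, "systolic_fraction", lower = 0,
                    upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  tpl <- structure(
    list(systolic_amplitude = systolic_amplitude,
         dicrotic_ratio = dicrotic_ratio,
         systolic_fraction = systolic_fraction),
    class = "beat_template")
  # Locate the template's minimum on a fine grid once, so that sampled
  # cycles can start at the valley.
  grid <- seq(0, 1, length.out = 4097)[-4097]
  v <- eval_template_raw(tpl, grid)
  tpl$u_min <- grid[which.min(v)]
  tpl$range <- range(v)
  tpl
}

# Raw periodic template before valley-alignment. Circular Gaussian bumps so
# the waveform is continuous across the beat boundary.
eval_template_raw <- function(tpl, u) {
  circ <- function(u, c) ((u - c + 0.5) %% 1) - 0.5
  sf <- tpl$systolic_fraction
  sl <- sf / 2.5           # upstroke width
  sr <- (1 - sf) / 3.5     # downslope width
  d <- circ(u, sf)
  main <- ifelse(d < 0, exp(-0.5 * (d / sl)^2), exp(-0.5 * (d / sr)^2))
  ud <- sf + 0.5 * (1 - sf)
  sdw <- (1 - sf) / 8
  db <- circ(u, ud)
  main + tpl$dicrotic_ratio * exp(-0.5 * (db / sdw)^2)
}

# Valley-aligned, [0, 1]-normalized template value at cycle phase u in [0,1).
eval_template <- function(tpl, u) {
  v <- eval_template_raw(tpl, (u + tpl$u_min) %% 1)
  (v - tpl$range[1]) / (tpl$range[2] - tpl$range[1])
}

#' Ground-truth map from waveform features to vital signs
#'
#' A deterministic linear map from (PPG pulse amplitude, heart rate,
#' per-patient offset) to ASBP, ADBP and SpO2, plus zero-mean label noise
#' standard deviations per target. The linearity makes parameter recovery by
#' the downstream regression pipeline analytically checkable.
#'
#' Defaults: ASBP = 90 + 25*amplitude + 0.25*hr + offset (mmHg);
#' ADBP = 55 + 8*amplitude + 0.10*hr + 0.5*offset (mmHg);
#' SpO2 = 97 + 1.0*(amplitude - 1) - 0.02*(hr - 75) (%).
#'
#' @param asbp,adbp,spo2 Numeric coefficient vectors
#'   `c(intercept, amplitude, heart_rate, offset)` per target.
#' @param label_noise_sd Named vector of per-beat label noise standard
#'   deviations (ASBP/ADBP in mmHg, SpO2 in percent).
#' @return An object of class `ground_truth_map`.
#' @export
ground_truth_map <- function(asbp = c(90, 25, 0.25, 1),
                             adbp = c(55, 8, 0.10, 0.5),
                             spo2 = c(97 - 1 + 0.02 * 75, 1.0, -0.02, 0),
                             label_noise_sd = c(asbp = 2, adbp = 1.5,
                                                spo2 = 0.3)) {
  stopifnot(length(asbp) == 4, length(adbp) == 4, length(spo2) == 4,
            all(label_noise_sd >= 0))
  structure(list(asbp = asbp, adbp = adbp, spo2 = spo2,
                 label_noise_sd = label_noise_sd),
            class = "ground_truth_map")
}

#' Evaluate the ground-truth map (noiseless)
#'
#' @param map A [ground_truth_map()].
#' @param pulse_amplitude PPG pulse amplitude (signal units); vectorized.
#' @param heart_rate_bpm Heart rate in beats/min.
#' @param personal_offset Per-patient bias in mmHg.
#' @return A list with vectors `asbp`, `adbp`, `spo2`.
#' @export
map_vitals <- function(map, pulse_amplitude, heart_rate_bpm,
                       personal_offset = 0) {
  f <- function(cf) cf[1] + cf[2] * pulse_amplitude +
    cf[3] * heart_rate_bpm + cf[4] * personal_offset
  list(asbp = f(map$asbp), adbp = f(map$adbp),
       spo2 = pmin(100, pmax(70, f(map$spo2))))
}

#' Synthetic patient specification
#'
#' @param patient_id Identifier.
#' @param heart_rate_bpm Heart rate in beats/min, within the physiological
#'   band 20–200.
#' @param pulse_amplitude Baseline PPG pulse amplitude (signal units).
#' @param personal_offset Per-patient bias (mmHg) linking PPG morphology to
#'   blood pressure through the ground-truth map.
#' @param spo2_base Baseline SpO2 in percent (70–100); default from the map.
#' @param noise_sd Additive measurement noise SD on the PPG channel (signal
#'   units; the ABP channel receives `20 * noise_sd` mmHg of noise).
#' @param artifact_plan List of artifacts, each a list with `kind` in
#'   `"flat_line"`, `"flat_peak"`, `"motion_spike"`, `start_s`, `duration_s`
#'   and optional `channel` (default `"PLETH"`).
#' @param map Ground-truth map used to derive baseline ASBP/ADBP.
#' @param amp_mod_frac,amp_mod_period_s Slow sinusoidal modulation of the
#'   pulse amplitude within a record (fraction, seconds); this is what makes
#'   consecutive slices of one patient differ.
#' @return An object of class `synthetic_patient_spec` with derived fields
#'   `asbp_base`, `adbp_base`.
#' @export
synthetic_patient_spec <- function(patient_id, heart_rate_bpm = 75,
                                   pulse_amplitude = 1, personal_offset = 0,
                                   spo2_base = NULL, noise_sd = 0.02,
                                   artifact_plan = list(),
                                   map = ground_truth_map(),
                                   amp_mod_frac = 0.05,
                                   amp_mod_period_s = 60) {
  assert_scalar_num(heart_rate_bpm, "heart_rate_bpm", lower = 20, upper = 200)
  assert_scalar_num(pulse_amplitude, "pulse_amplitude", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(personal_offset, "personal_offset")
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  v <- map_vitals(map, pulse_amplitude, heart_rate_bpm, personal_offset)
  if (is.null(spo2_base)) spo2_base <- v$spo2
  assert_scalar_num(spo2_base, "spo2_base", lower = 70, upper = 100)
  if (v$asbp <= v$adbp) {
    stop_field("personal_offset",
               "implied asbp_base must exceed adbp_base under the ground-truth map")
  }
  for (a in artifact_plan) {
    if (!is.list(a) || is.null(a$kind) ||
        !a$kind %in% c("flat_line", "flat_peak", "motion_spike")) {
      stop_field("artifact_plan",
                 "kind must be one of flat_line, flat_peak, motion_spike")
    }
    if (is.null(a$start_s) || is.null(a$duration_s) || a$duration_s <= 0) {
      stop_field("artifact_plan", "each artifact needs start_s and duration_s > 0")
    }
  }
  structure(
    list(patient_id = as.character(patient_id),
         heart_rate_bpm = heart_rate_bpm,
         pulse_amplitude = pulse_amplitude,
         personal_offset = personal_offset,
         asbp_base = v$asbp, adbp_base = v$adbp, spo2_base = spo2_base,
         noise_sd = noise_sd, artifact_plan = artifact_plan, map = map,
         amp_mod_frac = amp_mod_frac, amp_mod_period_s = amp_mod_period_s),
    class = "synthetic_patient_spec")
}

#' Generate a synthetic waveform record
#'
#' Produces PLETH, ABP and SpO2 channels for one patient. ABP per-beat peaks
#' and valleys track exactly the ASBP/ADBP trajectories implied by the
#' patient's ground-truth map (plus per-beat label noise), so downstream
#' label extraction is checkable against known truth. Artifacts from the
#' spec's plan are injected verbatim.
#'
#' @param spec A [synthetic_patient_spec()].
#' @param duration_s Record duration in seconds (> 0).
#' @param fs Sampling rate in Hz; must exceed twice the beat frequency.
#' @param seed Integer seed; identical `(spec, seed)` give identical output.
#' @param template Beat morphology, a [beat_template()].
#' @param record_id Record identifier.
#' @return A [waveform_record()] with channels `PLETH`, `ABP`, `SpO2`.
#' @export
generate_record <- function(spec, duration_s, fs = 125, seed = NULL,
                            template = beat_template(),
                            record_id = paste0(spec$patient_id, "-R1")) {
  stopifnot(inherits(spec, "synthetic_patient_spec"))
  assert_scalar_num(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (fs <= 2 * spec$heart_rate_bpm / 60) {
    stop_field("fs", "must exceed twice the beat frequency")
  }
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    hr <- spec$heart_rate_bpm
    beat_pos <- t * hr / 60
    beat_idx <- floor(beat_pos) + 1L          # 1-based beat number
    phase <- beat_pos - (beat_idx - 1L)
    n_beats <- max(beat_idx)
    p <- eval_template(template, phase)

    # Per-beat amplitudes (slow modulation) and map-derived vitals.
    t_beat <- (seq_len(n_beats) - 1) * 60 / hr
    amp_k <- spec$pulse_amplitude *
      (1 + spec$amp_mod_frac * sin(2 * pi * t_beat / spec$amp_mod_period_s))
    truth <- map_vitals(spec$map, amp_k, hr, spec$personal_offset)
    sds <- spec$map$label_noise_sd
    noise_on <- spec$noise_sd > 0
    asbp_k <- truth$asbp + if (noise_on) stats::rnorm(n_beats, 0, sds[["asbp"]]) else 0
    adbp_k <- truth$adbp + if (noise_on) stats::rnorm(n_beats, 0, sds[["adbp"]]) else 0
    spo2_k <- pmin(100, pmax(70, spec$spo2_base + (truth$spo2 - mean(truth$spo2)) +
      if (noise_on) stats::rnorm(n_beats, 0, sds[["spo2"]]) else 0))
    asbp_k <- pmax(asbp_k, adbp_k + 5)        # keep pulse pressure positive

    # Per-beat [0,1] normalization of the sampled pulse so the discrete beat
    # maximum/minimum land exactly on the target ASBP/ADBP.
    pmin_k <- tapply(p, beat_idx, min)[as.character(seq_len(n_beats))]
    pmax_k <- tapply(p, beat_idx, max)[as.character(seq_len(n_beats))]
    span <- pmax(pmax_k - pmin_k, 1e-12)
    p01 <- (p - pmin_k[beat_idx]) / span[beat_idx]

    ppg <- amp_k[beat_idx] * p01
    abp <- adbp_k[beat_idx] + (asbp_k[beat_idx] - adbp_k[beat_idx]) * p01
    spo2 <- spo2_k[beat_idx]
    if (noise_on) {
      ppg <- ppg + stats::rnorm(n, 0, spec$noise_sd)
      abp <- abp + stats::rnorm(n, 0, 20 * spec$noise_sd)
      spo2 <- spo2 + stats::rnorm(n, 0, spec$noise_sd)
    }

    for (a in spec$artifact_plan) {
      ch <- if (is.null(a$channel)) "PLETH" else a$channel
      target <- switch(ch, PLETH = "ppg", ABP = "abp", SpO2 = "spo2",
                       stop_field("artifact_plan", "unknown channel"))
      i0 <- round(a$start_s * fs) + 1L
      i1 <- min(n, i0 + round(a$duration_s * fs) - 1L)
      if (i0 > n || i1 < i0) next
      idx <- i0:i1
      x <- get(target)
      if (a$kind == "flat_line") {
        x[idx] <- x[idx[1]]
      } else if (a$kind == "flat_peak") {
        ceiling_v <- min(x[idx]) + 0.6 * (max(x[idx]) - min(x[idx]))
        x[idx] <- pmin(x[idx], ceiling_v)
      } else {                                 # motion_spike
        amp <- 4 * diff(range(x))
        w <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
        x[idx] <- x[idx] + amp * w * sin(2 * pi * 12 * (idx - i0) / fs)
      }
      assign(target, x)
    }

    rec <- waveform_record(spec$patient_id, record_id, fs,
                           list(PLETH = ppg, ABP = abp, SpO2 = spo2))
    attr(rec, "spec") <- spec
    rec
  })
}

#' Expected (noiseless) vitals of a synthetic patient at given times
#'
#' Evaluates the patient's ground-truth map along the record's amplitude
#' modulation, giving the labels a perfect pipeline would recover.
#'
#' @param spec A [synthetic_patient_spec()].
#' @param times_s Numeric vector of times (seconds from record start).
#' @return A list with vectors `asbp`, `adbp`, `spo2`.
#' @export
ground_truth_vitals <- function(spec, times_s) {
  amp <- spec$pulse_amplitude *
    (1 + spec$amp_mod_frac * sin(2 * pi * times_s / spec$amp_mod_period_s))
  map_vitals(spec$map, amp, spec$heart_rate_bpm, spec$personal_offset)
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient parameters from the configured study distributions:
#' heart rate ~ U(55, 95) bpm, pulse amplitude ~ U(0.7, 1.3), personal
#' offset ~ N(0, `offset_sd`) mmHg, and additive noise `noise_sd`. Runs with
#' identical arguments and seed are byte-identical.
#'
#' @param n_patients Number of patients (>= 1).
#' @param duration_s Record duration per patient in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param offset_sd SD of the per-patient blood-pressure offset (mmHg).
#' @param noise_sd Additive PPG noise SD (signal units).
#' @param map Ground-truth map shared by the cohort.
#' @return A list with one element per patient, each a list with `record`
#'   (a [waveform_record()]) and `spec` (the patient's
#'   [synthetic_patient_spec()]).
#' @export
generate_cohort <- function(n_patients, duration_s = 300, fs = 125,
                            seed = 1, offset_sd = 10, noise_sd = 0.02,
                            map = ground_truth_map()) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop_field("n_patients", "must be >= 1")
  }
  n_patients <- as.integer(n_patients)
  params <- with_seed(seed, {
    data.frame(
      hr = stats::runif(n_patients, 55, 95),
      amp = stats::runif(n_patients, 0.7, 1.3),
      offset = stats::rnorm(n_patients, 0, offset_sd))
  })
  lapply(seq_len(n_patients), function(i) {
    spec <- synthetic_patient_spec(
      patient_id = sprintf("P%03d", i),
      heart_rate_bpm = params$hr[i],
      pulse_amplitude = params$amp[i],
      personal_offset = params$offset[i],
      noise_sd = noise_sd, map = map)
    rec <- generate_record(spec, duration_s, fs, seed = derive_seed(seed, i))
    list(record = rec, spec = spec)
  })
}
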