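# Quality control and preprocessing: flat-run handling, Hampel filtering of
# beat-wise pressure extrema, zero-phase band-pass filtering, beat-cycle
# detection, 20-s slicing with anomalous-cycle gating, and label extraction.

#' Detect flat runs in a signal
#'
#' A "flat" stretch is three or more consecutive samples that are pairwise
#' within `eps` of each other (exact repeats for `eps = 0`, the default, as
#' digitized signals quantize). Returns maximal, non-overlapping, sorted
#' runs. Indices are 1-based.
#'
#' @param x Numeric vector.
#' @param min_run Minimum run length to report (default 3).
#' @param eps Equality tolerance on consecutive differences (>= 0).
#' @return A data.frame with columns `start` and `length`.
#' @export
detect_flat_runs <- function(x, min_run = 3, eps = 0) {
  stopifnot(length(x) >= 1, eps >= 0, min_run >= 2)
  if (length(x) < min_run) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  eq <- abs(diff(x)) <= eps
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= (min_run - 1L)
  data.frame(start = starts[keep],
             length = r$lengths[keep] + 1L)
}

#' Fraction of a signal covered by flat runs
#'
#' @param x Numeric vector the runs were computed on.
#' @param runs Output of [detect_flat_runs()] on `x`.
#' @return Fraction in `[0, 1]`.
#' @export
flat_fraction <- function(x, runs) {
  if (nrow(runs) == 0L) return(0)
  sum(runs$length) / length(x)
}

#' Apply the flat-part rule to a record: discard or suture
#'
#' If the flat fraction of either the PPG or the ABP channel exceeds
#' `flat_max` the whole record is rejected. Otherwise the flat samples
#' (union over both channels) are removed at the same indices from all
#' channels and the remainder is concatenated ("sutured"), preserving the
#' sampling rate.
#'
#' @param record A [waveform_record()] containing PLETH and ABP channels.
#' @param flat_max Maximum tolerated flat fraction (default 0.05).
#' @param min_run,eps Passed to [detect_flat_runs()].
#' @return The sutured `waveform_record`, or an object of class
#'   `qc_rejection` (with `reason = "flat_fraction"`) when rejected.
#' @export
drop_or_suture <- function(record, flat_max = 0.05, min_run = 3, eps = 0) {
  ppg <- get_channel(record, "PLETH")
  abp <- get_channel(record, "ABP")
  if (is.null(ppg) || is.null(abp)) {
    stop("record must contain PLETH and ABP channels", call. = FALSE)
  }
  runs_p <- detect_flat_runs(ppg, min_run, eps)
  runs_a <- detect_flat_runs(abp, min_run, eps)
  frac <- max(flat_fraction(ppg, runs_p), flat_fraction(abp, runs_a))
  if (frac > flat_max) {
    return(structure(list(reason = "flat_fraction", fraction = frac),
                     class = "qc_rejection"))
  }
  run_idx <- function(runs) {
    if (nrow(runs) == 0L) integer(0)
    else unlist(Map(function(s, l) s:(s + l - 1L), runs$start, runs$length))
  }
  drop <- union(run_idx(runs_p), run_idx(runs_a))
  if (length(drop) == 0L) return(record)
  channels <- lapply(record$channels, function(ch) ch[-drop])
  out <- waveform_record(record$subject_id, record$record_id, record$fs,
                         channels, record$start_time)
  attr(out, "spec") <- attr(record, "spec")
  out
}

#' Hampel filter (sliding median / MAD outlier replacement)
#'
#' For each sample, the median of a centered window (half-width
#' `floor(window / 2)`, truncated at the series edges) is computed; the
#' sample is replaced by that median iff it deviates from it by more than
#' `n_sigmas` robust sigmas (1.4826 * window MAD). All other samples pass
#' through unchanged.
#'
#' @param series Numeric vector.
#' @param window Nominal window size in samples (default 100).
#' @param n_sigmas Rejection threshold in robust sigmas (default 3).
#' @return Filtered vector, same length.
#' @export
hampel_filter <- function(series, window = 100, n_sigmas = 3) {
  n <- length(series)
  stopifnot(n >= 1, window >= 1)
  k <- floor(window / 2)
  out <- series
  for (i in seq_len(n)) {
    w <- series[max(1L, i - k):min(n, i + k)]
    med <- stats::median(w)
    sig <- 1.4826 * stats::median(abs(w - med))
    if (abs(series[i] - med) > n_sigmas * sig) out[i] <- med
  }
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward-backward (zero phase), so beat timing is not shifted relative to
#' the pressure channel. The effective magnitude response is the square of
#' the single-pass design.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (0 < low < high < fs/2).
#' @param order Filter order of the single-pass design (default 4).
#' @return Filtered vector, same length.
#' @export
butterworth_bandpass <- function(x, fs, low = 0.5, high = 8, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_field("low/high", "need 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# ---- beat-cycle detection --------------------------------------------------

cycle_index <- function(peaks, valleys, peak_values, valley_values) {
  structure(list(peaks = as.integer(peaks), valleys = as.integer(valleys),
                 peak_values = as.numeric(peak_values),
                 valley_values = as.numeric(valley_values)),
            class = "cycle_index")
}

n_cycles <- function(cyc) max(0L, length(cyc$valleys) - 1L)

#' Detect beat cycles (peaks and interleaved valleys)
#'
#' Candidate peaks are local maxima whose height above the local minimum
#' exceeds `prominence_frac` of the rolling amplitude range (window
#' `range_window_s`); peaks closer than the 200-bpm refractory distance are
#' resolved in favor of the taller one. Valleys are the minima between
#' consecutive peaks, plus a leading and a trailing valley, so valleys and
#' peaks strictly interleave. Deterministic.
#'
#' @param x Numeric vector (band-passed PPG or raw ABP).
#' @param fs Sampling rate in Hz.
#' @param min_distance_s Refractory distance between peaks in seconds
#'   (default 60/200, the 200-bpm bound).
#' @param prominence_frac Required height fraction of the rolling range.
#' @param range_window_s Rolling-range window in seconds (default 5).
#' @return A `cycle_index`: integer `peaks`, `valleys` (1-based, strictly
#'   increasing, interleaved) and the signal values at them. Empty when no
#'   cycles are found (e.g. a flat line).
#' @export
detect_cycles <- function(x, fs, min_distance_s = 60 / 200,
                          prominence_frac = 0.3, range_window_s = 5) {
  n <- length(x)
  stopifnot(n >= 2 * fs)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > x[cand - 1L]]      # strict rise into the peak
  empty <- cycle_index(integer(0), integer(0), numeric(0), numeric(0))
  if (length(cand) == 0L) return(empty)
  # topographic prominence: height above the higher of the two saddles on
  # the paths to the nearest taller candidates (or the signal ends)
  h <- x[cand]
  nc <- length(cand)
  prom <- numeric(nc)
  for (j in seq_len(nc)) {
    lsad <- -Inf; k <- j - 1L; lo <- 1L
    while (k >= 1L) { if (h[k] > h[j]) { lo <- cand[k]; break }; k <- k - 1L }
    lsad <- min(x[lo:cand[j]])
    rsad <- -Inf; k <- j + 1L; hi <- n
    while (k <= nc) { if (h[k] > h[j]) { hi <- cand[k]; break }; k <- k + 1L }
    rsad <- min(x[cand[j]:hi])
    prom[j] <- h[j] - max(lsad, rsad)
  }
  w2 <- round(range_window_s * fs / 2)
  ok <- vapply(seq_len(nc), function(j) {
    i <- cand[j]
    lo <- max(1L, i - w2); hi <- min(n, i + w2)
    rng <- range(x[lo:hi])
    prom[j] >= prominence_frac * (rng[2] - rng[1])
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) == 0L) return(empty)
  # refractory suppression: greedy by height
  min_dist <- round(min_distance_s * fs)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L || min(abs(kept - i)) >= min_dist) kept <- c(kept, i)
  }
  peaks <- sort(kept)
  argmin_between <- function(a, b) a + which.min(x[a:b]) - 1L
  valleys <- integer(length(peaks) + 1L)
  valleys[1] <- if (peaks[1] > 1L) argmin_between(1L, peaks[1] - 1L) else 1L
  if (length(peaks) > 1L) {
    for (j in seq_len(length(peaks) - 1L)) {
      valleys[j + 1L] <- argmin_between(peaks[j] + 1L, peaks[j + 1L] - 1L)
    }
  }
  valleys[length(valleys)] <-
    if (peaks[length(peaks)] < n) argmin_between(peaks[length(peaks)] + 1L, n) else n
  if (valleys[1] == peaks[1]) {             # degenerate: peak at sample 1
    peaks <- peaks[-1]; valleys <- valleys[-1]
    if (length(peaks) == 0L) return(empty)
  }
  cycle_index(peaks, valleys, x[peaks], x[valleys])
}

# Restrict a cycle_index to window [s, e]; indices are rebased to the window
# unless rebase = FALSE. Peak-value overrides allow passing Hampel-corrected
# beat series.
restrict_cycles <- function(cyc, s, e, rebase = TRUE,
                            peak_values = NULL, valley_values = NULL) {
  pv <- if (is.null(peak_values)) cyc$peak_values else peak_values
  vv <- if (is.null(valley_values)) cyc$valley_values else valley_values
  vsel <- which(cyc$valleys >= s & cyc$valleys <= e)
  if (length(vsel) < 2L) {
    return(cycle_index(integer(0), integer(0), numeric(0), numeric(0)))
  }
  v <- cyc$valleys[vsel]
  psel <- which(cyc$peaks > v[1] & cyc$peaks < v[length(v)])
  p <- cyc$peaks[psel]
  off <- if (rebase) s - 1L else 0L
  cycle_index(p - off, v - off, pv[psel], vv[vsel])
}

#' Segment quality assessment by anomalous-cycle counting
#'
#' A cycle is anomalous when its valley-to-valley length falls outside the
#' physiological band (60/200 s to 60/20 s, i.e. 20-200 bpm) or its
#' peak-to-valley amplitude deviates from the segment's median amplitude by
#' more than `n_sigmas` robust sigmas (with a 1% relative floor on the scale
#' to avoid zero-MAD degeneracy on near-identical beats). A segment
#' qualifies iff the anomalous count is at most `max_anomalous` in BOTH
#' channels and each channel shows at least `min_cycles` cycles.
#'
#' @param ppg_cycles,abp_cycles `cycle_index` objects computed on the
#'   segment.
#' @param fs Sampling rate in Hz.
#' @param max_anomalous Maximum tolerated anomalous cycles per channel
#'   (default 3).
#' @param n_sigmas Amplitude deviation threshold in robust sigmas.
#' @param min_cycles Minimum cycles required per channel (default 4).
#' @return List: `qualified` (logical), `n_anomalous_ppg`,
#'   `n_anomalous_abp`.
#' @export
assess_segment <- function(ppg_cycles, abp_cycles, fs, max_anomalous = 3,
                           n_sigmas = 3, min_cycles = 4) {
  count_anomalous <- function(cyc) {
    nc <- n_cycles(cyc)
    if (nc < min_cycles || length(cyc$peaks) == 0L) return(Inf)
    len_s <- diff(cyc$valleys) / fs
    bad_len <- len_s < 60 / 200 | len_s > 60 / 20
    np <- length(cyc$peaks)
    amp <- cyc$peak_values - cyc$valley_values[seq_len(np)]
    # MAD scale with a 2% relative floor: the floor keeps near-identical
    # noiseless beats (MAD ~ 0) from degenerating into flagging everything,
    # while spikes still exceed the threshold by orders of magnitude
    sig <- max(robust_sigma(amp), 0.02 * abs(stats::median(amp)))
    bad_amp <- abs(amp - stats::median(amp)) > n_sigmas * sig
    # a cycle is anomalous if EITHER rule flags it (no double counting)
    m <- min(length(bad_len), np)
    sum(bad_len[seq_len(m)] | bad_amp[seq_len(m)]) +
      sum(bad_len[-seq_len(m)]) + sum(bad_amp[-seq_len(m)])
  }
  na_p <- count_anomalous(ppg_cycles)
  na_a <- count_anomalous(abp_cycles)
  list(qualified = is.finite(na_p) && is.finite(na_a) &&
         na_p <= max_anomalous && na_a <= max_anomalous,
       n_anomalous_ppg = na_p, n_anomalous_abp = na_a)
}

#' Extract slice labels from the pressure channel
#'
#' ASBP is the mean of the ABP signal at cycle peak indices, ADBP the mean
#' at valley indices; the SpO2 label, when a saturation trace is supplied,
#' is its mean over the segment.
#'
#' @param abp Numeric ABP segment.
#' @param cycles A `cycle_index` on the segment (nonempty).
#' @param spo2 Optional SpO2 trace over the same segment.
#' @return List with `asbp`, `adbp`, and `spo2` (`NA` when absent).
#' @export
extract_labels <- function(abp, cycles, spo2 = NULL) {
  if (length(cycles$peaks) == 0L || length(cycles$valleys) == 0L) {
    stop("cannot extract labels from empty cycles", call. = FALSE)
  }
  list(asbp = mean(abp[cycles$peaks]),
       adbp = mean(abp[cycles$valleys]),
       spo2 = if (is.null(spo2)) NA_real_ else mean(spo2))
}

# ---- qualified slices ------------------------------------------------------

#' Construct a qualified 20-s slice
#'
#' @param subject_id,record_id Provenance identifiers.
#' @param start_sample 1-based start index within the (sutured) record.
#' @param fs Sampling rate in Hz.
#' @param ppg,abp Equal-length numeric segments (filtered PPG, raw ABP).
#' @param asbp,adbp Labels in mmHg; must satisfy `asbp > adbp`.
#' @param spo2 Optional SpO2 label in percent (`NA` when absent).
#' @return An object of class `qualified_slice`.
#' @export
qualified_slice <- function(subject_id, record_id, start_sample, fs,
                            ppg, abp, asbp, adbp, spo2 = NA_real_) {
  if (length(ppg) != length(abp)) {
    stop_field("ppg/abp", "must have equal length")
  }
  if (!is.finite(asbp) || !is.finite(adbp) || asbp <= adbp) {
    stop_field("asbp/adbp", "labels must be finite with asbp > adbp")
  }
  structure(list(subject_id = as.character(subject_id),
                 record_id = as.character(record_id),
                 start_sample = as.integer(start_sample),
                 fs = as.numeric(fs),
                 ppg = as.numeric(ppg), abp = as.numeric(abp),
                 asbp = as.numeric(asbp), adbp = as.numeric(adbp),
                 spo2 = as.numeric(spo2)),
            class = "qualified_slice")
}

#' QC pipeline configuration
#'
#' @param slice_s Slice length in seconds (default 20).
#' @param flat_max Maximum flat fraction before record rejection.
#' @param min_run,eps Flat-run detection parameters.
#' @param hampel_window,hampel_sigmas Hampel filter parameters for the
#'   beat-wise ABP extremum series.
#' @param bp_low,bp_high,bp_order Butterworth band-pass parameters for PPG.
#' @param max_anomalous,min_cycles Segment gating parameters.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(slice_s = 20, flat_max = 0.05, min_run = 3, eps = 0,
                      hampel_window = 100, hampel_sigmas = 3,
                      bp_low = 0.5, bp_high = 8, bp_order = 4,
                      max_anomalous = 3, min_cycles = 4) {
  structure(as.list(environment()), class = "qc_config")
}

#' Run the full cleaning pipeline on one record
#'
#' In order: flat handling (discard or suture), Hampel filtering of the
#' beat-wise ABP peak/valley series, zero-phase Butterworth band-pass on
#' PPG, segmentation into consecutive non-overlapping slices starting at the
#' first detected cardiac cycle, anomalous-cycle quality gating, and label
#' extraction (beat-extremum averaging). A trailing partial window is
#' dropped.
#'
#' @param record A [waveform_record()] with PLETH and ABP channels.
#' @param config A [qc_config()].
#' @return List with `slices` (list of [qualified_slice()]) and `report`
#'   (named counts: `kept` and per-reason rejections).
#' @export
preprocess_record <- function(record, config = qc_config()) {
  fs <- record$fs
  report <- c(kept = 0L, flat_fraction = 0L, too_few_cycles = 0L,
              anomalous_cycles = 0L, label_invariant = 0L)
  sutured <- drop_or_suture(record, config$flat_max, config$min_run, config$eps)
  if (inherits(sutured, "qc_rejection")) {
    report["flat_fraction"] <- NA_integer_  # whole record, not per segment
    return(list(slices = list(),
                report = list(counts = report, record_rejected = "flat_fraction")))
  }
  ppg <- get_channel(sutured, "PLETH")
  abp <- get_channel(sutured, "ABP")
  spo2 <- get_channel(sutured, "SpO2")
  ppg_f <- butterworth_bandpass(ppg, fs, config$bp_low, config$bp_high,
                                config$bp_order)
  ppg_cyc <- detect_cycles(ppg_f, fs)
  abp_cyc <- detect_cycles(abp, fs)
  L <- round(config$slice_s * fs)
  if (length(ppg_cyc$valleys) < 2L || length(abp_cyc$valleys) < 2L) {
    return(list(slices = list(),
                report = list(counts = report, record_rejected = "no_cycles")))
  }
  # Hampel on the beat-wise ABP extremum series (robust label cleaning).
  abp_pv <- hampel_filter(abp_cyc$peak_values, config$hampel_window,
                          config$hampel_sigmas)
  abp_vv <- hampel_filter(abp_cyc$valley_values, config$hampel_window,
                          config$hampel_sigmas)
  start0 <- ppg_cyc$valleys[1]
  n <- length(ppg)
  starts <- seq.int(start0, by = L, length.out = max(0L, (n - start0 + 1L) %/% L))
  slices <- list()
  for (s in starts) {
    e <- s + L - 1L
    pc <- restrict_cycles(ppg_cyc, s, e)
    ac <- restrict_cycles(abp_cyc, s, e, peak_values = abp_pv,
                          valley_values = abp_vv)
    if (n_cycles(pc) < config$min_cycles || n_cycles(ac) < config$min_cycles) {
      report["too_few_cycles"] <- report["too_few_cycles"] + 1L
      next
    }
    qa <- assess_segment(pc, ac, fs, config$max_anomalous,
                         min_cycles = config$min_cycles)
    if (!qa$qualified) {
      report["anomalous_cycles"] <- report["anomalous_cycles"] + 1L
      next
    }
    asbp <- mean(ac$peak_values)
    adbp <- mean(ac$valley_values)
    spo2_lab <- if (is.null(spo2)) NA_real_ else mean(spo2[s:e])
    if (!is.finite(asbp) || !is.finite(adbp) || asbp <= adbp) {
      report["label_invariant"] <- report["label_invariant"] + 1L
      next
    }
    report["kept"] <- report["kept"] + 1L
    slices[[length(slices) + 1L]] <- qualified_slice(
      record$subject_id, record$record_id, s, fs,
      ppg_f[s:e], abp[s:e], asbp, adbp, spo2_lab)
  }
  list(slices = slices, report = list(counts = report, record_rejected = NA))
}
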