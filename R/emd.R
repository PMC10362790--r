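# Empirical mode decomposition and assembly of the multichannel model input.
# Sifting with cubic-spline envelopes, the standard SD stopping criterion,
# and mirror extension to suppress end effects on 20-s windows.

find_local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # collapse zero slopes onto the previous sign so plateaus yield one extremum
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 1
  turns <- diff(s)
  list(maxima = which(turns < 0) + 1L, minima = which(turns > 0) + 1L)
}

spline_envelope <- function(idx, vals, n, n_mirror = 4L) {
  # mirror extrema about both series ends before fitting the spline: the
  # standard EMD boundary treatment, keeps envelopes flat at the edges
  k <- min(n_mirror, length(idx))
  li <- idx[seq_len(k)]; lv <- vals[seq_len(k)]
  keep <- li > 1L
  ridx <- rev(idx)[seq_len(k)]; rv <- rev(vals)[seq_len(k)]
  rkeep <- ridx < n
  xi <- c(2L - li[keep], idx, 2L * n - ridx[rkeep])
  yi <- c(lv[keep], vals, rv[rkeep])
  o <- order(xi)
  stats::spline(xi[o], yi[o], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterative
#' sifting: cubic-spline envelopes through the local maxima and minima, the
#' running mean of which is subtracted until the standard SD criterion drops
#' below `sd_thresh` (or `max_sift` iterations). Extraction stops when the
#' residue has fewer than two maxima or minima (monotone) or `max_imfs` is
#' reached. End effects are suppressed by mirroring extrema about both
#' series ends before envelope fitting; since each sifting step subtracts
#' the envelope mean from the running signal, the IMFs plus residue
#' reconstruct the input to machine precision by construction.
#'
#' @param x Numeric vector (length >= 4).
#' @param max_imfs Maximum number of IMFs to extract (default 9).
#' @param sd_thresh Sifting stop threshold on the normalized squared change
#'   (Huang's criterion, default 0.2).
#' @param max_sift Maximum sifting iterations per IMF (default 50).
#' @return An object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors) and `residue`. A constant input yields zero IMFs and
#'   `residue = x`.
#' @export
emd_decompose <- function(x, max_imfs = 9, sd_thresh = 0.2, max_sift = 50) {
  n <- length(x)
  stopifnot(n >= 4)
  imfs <- list()
  residue <- x
  repeat {
    ext <- find_local_extrema(residue)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L ||
        length(imfs) >= max_imfs) break
    h <- residue
    for (it in seq_len(max_sift)) {
      eh <- find_local_extrema(h)
      if (length(eh$maxima) < 2L || length(eh$minima) < 2L) break
      upper <- spline_envelope(eh$maxima, h[eh$maxima], n)
      lower <- spline_envelope(eh$minima, h[eh$minima], n)
      env_mean <- (upper + lower) / 2
      denom <- sum(h^2)
      h <- h - env_mean
      if (denom == 0 || sum(env_mean^2) / denom <= sd_thresh) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
  }
  structure(list(imfs = imfs, residue = residue), class = "imf_set")
}

#' Assemble the multichannel model input from an EMD
#'
#' Channels 1..(n-1) are the first IMFs (zero vectors where fewer IMFs
#' exist); the last channel is the input minus the preceding channels, so
#' the channel sum reconstructs the input exactly. The model therefore sees
#' a denoised multiresolution view with no information loss.
#'
#' @param x The original slice signal.
#' @param imfs An `imf_set` from [emd_decompose()] on `x`.
#' @param n_channels Number of output channels (default 4, >= 2).
#' @return A `n_channels x length(x)` numeric matrix.
#' @export
assemble_channels <- function(x, imfs, n_channels = 4) {
  stopifnot(n_channels >= 2)
  l <- length(x)
  ch <- matrix(0, nrow = n_channels, ncol = l)
  for (j in seq_len(n_channels - 1L)) {
    if (j <= length(imfs$imfs)) ch[j, ] <- imfs$imfs[[j]]
  }
  ch[n_channels, ] <- x - colSums(ch[seq_len(n_channels - 1L), , drop = FALSE])
  ch
}

#' Channelize a qualified slice for the model
#'
#' Runs EMD on the slice's PPG signal and assembles the channel matrix,
#' carrying labels and provenance. `decimate` subsamples the slice by an
#' integer factor before decomposition (the PPG band ends at 8 Hz after
#' filtering, so moderate decimation loses little); this is the knob for
#' desk-scale model runs.
#'
#' @param slice A [qualified_slice()].
#' @param n_channels Number of channels (default 4).
#' @param decimate Integer subsampling factor (default 1 = none).
#' @param ... Passed to [emd_decompose()].
#' @return An object of class `channelized_slice`: `channels` (w x l
#'   matrix), labels `asbp`, `adbp`, `spo2`, and provenance.
#' @export
channelize_slice <- function(slice, n_channels = 4, decimate = 1, ...) {
  x <- slice$ppg
  if (decimate > 1) x <- x[seq(1, length(x), by = decimate)]
  dec <- emd_decompose(x, ...)
  structure(list(channels = assemble_channels(x, dec, n_channels),
                 asbp = slice$asbp, adbp = slice$adbp, spo2 = slice$spo2,
                 subject_id = slice$subject_id, record_id = slice$record_id,
                 start_sample = slice$start_sample,
                 fs = slice$fs / decimate),
            class = "channelized_slice")
}
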