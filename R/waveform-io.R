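#' Construct a multichannel waveform record
#'
#' A `waveform_record` holds a subject's raw multichannel signal (for this
#' package typically PPG as `PLETH`, invasive arterial pressure as `ABP`,
#' and optionally `SpO2`) together with its sampling rate and identifiers.
#'
#' @param subject_id Subject identifier.
#' @param record_id Record identifier (a subject may have several records).
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Named list of equal-length numeric vectors, one per
#'   channel; names must be unique.
#' @param start_time Optional start time (any scalar; carried through as-is).
#'
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(subject_id, record_id, fs, channels,
                            start_time = NULL) {
  assert_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop_field("channels", "must be a non-empty named list")
  }
  if (anyDuplicated(names(channels))) {
    stop_field("channels", "channel names must be unique")
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop_field("channels", "all channels must have equal length")
  }
  channels <- lapply(channels, as.numeric)
  structure(
    list(subject_id = as.character(subject_id),
         record_id = as.character(record_id),
         fs = as.numeric(fs), channels = channels, start_time = start_time),
    class = "waveform_record"
  )
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<waveform_record> subject %s, record %s\n", x$subject_id,
              x$record_id))
  cat(sprintf("  fs = %g Hz, %d samples (%.1f s)\n", x$fs, n, n / x$fs))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(record) length(record$channels[[1]])

# ---- channel-name aliasing -------------------------------------------------

# Header dialects vary across ICU exports; canonical names are matched
# case-insensitively against an extensible alias table.
.default_aliases <- list(
  PLETH = c("PLETH", "PPG", "PLETHYSMOGRAM"),
  ABP   = c("ABP", "ART", "ARTERIAL"),
  SpO2  = c("SPO2", "SAO2", "%SPO2", "O2SAT")
)

#' Resolve a canonical channel from a record by alias
#'
#' @param record A `waveform_record`.
#' @param canonical Canonical channel name (`"PLETH"`, `"ABP"`, `"SpO2"`).
#' @param aliases Alias table: named list mapping canonical names to accepted
#'   header spellings (matched case-insensitively).
#' @return The channel vector, or `NULL` when absent.
#' @export
get_channel <- function(record, canonical, aliases = .default_aliases) {
  accepted <- toupper(c(canonical, aliases[[canonical]]))
  hit <- which(toupper(names(record$channels)) %in% accepted)
  if (length(hit) == 0L) return(NULL)
  record$channels[[hit[1]]]
}

has_channel <- function(record, canonical, aliases = .default_aliases) {
  !is.null(get_channel(record, canonical, aliases))
}

# ---- plain-text array container -------------------------------------------

#' Write / read a waveform record
#'
#' Two on-disk layouts are supported. The native container is a
#' self-describing text file: a first line holding a JSON metadata object
#' (subject, record, fs, channel names, sample count) followed by one CSV row
#' per sample. A WFDB-subset layout (MIT-format `.hea` header plus 16-bit
#' little-endian `.dat` signal file with per-channel gain/baseline) is read
#' and written when `path` ends in `.hea`.
#'
#' @param record A `waveform_record`.
#' @param path File path. `.hea` selects the WFDB-subset layout; anything
#'   else the native text container.
#' @return `read_record` returns a `waveform_record`; `write_record`
#'   invisibly returns `path`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  if (grepl("\\.hea$", path)) return(write_record_wfdb(record, path))
  meta <- list(format = "ppgvitals-record", version = 1L,
               subject_id = record$subject_id, record_id = record$record_id,
               fs = record$fs, channel_names = names(record$channels),
               n_samples = n_samples(record))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), con)
  m <- do.call(cbind, record$channels)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.hea$", path)) return(read_record_wfdb(path))
  first <- readLines(path, n = 1L)
  meta <- tryCatch(jsonlite::fromJSON(first), error = function(e) NULL)
  if (is.null(meta) || !identical(meta$format, "ppgvitals-record")) {
    stop("unknown record format: ", path, call. = FALSE)
  }
  m <- utils::read.table(path, skip = 1L, sep = ",", header = FALSE,
                         colClasses = "numeric")
  if (nrow(m) != meta$n_samples || ncol(m) != length(meta$channel_names)) {
    stop(sprintf(
      "integrity error: header declares %d samples x %d channels, data has %d x %d",
      meta$n_samples, length(meta$channel_names), nrow(m), ncol(m)),
      call. = FALSE)
  }
  channels <- stats::setNames(lapply(seq_len(ncol(m)), function(j) m[[j]]),
                              meta$channel_names)
  waveform_record(meta$subject_id, meta$record_id, meta$fs, channels)
}

# ---- WFDB subset (MIT header + format-16 signal file) ----------------------

write_record_wfdb <- function(record, path) {
  base <- sub("\\.hea$", "", basename(path))
  dir <- dirname(path)
  dat_name <- paste0(base, ".dat")
  n <- n_samples(record)
  nsig <- length(record$channels)
  gains <- numeric(nsig); baselines <- integer(nsig)
  adc <- matrix(0L, nrow = n, ncol = nsig)
  for (j in seq_len(nsig)) {
    x <- record$channels[[j]]
    rng <- range(x)
    span <- max(rng[2] - rng[1], 1e-12)
    gains[j] <- 60000 / span                    # use most of the 16-bit range
    baselines[j] <- as.integer(round(-rng[1] * gains[j] - 30000))
    adc[, j] <- as.integer(round(x * gains[j] + baselines[j]))
  }
  hdr <- c(sprintf("%s %d %g %d", base, nsig, record$fs, n),
           sprintf("%s 16 %.6f(%d)/unit 16 0 0 0 0 %s",
                   dat_name, gains, baselines, names(record$channels)))
  writeLines(hdr, path)
  con <- file(file.path(dir, dat_name), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(path)
}

read_record_wfdb <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_tok) < 4L) stop("malformed WFDB header: ", path, call. = FALSE)
  rec_name <- head_tok[1]
  nsig <- as.integer(head_tok[2])
  fs <- as.numeric(head_tok[3])
  n <- as.integer(head_tok[4])
  if (length(lines) < 1L + nsig) {
    stop("malformed WFDB header: fewer signal lines than declared", call. = FALSE)
  }
  sig <- lines[1 + seq_len(nsig)]
  dat_files <- character(nsig); gains <- numeric(nsig)
  baselines <- numeric(nsig); ch_names <- character(nsig)
  for (j in seq_len(nsig)) {
    tok <- strsplit(trimws(sig[j]), "\\s+")[[1]]
    dat_files[j] <- tok[1]
    if (tok[2] != "16") {
      stop("unsupported WFDB signal format: ", tok[2], call. = FALSE)
    }
    gspec <- tok[3]                     # gain(baseline)/units, parts optional
    g <- sub("\\(.*", "", sub("/.*", "", gspec))
    gains[j] <- as.numeric(g)
    if (is.na(gains[j]) || gains[j] == 0) gains[j] <- 200
    b <- regmatches(gspec, regexec("\\((-?[0-9]+)\\)", gspec))[[1]]
    baselines[j] <- if (length(b) == 2L) as.numeric(b[2]) else 0
    ch_names[j] <- if (length(tok) >= 9L) {
      paste(tok[9:length(tok)], collapse = " ")
    } else sprintf("sig%d", j)
  }
  if (length(unique(dat_files)) != 1L) {
    stop("multi-file WFDB records are not supported", call. = FALSE)
  }
  dat_path <- file.path(dirname(path), dat_files[1])
  if (!file.exists(dat_path)) stop("signal file missing: ", dat_path, call. = FALSE)
  raw_n <- file.size(dat_path) / 2
  vals <- readBin(dat_path, "integer", n = raw_n, size = 2L, signed = TRUE,
                  endian = "little")
  if (length(vals) != n * nsig) {
    stop(sprintf(
      "integrity error: header declares %d samples x %d channels but signal file holds %d values",
      n, nsig, length(vals)), call. = FALSE)
  }
  adc <- matrix(vals, ncol = nsig, byrow = TRUE)
  channels <- stats::setNames(lapply(seq_len(nsig), function(j) {
    (adc[, j] - baselines[j]) / gains[j]
  }), ch_names)
  waveform_record(rec_name, rec_name, fs, channels)
}

# ---- record manifests and inclusion filters --------------------------------

#' Build a manifest over waveform records
#'
#' @param paths Character vector of record file paths, or a list of
#'   `waveform_record` objects (then `bytes` is estimated from memory size).
#' @return A data.frame with one row per record: `subject_id`, `record_id`,
#'   `duration_s`, `channel_names` (comma-joined), `bytes`, `path`.
#' @export
record_manifest <- function(paths) {
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (inherits(p, "waveform_record")) {
      rec <- p; path <- NA_character_
      bytes <- n_samples(rec) * length(rec$channels) * 2  # as stored 16-bit
    } else {
      rec <- read_record(p); path <- p
      bytes <- file.size(p)
      if (grepl("\\.hea$", p)) {
        dat <- file.path(dirname(p), paste0(sub("\\.hea$", "", basename(p)), ".dat"))
        if (file.exists(dat)) bytes <- bytes + file.size(dat)
      }
    }
    data.frame(subject_id = rec$subject_id, record_id = rec$record_id,
               duration_s = n_samples(rec) / rec$fs,
               channel_names = paste(names(rec$channels), collapse = ","),
               bytes = bytes, path = path, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Record-level inclusion filter
#'
#' Retains records that (i) last at least `min_duration_s`, (ii) contain all
#' `required` channels (alias-aware, case-insensitive), and (iii) occupy at
#' least `min_bytes` on disk. Every excluded record is reported with the
#' reasons it failed.
#'
#' @param manifest A manifest data.frame from [record_manifest()].
#' @param min_duration_s Minimum duration in seconds (default 600 = 10 min).
#' @param required Canonical channel names that must be present.
#' @param min_bytes Minimum stored size in bytes (default 17 * 1024).
#' @param aliases Channel alias table (see [get_channel()]).
#' @return A list of class `record_filter` with elements `kept` (manifest
#'   subset), `excluded` (manifest subset plus a `reasons` column), and the
#'   thresholds used.
#' @export
filter_records <- function(manifest, min_duration_s = 600,
                           required = c("PLETH", "ABP"),
                           min_bytes = 17 * 1024,
                           aliases = .default_aliases) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) {
    stop("manifest must be a non-empty data.frame", call. = FALSE)
  }
  reasons <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- character(0)
    if (manifest$duration_s[i] < min_duration_s) r <- c(r, "duration")
    present <- toupper(strsplit(manifest$channel_names[i], ",")[[1]])
    for (req in required) {
      accepted <- toupper(c(req, aliases[[req]]))
      if (!any(present %in% accepted)) r <- c(r, "missing channel")
    }
    if (!is.na(manifest$bytes[i]) && manifest$bytes[i] < min_bytes) {
      r <- c(r, "size")
    }
    reasons[[i]] <- unique(r)
  }
  keep <- lengths(reasons) == 0L
  excluded <- manifest[!keep, , drop = FALSE]
  excluded$reasons <- vapply(reasons[!keep], paste, character(1), collapse = ";")
  structure(list(kept = manifest[keep, , drop = FALSE], excluded = excluded,
                 min_duration_s = min_duration_s, required = required,
                 min_bytes = min_bytes),
            class = "record_filter")
}

#' @export
print.record_filter <- function(x, ...) {
  cat(sprintf("<record_filter> kept %d, excluded %d\n",
              nrow(x$kept), nrow(x$excluded)))
  if (nrow(x$excluded) > 0) {
    tab <- table(unlist(strsplit(x$excluded$reasons, ";")))
    for (nm in names(tab)) cat(sprintf("  %-16s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

# ---- slice datasets --------------------------------------------------------

#' Write / read qualified-slice datasets
#'
#' Stores a list of qualified 20-s slices as a single self-describing text
#' file: a JSON metadata line, a CSV label table (subject, record, start
#' sample, ASBP, ADBP, SpO2), then one whitespace-separated row per slice and
#' channel for the PPG and ABP signal arrays. The round trip is lossless.
#'
#' @param slices List of `qualified_slice` objects sharing `fs` and length.
#' @param path Output file path.
#' @return `read_slices` returns the list of slices; `write_slices`
#'   invisibly returns `path`.
#' @export
write_slices <- function(slices, path) {
  if (length(slices) > 0) {
    lens <- vapply(slices, function(s) length(s$ppg), integer(1))
    fss <- vapply(slices, function(s) s$fs, numeric(1))
    if (length(unique(lens)) > 1L || length(unique(fss)) > 1L) {
      stop("all slices must share fs and length", call. = FALSE)
    }
  }
  meta <- list(format = "ppgvitals-slices", version = 1L,
               n = length(slices),
               fs = if (length(slices)) slices[[1]]$fs else NA,
               len = if (length(slices)) length(slices[[1]]$ppg) else 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), con)
  for (s in slices) {
    lab <- c(s$subject_id, s$record_id, format(s$start_sample),
             format(s$asbp, digits = 17),
             format(s$adbp, digits = 17),
             if (is.null(s$spo2) || is.na(s$spo2)) "NA"
             else format(s$spo2, digits = 17))
    writeLines(paste(lab, collapse = ","), con)
    writeLines(paste(format(s$ppg, digits = 17, trim = TRUE), collapse = " "), con)
    writeLines(paste(format(s$abp, digits = 17, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_slices
#' @export
read_slices <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  if (!identical(meta$format, "ppgvitals-slices")) {
    stop("unknown slice dataset format: ", path, call. = FALSE)
  }
  out <- vector("list", meta$n)
  for (i in seq_len(meta$n)) {
    base <- 1L + (i - 1L) * 3L
    lab <- strsplit(lines[base + 1L], ",")[[1]]
    ppg <- as.numeric(strsplit(lines[base + 2L], " +")[[1]])
    abp <- as.numeric(strsplit(lines[base + 3L], " +")[[1]])
    out[[i]] <- qualified_slice(
      subject_id = lab[1], record_id = lab[2],
      start_sample = as.integer(lab[3]), fs = meta$fs,
      ppg = ppg, abp = abp,
      asbp = as.numeric(lab[4]), adbp = as.numeric(lab[5]),
      spo2 = if (lab[6] == "NA") NA_real_ else as.numeric(lab[6]))
  }
  out
}
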