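#' EEG recording container
#'
#' Holds one continuous multichannel EEG record: a channels x samples matrix
#' in microvolts, the sampling rate, channel labels, and the record's start
#' time `t0` on a per-subject monotonic timeline (seconds, 0 at the start of
#' the subject's first record). All intervals in the package are half-open
#' `[start, end)` seconds on that timeline.
#'
#' @param signal numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per signal row.
#' @param t0 start time of this record on the subject timeline (seconds).
#' @param record_id identifier, typically the EDF file stem.
#' @param band name of the frequency band the signal currently holds
#'   (`"broadband"` for unfiltered data).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_labels = NULL, t0 = 0,
                          record_id = "record", band = "broadband") {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)")
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("signal contains NaN/Inf values; excise them before ingestion")
  if (length(fs) != 1L || fs <= 0) stop("`fs` must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- sprintf("CH%02d", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal))
    stop("number of channel labels (", length(channel_labels),
         ") does not match signal rows (", nrow(signal), ")")
  structure(list(signal = signal, fs = fs,
                 channel_labels = as.character(channel_labels),
                 t0 = as.numeric(t0), record_id = as.character(record_id),
                 band = band),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s: %d ch x %d samples @ %g Hz, t0 = %gs, band = %s>\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs, x$t0, x$band))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `eeg_recording`.
#' @export
recording_duration <- function(recording) ncol(recording$signal) / recording$fs

## ---- EDF binary format (16-bit) ------------------------------------------
## Fixed-layout ASCII header (256 bytes + 256 per signal), little-endian
## int16 data records. Only equal per-channel rates are supported downstream.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_unit_scale <- function(dim) {
  switch(trimws(dim), uV = 1, "µV" = 1, mV = 1e3, V = 1e6, 1)
}

# Low-level writer: per-channel signal list + per-channel samples-per-record.
# Exists separately so tests can construct deliberately inconsistent files.
write_edf_raw <- function(path, signals, fs_per_channel, labels,
                          phys_range = c(-5000, 5000), record_dur = 1) {
  if (is.matrix(signals)) {                 # channels x samples fast path
    sig_mat <- signals
    signals <- lapply(seq_len(nrow(sig_mat)), function(i) NULL)
    ns <- nrow(sig_mat)
    lens <- rep(ncol(sig_mat), ns)
  } else {
    sig_mat <- NULL
    ns <- length(signals)
    lens <- vapply(signals, length, numeric(1))
  }
  spr <- as.integer(round(fs_per_channel * record_dur))
  nrec_each <- lens / spr
  if (length(unique(nrec_each)) != 1L || any(nrec_each != round(nrec_each)))
    stop("all channels must span the same whole number of data records")
  nrec <- as.integer(nrec_each[1])
  dmin <- -32768L; dmax <- 32767L
  pmin <- phys_range[1]; pmax <- phys_range[2]
  rng <- if (is.null(sig_mat)) range(vapply(signals, function(s) range(s),
                                            numeric(2)))
         else range(sig_mat)
  if (rng[1] < pmin || rng[2] > pmax)
    stop(sprintf("signal amplitude [%g, %g] outside EDF physical range [%g, %g]",
                 rng[1], rng[2], pmin, pmax))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8); wr("", 44)
  wr(nrec, 8); wr(format(record_dur), 8); wr(ns, 4)
  fields <- list(list(labels, 16), list(rep("", ns), 80), list(rep("uV", ns), 8),
                 list(rep(format(pmin), ns), 8), list(rep(format(pmax), ns), 8),
                 list(rep(format(dmin), ns), 8), list(rep(format(dmax), ns), 8),
                 list(rep("", ns), 80), list(spr, 8), list(rep("", ns), 32))
  for (f in fields) for (i in seq_len(ns)) wr(f[[1]][i], f[[2]])

  scale <- (dmax - dmin) / (pmax - pmin)
  if (length(unique(spr)) == 1L) {
    ## equal rates: digitize and interleave records in few vectorized passes
    ## (range was checked above, so no clamping pass is needed)
    m <- if (is.null(sig_mat)) matrix(unlist(signals, use.names = FALSE),
                                      ncol = ns)
         else t(sig_mat)
    dig <- as.integer(round(m * scale + (dmin - pmin * scale)))
    dim(dig) <- c(spr[1], nrec, ns)
    dig <- aperm(dig, c(1, 3, 2))
    dim(dig) <- NULL
    writeBin(dig, con, size = 2L, endian = "little")
  } else {
    dig <- lapply(signals, function(s)
      as.integer(pmin(pmax(round((s - pmin) * scale + dmin), dmin), dmax)))
    for (r in seq_len(nrec)) {
      for (i in seq_len(ns)) {
        idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
        writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
      }
    }
  }
  invisible(path)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one data record per second; optionally writes a companion
#' plain-text seizure annotation ("summary") file in the dialect that
#' [parse_seizure_summary()] reads. Values are quantized to the declared
#' physical range; the round trip through [read_edf()] reproduces the signal
#' within one quantization step.
#'
#' @param recording an [eeg_recording()].
#' @param path output `.edf` path.
#' @param events optional data frame of seizures (`onset_s`, `offset_s`,
#'   subject-timeline seconds) to write as a companion summary file.
#' @param summary_path companion summary path; defaults to
#'   `<path minus .edf>-summary.txt` when `events` is given.
#' @param phys_range physical (microvolt) min/max declared in the header;
#'   signal values outside it are an error.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, events = NULL, summary_path = NULL,
                      phys_range = c(-5000, 5000)) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- ncol(recording$signal)
  if (n %% recording$fs != 0)
    stop("signal length must be a whole number of seconds for EDF export")
  write_edf_raw(path, recording$signal,
                rep(recording$fs, nrow(recording$signal)),
                recording$channel_labels, phys_range)
  if (!is.null(events)) {
    if (is.null(summary_path))
      summary_path <- paste0(sub("\\.edf$", "", path), "-summary.txt")
    recs <- data.frame(record_id = recording$record_id,
                       start_s = recording$t0,
                       end_s = recording$t0 + recording_duration(recording))
    write_seizure_summary(recs, events, summary_path, fs = recording$fs)
  }
  invisible(path)
}

.edf_read_field <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)),
         character(1))
}

#' Read an EDF file
#'
#' Minimal 16-bit EDF reader: parses the fixed-layout header, converts data
#' to physical units (microvolts), and returns an [eeg_recording()]. All
#' channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param channel_selection optional character vector of channel labels; the
#'   returned rows follow this order. Missing labels are an error.
#' @param t0 subject-timeline start second to attach to the recording.
#' @param record_id identifier; defaults to the file stem.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channel_selection = NULL, t0 = 0,
                     record_id = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edf_read_field(con, 8)
  invisible(.edf_read_field(con, 80, 2))          # patient, recording ids
  invisible(.edf_read_field(con, 8, 2))           # start date, time
  header_bytes <- suppressWarnings(as.integer(.edf_read_field(con, 8)))
  invisible(.edf_read_field(con, 44))
  nrec <- suppressWarnings(as.integer(.edf_read_field(con, 8)))
  rec_dur <- suppressWarnings(as.numeric(.edf_read_field(con, 8)))
  ns <- suppressWarnings(as.integer(.edf_read_field(con, 4)))
  if (anyNA(c(header_bytes, nrec, rec_dur, ns)) || ns < 1L || nrec < 0L)
    stop("malformed EDF header in ", path)
  if (header_bytes != 256L * (ns + 1L))
    stop("malformed EDF header (header-bytes field inconsistent) in ", path)

  labels <- .edf_read_field(con, 16, ns)
  invisible(.edf_read_field(con, 80, ns))         # transducer
  dims <- .edf_read_field(con, 8, ns)
  pmin <- as.numeric(.edf_read_field(con, 8, ns))
  pmax <- as.numeric(.edf_read_field(con, 8, ns))
  dmin <- as.numeric(.edf_read_field(con, 8, ns))
  dmax <- as.numeric(.edf_read_field(con, 8, ns))
  invisible(.edf_read_field(con, 80, ns))         # prefilter
  spr <- suppressWarnings(as.integer(.edf_read_field(con, 8, ns)))
  invisible(.edf_read_field(con, 32, ns))
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop("malformed EDF signal headers in ", path)
  if (length(unique(spr)) != 1L)
    stop("inconsistent per-channel sampling rates in ", path,
         " (samples per record: ", paste(unique(spr), collapse = ", "), ")")
  fs <- spr[1] / rec_dur

  raw <- readBin(con, integer(), n = nrec * sum(spr), size = 2L,
                 endian = "little")
  if (length(raw) != nrec * sum(spr))
    stop("malformed EDF: truncated data section in ", path)
  x <- array(as.numeric(raw), dim = c(spr[1], ns, nrec))
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(spr[1] * nrec, ns)
  for (i in seq_len(ns)) {                     # scale column-wise (contiguous)
    q <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    x[, i] <- ((x[, i] - dmin[i]) * q + pmin[i]) * .edf_unit_scale(dims[i])
  }
  signal <- t(x)

  if (!is.null(channel_selection)) {
    idx <- match(channel_selection, labels)
    if (anyNA(idx))
      stop("channel(s) not present in ", path, ": ",
           paste(channel_selection[is.na(idx)], collapse = ", "))
    signal <- signal[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  eeg_recording(signal, fs, labels, t0 = t0,
                record_id = record_id %||% sub("\\.edf$", "", basename(path)))
}

## ---- seizure annotation summary files ------------------------------------

.fmt_hms <- function(s) {
  s <- round(s)
  sprintf("%d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

.parse_hms <- function(x) {
  p <- as.numeric(strsplit(trimws(x), ":")[[1]])
  if (length(p) != 3L || anyNA(p)) stop("unparseable time field: ", x)
  p[1] * 3600 + p[2] * 60 + p[3]
}

#' Write a seizure annotation summary file
#'
#' Plain-text per-subject annotation in the CHB-MIT summary dialect: one
#' stanza per record with file name, start/end clock time (hours may exceed
#' 24 on long timelines), a seizure count, and per-seizure start/end times in
#' seconds from the record start.
#'
#' @param records data frame with `record_id`, `start_s`, `end_s`
#'   (subject-timeline seconds).
#' @param events data frame with `onset_s`, `offset_s` on the subject
#'   timeline (and optionally `record_id`); each event must fall inside one
#'   record.
#' @param path output path.
#' @param fs sampling rate noted in the file header.
#' @return `path`, invisibly.
#' @export
write_seizure_summary <- function(records, events, path, fs = 256) {
  records <- records[order(records$start_s), , drop = FALSE]
  lines <- c(sprintf("Data Sampling Rate: %g Hz", fs), "")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ev <- events[events$onset_s >= r$start_s & events$onset_s < r$end_s, ,
                 drop = FALSE]
    lines <- c(lines,
               sprintf("File Name: %s.edf", r$record_id),
               sprintf("File Start Time: %s", .fmt_hms(r$start_s)),
               sprintf("File End Time: %s", .fmt_hms(r$end_s)),
               sprintf("Number of Seizures in File: %d", nrow(ev)))
    if (nrow(ev) > 0) {
      for (j in seq_len(nrow(ev))) {
        lines <- c(lines,
                   sprintf("Seizure %d Start Time: %g seconds", j,
                           ev$onset_s[j] - r$start_s),
                   sprintf("Seizure %d End Time: %g seconds", j,
                           ev$offset_s[j] - r$start_s))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a seizure annotation summary file
#'
#' Reads the CHB-MIT-style summary dialect (see [write_seizure_summary()]):
#' `File Name` stanzas with start/end clock times and per-seizure start/end
#' times in seconds from the record start. Clock times that wrap past
#' midnight are unrolled so that all records lie on one monotonic subject
#' timeline starting at 0 at the first record.
#'
#' @param x a file path, or the summary text as a character vector.
#' @return A list with `records` (data frame: `record_id`, `start_s`,
#'   `end_s`) and `events` (data frame: `record_id`, `onset_s`, `offset_s`,
#'   subject-timeline seconds).
#' @export
parse_seizure_summary <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
           else unlist(strsplit(x, "\n"))
  starts <- grep("^\\s*File Name:", lines)
  if (length(starts) == 0L) stop("no 'File Name:' stanzas found")
  bounds <- c(starts, length(lines) + 1L)

  recs <- list(); evs <- list()
  day_offset <- 0; prev_end_raw <- -Inf; prev_end <- -Inf
  for (k in seq_along(starts)) {
    chunk <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    getv <- function(pat) {
      m <- grep(pat, chunk, value = TRUE)
      if (length(m) == 0L) return(NULL)
      trimws(sub(pat, "", m[1]))
    }
    rid <- sub("\\.edf$", "", getv("^\\s*File Name:\\s*"))
    st_raw <- getv("^\\s*File Start Time:\\s*")
    en_raw <- getv("^\\s*File End Time:\\s*")
    if (is.null(st_raw) || is.null(en_raw))
      stop("stanza for ", rid, " lacks File Start/End Time")
    st <- .parse_hms(st_raw); en <- .parse_hms(en_raw)
    if (en < st) en <- en + 86400          # record itself wraps midnight
    if (st + day_offset < prev_end) day_offset <- day_offset + 86400
    st <- st + day_offset; en <- en + day_offset
    if (st < prev_end)
      stop("record ", rid, " overlaps the previous record on the timeline")
    prev_end <- en
    dur <- en - st

    nsz <- getv("^\\s*Number of Seizures in File:\\s*")
    if (is.null(nsz)) stop("stanza for ", rid, " lacks a seizure count")
    nsz <- as.integer(nsz)
    if (is.na(nsz)) stop("unparseable seizure count for ", rid)
    sz_st <- grep("^\\s*Seizure( \\d+)? Start Time:", chunk, value = TRUE)
    sz_en <- grep("^\\s*Seizure( \\d+)? End Time:", chunk, value = TRUE)
    if (length(sz_st) != nsz || length(sz_en) != nsz)
      stop("stanza for ", rid, ": seizure count (", nsz,
           ") does not match the listed times")
    num <- function(v) as.numeric(sub("\\s*seconds?\\s*$", "",
                                      sub("^.*Time:\\s*", "", v)))
    on <- num(sz_st); off <- num(sz_en)
    if (anyNA(on) || anyNA(off)) stop("unparseable seizure times for ", rid)
    if (any(off <= on))
      stop("seizure end time <= start time in record ", rid)
    if (any(on < 0) || any(off > dur))
      stop("seizure outside record duration in record ", rid)

    recs[[k]] <- data.frame(record_id = rid, start_s = st, end_s = en)
    if (nsz > 0)
      evs[[k]] <- data.frame(record_id = rid, onset_s = st + on,
                             offset_s = st + off)
  }
  records <- do.call(rbind, recs)
  events <- if (length(evs)) do.call(rbind, evs)
            else data.frame(record_id = character(), onset_s = numeric(),
                            offset_s = numeric())
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(records) <- rownames(events) <- NULL
  if (nrow(events) > 1 &&
      any(events$onset_s[-1] < events$offset_s[-nrow(events)]))
    stop("seizure events overlap on the subject timeline")
  list(records = records, events = events)
}

#' Recorded spans of a subject
#'
#' @param records data frame with `start_s`, `end_s` as returned in
#'   `parse_seizure_summary()$records`.
#' @return data frame of half-open recorded intervals, sorted.
#' @export
recorded_spans <- function(records) {
  s <- records[order(records$start_s), c("start_s", "end_s"), drop = FALSE]
  rownames(s) <- NULL
  s
}
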