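#' Synthetic EEG generator configuration
#'
#' The generator emulates the statistical premise the classifier exploits:
#' multichannel 1/f^alpha background activity whose band power depends on
#' the seizure stage -- by default, gamma-band power raised 1.5x in
#' preictal and 1.25x in postictal spans relative to interictal baseline --
#' plus large rhythmic ictal bursts and optional EMG-like broadband
#' high-frequency artifacts. It makes no attempt at physiological seizure
#' morphology; it controls exactly the band-power feature, which is what
#' the pipeline's recovery tests require.
#'
#' @param n_channels,fs geometry of the recordings (23 channels, 256 Hz).
#' @param band_power named list: stage -> named numeric vector of per-band
#'   power multipliers relative to interictal (bands as in [eeg_bands()]).
#' @param noise_alpha exponent of the 1/f^alpha background.
#' @param background_rms_uv RMS of the background in microvolts.
#' @param ictal_amp_uv amplitude of the rhythmic ictal burst.
#' @param artifact_rate_per_h expected EMG bursts per hour (Poisson).
#' @param artifact_amp_uv,artifact_dur_s amplitude/duration ranges of one
#'   EMG burst.
#' @param seed master seed; every record derives its own stream from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 23, fs = 256,
                         band_power = list(PREICTAL = c(gamma = 1.5),
                                           POSTICTAL = c(gamma = 1.25)),
                         noise_alpha = 1, background_rms_uv = 30,
                         ictal_amp_uv = 300, artifact_rate_per_h = 0,
                         artifact_amp_uv = c(200, 2000),
                         artifact_dur_s = c(0.5, 2), seed = 1) {
  stopifnot(n_channels >= 1, fs > 0, background_rms_uv > 0)
  if (any(unlist(band_power) <= 0)) stop("band power multipliers must be > 0")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 band_power = band_power, noise_alpha = noise_alpha,
                 background_rms_uv = background_rms_uv,
                 ictal_amp_uv = ictal_amp_uv,
                 artifact_rate_per_h = artifact_rate_per_h,
                 artifact_amp_uv = artifact_amp_uv,
                 artifact_dur_s = artifact_dur_s, seed = as.integer(seed)),
            class = "synth_config")
}

# Amplitude spectrum of the background on FFT grid `f` (two-sided), with the
# per-band gains of `stage` applied. The low-frequency knee at 0.5 Hz keeps
# 1/f^alpha integrable; the overall `scale` is chosen once from the
# interictal spectrum so that configured multipliers translate into exact
# expected power ratios.
.stage_amplitude <- function(f, stage, config, scale = 1) {
  a <- pmax(abs(f), 0.5)^(-config$noise_alpha / 2)
  gains <- config$band_power[[stage]]
  if (!is.null(gains)) {
    bands <- eeg_bands(config$fs)
    for (bn in names(gains)) {
      b <- bands[bands$name == bn, ]
      if (nrow(b) != 1) stop("unknown band in band_power: ", bn)
      sel <- abs(f) > b$low_hz & abs(f) <= b$high_hz
      a[sel] <- a[sel] * sqrt(gains[[bn]])
    }
  }
  a * scale
}

# E[signal^2] of spectrally shaped white noise with amplitude vector a:
# ifft(a * fft(white)) has expected power mean(a^2).
.background_scale <- function(config) {
  n <- 8192
  f <- (seq_len(n) - 1) / n * config$fs
  f <- ifelse(f > config$fs / 2, f - config$fs, f)
  a <- pmax(abs(f), 0.5)^(-config$noise_alpha / 2)
  config$background_rms_uv / sqrt(mean(a^2))
}

# One stage span for all channels: shaped Gaussian noise, plus the rhythmic
# burst on ictal spans. Channels are drawn in pairs from one complex
# spectrum: with the (symmetric) amplitude a(|f|), the real and imaginary
# parts of sqrt(N)^-1 * F^-1{a z}, z complex white Gaussian, are two
# independent real channels with expected power mean(a^2).
.synth_span <- function(stage, n_pts, config, scale) {
  fs <- config$fs
  f <- (seq_len(n_pts) - 1) / n_pts * fs
  f <- ifelse(f > fs / 2, f - fs, f)
  amp_stage <- if (stage %in% names(config$band_power)) stage else "INTERICTAL"
  a <- .stage_amplitude(f, amp_stage, config, scale)
  out <- matrix(0, config$n_channels, n_pts)
  ch <- 1L
  while (ch <= config$n_channels) {
    z <- complex(real = rnorm(n_pts), imaginary = rnorm(n_pts))
    y <- fft(a * z, inverse = TRUE) / sqrt(n_pts)
    out[ch, ] <- Re(y)
    if (ch + 1L <= config$n_channels) out[ch + 1L, ] <- Im(y)
    ch <- ch + 2L
  }
  if (stage == "ICTAL") {
    tt <- (seq_len(n_pts) - 1) / fs
    for (ch in seq_len(config$n_channels)) {
      ph <- runif(1, 0, 2 * pi)
      out[ch, ] <- out[ch, ] +
        config$ictal_amp_uv * sin(2 * pi * 4 * tt + ph) +
        0.3 * config$ictal_amp_uv * sin(2 * pi * 8 * tt + 2 * ph)
    }
  }
  out
}

# Broadband >60 Hz EMG-like bursts added in place.
.add_artifacts <- function(signal, fs, config) {
  dur_total_h <- ncol(signal) / fs / 3600
  n_art <- stats::rpois(1, config$artifact_rate_per_h * dur_total_h)
  if (n_art == 0) return(signal)
  h <- signal::fir1(100, 60 / (fs / 2), type = "high")
  for (k in seq_len(n_art)) {
    dur <- runif(1, config$artifact_dur_s[1], config$artifact_dur_s[2])
    amp <- runif(1, config$artifact_amp_uv[1], config$artifact_amp_uv[2])
    npts <- as.integer(dur * fs)
    start <- sample.int(ncol(signal) - npts, 1)
    chans <- sample.int(nrow(signal), sample(seq_len(min(3, nrow(signal))), 1))
    burst <- as.numeric(signal::filter(h, rnorm(npts + 200)))[-(1:200)]
    burst <- burst / max(abs(burst)) * amp
    for (ch in chans)
      signal[ch, start:(start + npts - 1L)] <-
        signal[ch, start:(start + npts - 1L)] + burst
  }
  signal
}

#' Generate one continuous stage-labeled recording
#'
#' Builds the signal span by span from a stage schedule. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @param schedule data frame with `stage`, `duration_s` (whole seconds)
#'   describing the recording from its start.
#' @param t0 timeline start second; `record_id` its name.
#' @return list with `recording` ([eeg_recording()]), `events` (data frame
#'   of ictal spans: `onset_s`, `offset_s`) and `stages` (ground-truth
#'   intervals).
#' @export
generate_recording <- function(config, schedule, t0 = 0,
                               record_id = "synth") {
  stopifnot(inherits(config, "synth_config"))
  if (any(schedule$duration_s <= 0) ||
      any(schedule$duration_s %% 1 != 0))
    stop("schedule durations must be positive whole seconds")
  if (!all(schedule$stage %in% STAGES)) stop("unknown stage in schedule")
  scale <- .background_scale(config)
  with_seed(config$seed, {
    parts <- lapply(seq_len(nrow(schedule)), function(i)
      .synth_span(schedule$stage[i],
                  as.integer(schedule$duration_s[i] * config$fs),
                  config, scale))
    signal <- do.call(cbind, parts)
    signal <- .add_artifacts(signal, config$fs, config)
  })
  ends <- t0 + cumsum(schedule$duration_s)
  starts <- c(t0, head(ends, -1))
  ict <- schedule$stage == "ICTAL"
  list(recording = eeg_recording(signal, config$fs,
                                 sprintf("SYN%02d", seq_len(config$n_channels)),
                                 t0 = t0, record_id = record_id),
       events = data.frame(onset_s = starts[ict], offset_s = ends[ict]),
       stages = data.frame(stage = schedule$stage, start_s = starts,
                           end_s = ends))
}

# Plan the records of a synthetic subject: a record around every seizure
# (full preictal + ictal + a postictal stub) and interictal records centered
# in the buffered zones between/around seizures.
.plan_subject <- function(n_seizures, gap_s, policy, ictal_len_s,
                          postictal_record_s, interictal_record_s,
                          lead_in_s, edge_interictal) {
  gap_s <- rep_len(gap_s, max(n_seizures - 1, 1))
  pre <- policy$preictal_len_s
  onset <- numeric(n_seizures)
  onset[1] <- pre + lead_in_s
  if (edge_interictal)
    onset[1] <- onset[1] + interictal_record_s +
      policy$interictal_post_buffer_s
  if (n_seizures > 1)
    for (k in 2:n_seizures)
      onset[k] <- onset[k - 1] + ictal_len_s + gap_s[k - 1]
  offset <- onset + ictal_len_s

  recs <- data.frame(kind = character(0), start_s = numeric(0),
                     end_s = numeric(0))
  if (edge_interictal)
    recs <- rbind(recs, data.frame(kind = "interictal", start_s = 0,
                                   end_s = interictal_record_s))
  for (k in seq_len(n_seizures)) {
    recs <- rbind(recs, data.frame(kind = "seizure",
                                   start_s = onset[k] - pre - lead_in_s,
                                   end_s = offset[k] + postictal_record_s))
    ## interictal record inside the buffered zone after this seizure
    zone_lo <- offset[k] + policy$interictal_pre_buffer_s
    zone_hi <- if (k < n_seizures)
      onset[k + 1] - policy$interictal_post_buffer_s
    else if (edge_interictal) zone_lo + 2 * interictal_record_s
    else zone_lo   # no trailing interictal record
    if (zone_hi - zone_lo >= interictal_record_s) {
      mid <- floor((zone_lo + zone_hi - interictal_record_s) / 2)
      recs <- rbind(recs, data.frame(kind = "interictal", start_s = mid,
                                     end_s = mid + interictal_record_s))
    }
  }
  recs <- recs[order(recs$start_s), ]
  rownames(recs) <- NULL
  list(records = recs,
       events = data.frame(onset_s = onset, offset_s = offset))
}

#' Generate a complete synthetic subject on disk
#'
#' Lays out a multi-record subject with `n_seizures` annotated seizures
#' separated by `gap_s` seconds (offset to next onset), writes one EDF per
#' record plus a seizure summary file via the io layer, and returns the
#' ground truth. Records cover each seizure's full preictal hour plus a
#' postictal stub, and interictal records are placed inside the buffered
#' interictal zones, so the staging of the written files recovers the
#' intended stages.
#'
#' @param config a [synth_config()].
#' @param n_seizures number of seizures.
#' @param gap_s seconds from each seizure's offset to the next onset
#'   (scalar or vector of length `n_seizures - 1`).
#' @param dir output directory (created if needed).
#' @param policy the [staging_policy()] the layout must respect.
#' @param ictal_len_s seizure duration.
#' @param postictal_record_s recorded seconds kept after each seizure.
#' @param interictal_record_s length of each interictal record.
#' @param lead_in_s recorded margin before each preictal window.
#' @param edge_interictal also place interictal records before the first
#'   and after the last seizure.
#' @return list with `dir`, `summary_path`, `records`, `events`, `stages`
#'   (ground-truth staging of the recorded spans).
#' @export
generate_subject <- function(config, n_seizures = 3, gap_s = 9 * 3600,
                             dir = tempfile("synth_subject"),
                             policy = staging_policy(), ictal_len_s = 60,
                             postictal_record_s = 600,
                             interictal_record_s = 3600, lead_in_s = 60,
                             edge_interictal = TRUE) {
  plan <- .plan_subject(n_seizures, gap_s, policy, ictal_len_s,
                        postictal_record_s, interictal_record_s, lead_in_s,
                        edge_interictal)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spans <- plan$records[, c("start_s", "end_s")]
  stages <- assign_stages(spans, plan$events, policy)

  records <- data.frame(record_id = sprintf("rec%02d",
                                            seq_len(nrow(plan$records))),
                        start_s = plan$records$start_s,
                        end_s = plan$records$end_s)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ## per-record schedule = ground-truth stages clipped to the record
    sch <- stages[stages$end_s > r$start_s & stages$start_s < r$end_s, ,
                  drop = FALSE]
    sch$start_s <- pmax(sch$start_s, r$start_s)
    sch$end_s <- pmin(sch$end_s, r$end_s)
    sch <- data.frame(stage = sch$stage,
                      duration_s = sch$end_s - sch$start_s)
    cfg_i <- config
    cfg_i$seed <- (config$seed %% 2000000L) * 1000L + i   # per-record stream
    g <- generate_recording(cfg_i, sch, t0 = r$start_s,
                            record_id = r$record_id)
    write_edf(g$recording, file.path(dir, paste0(r$record_id, ".edf")))
  }
  summary_path <- file.path(dir, "subject-summary.txt")
  write_seizure_summary(records, plan$events, summary_path, fs = config$fs)
  truth <- list(records = records, events = plan$events, stages = stages)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  c(list(dir = dir, summary_path = summary_path), truth)
}
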