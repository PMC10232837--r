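# Shared fixture builders. Everything is generated in code; no data files.

# A small broadband recording with given channels/duration.
make_recording <- function(n_ch = 3, dur_s = 60, fs = 256, sd = 30,
                           t0 = 0, record_id = "rec", seed = 1) {
  preictal:::with_seed(seed,
    eeg_recording(matrix(rnorm(n_ch * dur_s * fs, sd = sd), n_ch),
                  fs, t0 = t0, record_id = record_id))
}

# A sample_set built directly from an array of per-sample sd values.
make_samples <- function(stages, n_time = 80, n_ch = 3, fs = 16,
                         sd = rep(1, length(stages)), seed = 1,
                         start_s = NULL, record_id = "rec") {
  n <- length(stages)
  x <- preictal:::with_seed(seed,
    array(rnorm(n_time * n_ch * n), dim = c(n_time, n_ch, n)))
  for (j in seq_len(n)) x[, , j] <- x[, , j] * sd[j]
  window_s <- n_time / fs
  if (is.null(start_s)) start_s <- (seq_len(n) - 1) * window_s
  sample_set(x, data.frame(record_id = record_id, start_s = start_s,
                           stage = stages),
             fs = fs, window_s = window_s)
}

# Brute-force per-second stage labeler: the independent oracle for
# assign_stages. Labels the second [k, k+1) via its midpoint, one stage
# rule at a time in precedence order.
oracle_stage_per_second <- function(spans, events, policy) {
  secs <- unlist(lapply(seq_len(nrow(spans)), function(i)
    seq(spans$start_s[i], spans$end_s[i] - 1)))
  mids <- secs + 0.5
  lead <- select_leading_seizures(events, policy, spans)
  in_any <- function(lo, hi) {
    if (length(lo) == 0) return(rep(FALSE, length(mids)))
    rowSums(outer(mids, lo, ">=") & outer(mids, hi, "<")) > 0
  }
  li <- lead$onset_s[lead$leading]
  ict <- in_any(events$onset_s, events$offset_s)
  pre <- in_any(li - policy$preictal_len_s, li)
  post <- in_any(events$offset_s, events$offset_s + policy$postictal_len_s)
  # a second is barred from interictal inside [onset - post_buffer,
  # offset + pre_buffer) of any seizure
  forb <- in_any(events$onset_s - policy$interictal_post_buffer_s,
                 events$offset_s + policy$interictal_pre_buffer_s)
  lab <- ifelse(ict, "ICTAL",
         ifelse(pre, "PREICTAL",
         ifelse(post, "POSTICTAL",
         ifelse(forb, "EXCLUDED", "INTERICTAL"))))
  data.frame(second = secs, stage = lab)
}

# Exhaustive threshold oracle for the majority-vote fusion rules.
oracle_classify <- function(labels, n_classes) {
  n <- length(labels)
  npre <- sum(labels == "PREICTAL")
  if (n_classes == 2) {
    if (npre / n > 1 / 2) "PREICTAL" else "INTERICTAL"
  } else {
    if (npre / n > 1 / 3) "PREICTAL"
    else {
      npost <- sum(labels == "POSTICTAL")
      nint <- sum(labels == "INTERICTAL")
      if (npost > nint) "POSTICTAL" else "INTERICTAL"
    }
  }
}

# Expand assign_stages output to per-second labels for comparison.
stages_per_second <- function(stages) {
  secs <- unlist(lapply(seq_len(nrow(stages)), function(i)
    seq(stages$start_s[i], stages$end_s[i] - 1)))
  lab <- rep(stages$stage, stages$end_s - stages$start_s)
  data.frame(second = secs, stage = lab)[order(secs), ]
}

# A tiny, fast model config for unit tests (not the reduced profile).
tiny_model_config <- function(...) {
  args <- list(...)
  defaults <- list(fs = 16, window_s = 5, n_channels = 3, lstm_units = 8,
                   dropout = 0.2, max_epochs = 6, patience = 6,
                   batch_size = 32, lr = 3e-3, seed = 7)
  do.call(model_config, utils::modifyList(defaults, args))
}

# Random seizure schedule on a recorded timeline, for property tests.
random_schedule <- function(seed, total_h = 12) {
  preictal:::with_seed(seed, {
    n_sz <- sample(0:4, 1)
    total <- total_h * 3600
    onsets <- sort(sample.int(total - 600, n_sz))
    durs <- sample(20:120, max(n_sz, 1), replace = TRUE)[seq_len(n_sz)]
    ev <- data.frame(onset_s = onsets, offset_s = onsets + durs)
    ## drop overlapping events
    if (nrow(ev) > 1) {
      keep <- c(TRUE, ev$onset_s[-1] > ev$offset_s[-nrow(ev)])
      ev <- ev[keep, , drop = FALSE]
    }
    ## recorded spans: either continuous or split with gaps
    if (runif(1) < 0.5) {
      spans <- data.frame(start_s = 0, end_s = total)
    } else {
      cuts <- sort(sample.int(total - 1, 4))
      spans <- data.frame(start_s = c(0, cuts[2], cuts[4]),
                          end_s = c(cuts[1], cuts[3], total))
    }
    list(spans = spans, events = ev)
  })
}
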