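#' Windowed sample set
#'
#' The classifier's unit of prediction: non-overlapping fixed-length windows
#' of a (typically band-filtered) recording, each carrying the stage label of
#' the interval it was cut from. Stored densely as a `time x channel x
#' sample` array plus a metadata frame.
#'
#' @param x numeric array `(window_s * fs) x channels x n`.
#' @param meta data frame with one row per sample: `record_id`, `start_s`
#'   (timeline second of the window start), `stage`.
#' @param fs sampling rate; `window_s` window length in seconds.
#' @param band band name the samples were filtered to.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(x, meta, fs, window_s, band = "broadband") {
  stopifnot(is.array(x), length(dim(x)) == 3, nrow(meta) == dim(x)[3])
  if (dim(x)[1] != window_s * fs)
    stop("window length must be exactly window_s * fs points")
  if (!all(meta$stage %in% c(CLASS_STAGES_3)))
    stop("classifier samples must be PREICTAL, POSTICTAL or INTERICTAL")
  structure(list(x = x, meta = meta, fs = fs, window_s = window_s,
                 band = band),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  tab <- table(factor(x$meta$stage, levels = CLASS_STAGES_3))
  cat(sprintf("<sample_set: %d samples of %gs x %d ch @ %g Hz, band %s | %s>\n",
              n_samples(x), x$window_s, dim(x$x)[2], x$fs, x$band,
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Number of samples in a sample set
#' @param samples a [sample_set()].
#' @export
n_samples <- function(samples) dim(samples$x)[3]

#' Subset a sample set
#' @param samples a [sample_set()]; @param idx integer or logical index.
#' @export
subset_samples <- function(samples, idx) {
  if (is.logical(idx)) idx <- which(idx)
  sample_set(samples$x[, , idx, drop = FALSE],
             samples$meta[idx, , drop = FALSE],
             samples$fs, samples$window_s, samples$band)
}

#' Concatenate sample sets
#' @param ... sample sets with identical geometry.
#' @export
bind_samples <- function(...) {
  ss <- list(...)
  ss <- ss[vapply(ss, Negate(is.null), logical(1))]
  if (length(ss) == 0) stop("nothing to bind")
  nonempty <- ss[vapply(ss, function(s) n_samples(s) > 0, logical(1))]
  if (length(nonempty) > 0) ss <- nonempty else ss <- ss[1]
  if (length(ss) == 1) return(ss[[1]])
  d1 <- dim(ss[[1]]$x)
  x <- array(0, dim = c(d1[1], d1[2], sum(vapply(ss, n_samples, numeric(1)))))
  at <- 0L
  for (s in ss) {
    n <- n_samples(s)
    x[, , at + seq_len(n)] <- s$x
    at <- at + n
  }
  meta <- do.call(rbind, lapply(ss, `[[`, "meta"))
  rownames(meta) <- NULL
  sample_set(x, meta, ss[[1]]$fs, ss[[1]]$window_s, ss[[1]]$band)
}

#' Cut a recording into stage-labeled windows
#'
#' Windows of `window_s` seconds tile each preictal/postictal/interictal
#' stage interval from its start; a window is emitted only when it lies
#' entirely inside one such interval *and* inside the recording, so windows
#' straddling stage boundaries or file edges are dropped. Ictal and excluded
#' time never becomes a sample.
#'
#' @param recording an [eeg_recording()] (typically band-filtered).
#' @param stage_intervals data frame from [assign_stages()].
#' @param window_s window length in seconds; `window_s * fs` must be an
#'   integer.
#' @return A [sample_set()] (possibly with zero samples).
#' @export
segment_recording <- function(recording, stage_intervals, window_s = 5) {
  fs <- recording$fs
  if (abs(window_s * fs - round(window_s * fs)) > 1e-9)
    stop("window_s * fs must be an integer number of points")
  wlen <- as.integer(round(window_s * fs))
  t0 <- recording$t0
  t1 <- t0 + recording_duration(recording)

  keep <- stage_intervals$stage %in% CLASS_STAGES_3
  iv <- stage_intervals[keep, , drop = FALSE]
  starts <- numeric(0); stages <- character(0)
  for (i in seq_len(nrow(iv))) {
    lo <- max(iv$start_s[i], t0)
    hi <- min(iv$end_s[i], t1)
    if (hi - lo < window_s) next
    ## anchor the tiling at the interval start, then keep in-record windows
    k0 <- ceiling((lo - iv$start_s[i]) / window_s - 1e-9)
    ws <- iv$start_s[i] + seq(k0, by = 1,
                              length.out = floor((hi - iv$start_s[i]) / window_s) - k0 + 1) * window_s
    ws <- ws[ws >= lo - 1e-9 & ws + window_s <= hi + 1e-9]
    starts <- c(starts, ws)
    stages <- c(stages, rep(iv$stage[i], length(ws)))
  }
  n <- length(starts)
  x <- array(0, dim = c(wlen, nrow(recording$signal), n))
  for (j in seq_len(n)) {
    a <- as.integer(round((starts[j] - t0) * fs)) + 1L
    x[, , j] <- t(recording$signal[, a:(a + wlen - 1L), drop = FALSE])
  }
  meta <- data.frame(record_id = rep(recording$record_id, n),
                     start_s = starts,
                     stage = stages, stringsAsFactors = FALSE)
  sample_set(x, meta, fs, window_s, recording$band)
}

#' Remove EMG-contaminated samples
#'
#' Deterministic two-rule artifact screen for muscle activity: a sample is
#' rejected when any channel's peak absolute amplitude exceeds `amp_max_uv`,
#' or when on any channel more than `hf_frac` of the (non-DC) power lies
#' above `hf_cut_hz` -- scalp EMG is broadband with most energy above 60 Hz,
#' unlike gamma-band EEG.
#'
#' @param samples a [sample_set()].
#' @param amp_max_uv peak-amplitude threshold in microvolts.
#' @param hf_frac maximal tolerated fraction of power above `hf_cut_hz`.
#' @param hf_cut_hz high-frequency cut for the power-fraction rule.
#' @return list with `kept` (a [sample_set()]), `rejected` (data frame:
#'   `record_id`, `start_s`, `reason`) and `n_rejected`.
#' @export
reject_emg_artifacts <- function(samples, amp_max_uv = 500, hf_frac = 0.85,
                                 hf_cut_hz = 60) {
  n <- n_samples(samples)
  wlen <- dim(samples$x)[1]
  n_ch <- dim(samples$x)[2]
  freqs <- (seq_len(wlen) - 1) / wlen * samples$fs
  hi <- freqs > hf_cut_hz & freqs < samples$fs - hf_cut_hz  # both spectrum halves
  nz <- freqs > 0
  reason <- character(n)
  if (n > 0) {
    ## one batched FFT over all channel-windows of the set
    flat <- samples$x
    dim(flat) <- c(wlen, n_ch * n)
    amp <- apply(abs(flat), 2, max)
    dim(amp) <- c(n_ch, n)
    reason[apply(amp, 2, max) > amp_max_uv] <- "amplitude"
    P <- Mod(stats::mvfft(sweep(flat, 2, colMeans(flat))))^2
    frac <- colSums(P[hi, , drop = FALSE]) /
      pmax(colSums(P[nz, , drop = FALSE]), .Machine$double.eps)
    dim(frac) <- c(n_ch, n)
    hf_bad <- apply(frac, 2, max) > hf_frac
    reason[reason == "" & hf_bad] <- "hf_power"
  }
  bad <- reason != ""
  list(kept = subset_samples(samples, !bad),
       rejected = data.frame(record_id = samples$meta$record_id[bad],
                             start_s = samples$meta$start_s[bad],
                             reason = reason[bad]),
       n_rejected = sum(bad))
}

#' Undersample the interictal class
#'
#' Interictal recordings dwarf the preictal (and postictal) hours, so the
#' interictal class is uniformly subsampled without replacement to the size
#' of the largest non-interictal class; preictal and postictal samples are
#' never touched. Deterministic given `seed`.
#'
#' @param samples a [sample_set()].
#' @param seed RNG seed for the subsample.
#' @return A balanced [sample_set()].
#' @export
balance_classes <- function(samples, seed = 1) {
  st <- samples$meta$stage
  n_inter <- sum(st == "INTERICTAL")
  target <- max(sum(st == "PREICTAL"), sum(st == "POSTICTAL"))
  if (target == 0) stop("no preictal or postictal samples to balance against")
  if (n_inter <= target) {
    if (n_inter < target)
      warning("fewer interictal (", n_inter, ") than minority-class (",
              target, ") samples; keeping all interictal samples")
    return(samples)
  }
  keep_inter <- with_seed(seed, sort(sample(which(st == "INTERICTAL"), target)))
  subset_samples(samples, sort(c(which(st != "INTERICTAL"), keep_inter)))
}
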