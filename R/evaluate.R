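#' Majority-vote fusion of sample labels within a segment
#'
#' Two-class rule: the segment is PREICTAL iff strictly more than half of
#' its samples are predicted preictal. Three-class rule: PREICTAL iff
#' strictly more than one third are preictal; otherwise the plurality of the
#' remaining classes, with ties resolved to INTERICTAL. Boundary cases
#' (exactly half, exactly one third) therefore resolve to the non-alarm
#' side. Thresholds are compared in integer arithmetic, so they are exact.
#'
#' @param labels character vector of sample labels within one segment.
#' @param n_classes 2 or 3.
#' @return A single segment label.
#' @export
classify_segment <- function(labels, n_classes = 2) {
  n <- length(labels)
  if (n == 0) stop("empty segment")
  npre <- sum(labels == "PREICTAL")
  if (n_classes == 2) {
    return(if (2L * npre > n) "PREICTAL" else "INTERICTAL")
  }
  if (3L * npre > n) return("PREICTAL")
  npost <- sum(labels == "POSTICTAL")
  ninter <- sum(labels == "INTERICTAL")
  if (npost > ninter) "POSTICTAL" else "INTERICTAL"
}

#' Confusion counts and sensitivity/specificity at segment level
#'
#' The preictal class is the positive: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), with every non-preictal label counted as
#' negative. In three-class mode the per-class true-positive rates are also
#' returned.
#'
#' @param true,pred equal-length label vectors.
#' @param n_classes 2 or 3.
#' @return list of class `segment_eval`: `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `per_class_TPR`, `n`.
#' @export
segment_metrics <- function(true, pred, n_classes = 2) {
  if (length(true) != length(pred))
    stop("label vectors differ in length")
  lev <- .class_levels(n_classes)
  bad <- setdiff(unique(c(true, pred)), lev)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  pos_t <- true == "PREICTAL"; pos_p <- pred == "PREICTAL"
  TP <- sum(pos_t & pos_p); FN <- sum(pos_t & !pos_p)
  FP <- sum(!pos_t & pos_p); TN <- sum(!pos_t & !pos_p)
  tpr <- vapply(lev, function(cl) {
    i <- true == cl
    if (!any(i)) NA_real_ else mean(pred[i] == cl)
  }, numeric(1))
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
                 per_class_TPR = tpr, n = length(true)),
            class = "segment_eval")
}

#' @export
print.segment_eval <- function(x, ...) {
  cat(sprintf("<segment_eval: n=%d TP=%d FP=%d TN=%d FN=%d sens=%.4f spec=%.4f>\n",
              x$n, x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity))
  invisible(x)
}

# Fuse a prediction stream into L-second segments inside stage-pure runs.
# Vectorized application of the classify_segment rules (integer-exact
# thresholds): chunks are columns of a per_seg x nseg matrix per run.
.fuse_stream <- function(true, pred, per_seg, n_classes) {
  r <- rle(true)
  ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1) + 1L)
  ft <- vector("list", length(r$values)); fp <- ft
  for (i in seq_along(r$values)) {
    nseg <- r$lengths[i] %/% per_seg
    if (nseg == 0) next
    idx <- starts[i]:(starts[i] + nseg * per_seg - 1L)
    npre <- colSums(matrix(pred[idx] == "PREICTAL", per_seg))
    if (n_classes == 2) {
      lab <- ifelse(2L * npre > per_seg, "PREICTAL", "INTERICTAL")
    } else {
      npost <- colSums(matrix(pred[idx] == "POSTICTAL", per_seg))
      ninter <- colSums(matrix(pred[idx] == "INTERICTAL", per_seg))
      lab <- ifelse(3L * npre > per_seg, "PREICTAL",
                    ifelse(npost > ninter, "POSTICTAL", "INTERICTAL"))
    }
    fp[[i]] <- lab
    ft[[i]] <- rep(r$values[i], nseg)
  }
  list(true = unlist(ft) %||% character(0),
       pred = unlist(fp) %||% character(0))
}

#' Sensitivity/specificity versus segment length (minimum time prediction window)
#'
#' Fuses per-sample predictions into segments of increasing length by the
#' majority-vote rules and scores each length, yielding the curve from
#' which the minimum time prediction window (MTPW) is read: the smallest
#' length at which both metrics are within `tol` of their maximum
#' thereafter (the plateau).
#'
#' @param true,pred per-sample label vectors, time-ordered within
#'   stage-pure runs (`true` must be constant within a run).
#' @param window_lengths segment lengths in seconds, multiples of
#'   `window_s`.
#' @param window_s the sample length in seconds.
#' @param n_classes 2 or 3.
#' @param tol plateau tolerance.
#' @return list with `curve` (data frame: `length_s`, `sensitivity`,
#'   `specificity`, `n_segments`) and `mtpw_s`.
#' @export
mtpw_scan <- function(true, pred, window_lengths = seq(5, 150, by = 5),
                      window_s = 5, n_classes = 2, tol = 0.02) {
  if (any(window_lengths %% window_s != 0))
    stop("window lengths must be multiples of the sample length")
  rows <- lapply(window_lengths, function(L) {
    f <- .fuse_stream(true, pred, as.integer(L / window_s), n_classes)
    m <- segment_metrics(f$true, f$pred, n_classes)
    data.frame(length_s = L, sensitivity = m$sensitivity,
               specificity = m$specificity, n_segments = m$n)
  })
  curve <- do.call(rbind, rows)
  ok <- rep(TRUE, nrow(curve))
  for (i in seq_len(nrow(curve))) {
    later <- seq(i, nrow(curve))
    for (met in c("sensitivity", "specificity")) {
      v <- curve[[met]][later]
      if (all(is.na(v))) next
      if (!is.na(curve[[met]][i]) &&
          curve[[met]][i] < max(v, na.rm = TRUE) - tol) ok[i] <- FALSE
    }
  }
  list(curve = curve,
       mtpw_s = if (any(ok)) curve$length_s[which(ok)[1]] else NA_real_)
}

#' Raise alarms from a prediction stream
#'
#' A sliding window holding the trailing `window_min` minutes of 5-s sample
#' predictions advances one sample at a time; an alarm is raised the first
#' time strictly more than `frac` of the window is predicted preictal.
#' After an alarm, no further alarm is raised until `refractory_s` elapses
#' (default SPH + SOP, so one alarm covers one prediction window). Gaps in
#' the recording reset the window. The alarm is stamped at the end of the
#' sample that completed the window.
#'
#' @param pred per-sample predicted labels, time-ordered.
#' @param times per-sample start seconds on the subject timeline.
#' @param window_s sample length (seconds).
#' @param window_min alarm window length in minutes.
#' @param frac preictal fraction that must be strictly exceeded.
#' @param refractory_s post-alarm dead time in seconds.
#' @param mode `"sliding"` (default) or `"tumbling"` (non-overlapping
#'   windows).
#' @return data frame of class `alarm_events`: `time_s`, `frac`.
#' @export
raise_alarms <- function(pred, times, window_s = 5, window_min = 10,
                         frac = 0.70, refractory_s = 1200 + 1800,
                         mode = c("sliding", "tumbling")) {
  mode <- match.arg(mode)
  nwin <- as.integer(window_min * 60 / window_s)
  if (length(pred) < nwin) {
    warning("stream shorter than one alarm window; no alarms possible")
    return(data.frame(time_s = numeric(0), frac = numeric(0)))
  }
  if (is.unsorted(times)) stop("prediction stream must be time-ordered")
  is_pre <- as.integer(pred == "PREICTAL")
  ## contiguous runs: break where consecutive samples are not window_s apart
  brk <- c(TRUE, abs(diff(times) - window_s) > 1e-6)
  run <- cumsum(brk)
  out_t <- numeric(0); out_f <- numeric(0)
  last_alarm <- -Inf
  for (r in unique(run)) {
    i <- which(run == r)
    if (length(i) < nwin) next
    cs <- cumsum(is_pre[i])
    counts <- cs[nwin:length(i)] - c(0, cs)[nwin:length(i) - nwin + 1]
    idx <- if (mode == "sliding") seq_along(counts)
           else seq(1L, length(counts), by = nwin)
    for (j in idx) {
      if (counts[j] > frac * nwin + 1e-9) {
        t_al <- times[i[j + nwin - 1L]] + window_s
        if (t_al - last_alarm >= refractory_s) {
          out_t <- c(out_t, t_al)
          out_f <- c(out_f, counts[j] / nwin)
          last_alarm <- t_al
        }
      }
    }
  }
  data.frame(time_s = out_t, frac = out_f)
}

#' Score alarms against seizures under the SOP/SPH framework
#'
#' An alarm at time `t` is correct iff some leading-seizure onset lies in
#' `[t + SPH, t + SPH + SOP)`: the seizure must not occur during the
#' prediction horizon (reserved for intervention) and must occur within the
#' occurrence period. A seizure is predicted iff at least one alarm is
#' correct for it; alarms correct for no seizure are false alarms. The
#' warning time of a predicted seizure is its onset minus its first correct
#' alarm.
#'
#' @param alarms data frame with `time_s` (from [raise_alarms()]), sorted.
#' @param seizures data frame of leading seizures with `onset_s`.
#' @param sop_s seizure occurrence period (seconds; default 20 min).
#' @param sph_s seizure prediction horizon (seconds; default 30 min).
#' @param evaluated_hours hours of evaluated non-ictal recording, the FPR
#'   denominator.
#' @return list of class `event_eval`: `M`, `m`, `sensitivity`, `FPR`
#'   (false alarms per hour), `warning_times_s`, `n_false`, `P` (chance
#'   alarm probability at this FPR) and `p` (random-predictor p-value).
#' @export
score_events <- function(alarms, seizures, sop_s = 1200, sph_s = 1800,
                         evaluated_hours) {
  if (sop_s <= 0 || sph_s <= 0) stop("SOP and SPH must be positive")
  if (evaluated_hours < 0) stop("evaluated_hours must be >= 0")
  onsets <- sort(seizures$onset_s)
  M <- length(onsets)
  at <- sort(alarms$time_s)
  correct_for <- lapply(at, function(t)
    which(onsets >= t + sph_s & onsets < t + sph_s + sop_s))
  is_false <- vapply(correct_for, function(x) length(x) == 0, logical(1))
  warning_s <- rep(NA_real_, M)
  for (k in seq_along(at)) {
    for (s in correct_for[[k]]) {
      if (is.na(warning_s[s])) warning_s[s] <- onsets[s] - at[k]
    }
  }
  m <- sum(!is.na(warning_s))
  fpr <- if (evaluated_hours > 0) sum(is_false) / evaluated_hours else NA_real_
  P <- if (!is.na(fpr)) random_predictor_alarm_prob(fpr, sop_s) else NA_real_
  p <- if (!is.na(P) && M > 0) random_predictor_pvalue(P, M, m) else NA_real_
  structure(list(M = M, m = m,
                 sensitivity = if (M > 0) m / M else NA_real_,
                 FPR = fpr, n_false = sum(is_false),
                 warning_times_s = warning_s,
                 sop_s = sop_s, sph_s = sph_s,
                 evaluated_hours = evaluated_hours, P = P, p = p),
            class = "event_eval")
}

#' @export
print.event_eval <- function(x, ...) {
  cat(sprintf("<event_eval: %d/%d seizures predicted (%.1f%%), FPR %.3f/h, p=%.4g>\n",
              x$m, x$M, 100 * x$sensitivity, x$FPR, x$p))
  invisible(x)
}

#' Chance probability of an alarm falling in one occurrence period
#'
#' For a random (Poisson) predictor with false prediction rate `FPR`, the
#' probability that at least one alarm lands in a window of length SOP is
#' `P = 1 - exp(-FPR * SOP)`.
#'
#' @param fpr_per_h false alarms per hour (>= 0).
#' @param sop_s seizure occurrence period in seconds (> 0).
#' @return `P` in `[0, 1]`.
#' @export
random_predictor_alarm_prob <- function(fpr_per_h, sop_s) {
  if (fpr_per_h < 0) stop("FPR must be >= 0")
  if (sop_s <= 0) stop("SOP must be > 0")
  1 - exp(-fpr_per_h * sop_s / 3600)
}

#' Random-predictor significance
#'
#' Probability that an unskilled predictor with per-seizure success
#' probability `P` predicts at least `m` of `M` independent seizures: the
#' upper binomial tail. The method is declared significantly better than
#' chance when `p < 0.05`.
#'
#' @param P chance alarm probability from
#'   [random_predictor_alarm_prob()].
#' @param M total leading seizures; `m` the number predicted.
#' @param m number of predicted seizures, `0 <= m <= M`.
#' @return The p-value.
#' @export
random_predictor_pvalue <- function(P, M, m) {
  if (P < 0 || P > 1) stop("P must be in [0, 1]")
  if (m < 0 || m > M) stop("need 0 <= m <= M")
  if (m == 0) return(1)
  pbinom(m - 1, M, P, lower.tail = FALSE)
}

#' Fraction of samples classified preictal versus time after a seizure
#'
#' Bins per-sample predicted labels by their time since the preceding
#' seizure's offset and reports the preictal fraction per bin; bins with no
#' samples are omitted (missing, not zero). Used to quantify how long the
#' postictal state keeps resembling the preictal one to a binary
#' classifier.
#'
#' @param pred per-sample predicted labels.
#' @param t_since_offset_s per-sample seconds since the preceding ictal
#'   offset (>= 0).
#' @param bin_s bin width in seconds (default one hour).
#' @return data frame: `bin_start_s`, `n`, `frac_preictal`.
#' @export
postictal_drift_profile <- function(pred, t_since_offset_s, bin_s = 3600) {
  if (length(pred) != length(t_since_offset_s))
    stop("inputs differ in length")
  if (any(t_since_offset_s < 0)) stop("time offsets must be >= 0")
  bin <- floor(t_since_offset_s / bin_s)
  agg <- tapply(pred == "PREICTAL", bin, function(z) c(length(z), mean(z)))
  out <- data.frame(bin_start_s = as.numeric(names(agg)) * bin_s,
                    n = vapply(agg, `[`, numeric(1), 1),
                    frac_preictal = vapply(agg, `[`, numeric(1), 2))
  rownames(out) <- NULL
  out[order(out$bin_start_s), , drop = FALSE]
}
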