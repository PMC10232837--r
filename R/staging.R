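#' Stage-labeling policy
#'
#' Durations (seconds) that turn seizure annotations into a four-stage
#' labeling of the recorded timeline. Defaults follow the usual convention
#' for long-term scalp EEG: a seizure is *leading* (a prediction target) when
#' more than 60 min separate it from the previous seizure's end; the
#' preictal period is the hour before a leading seizure; the postictal
#' period is the hour after any seizure's end; interictal baseline must lie
#' at least 5 h after the previous seizure and 3 h before the next one.
#'
#' @param leading_gap_s minimum gap (previous offset to onset) for a seizure
#'   to count as leading.
#' @param preictal_len_s preictal duration before each leading seizure.
#' @param postictal_len_s postictal duration after each seizure.
#' @param interictal_pre_buffer_s required clearance after a seizure's offset
#'   before interictal time may start.
#' @param interictal_post_buffer_s required clearance before the next onset.
#' @return A list of class `staging_policy`.
#' @export
staging_policy <- function(leading_gap_s = 3600, preictal_len_s = 3600,
                           postictal_len_s = 3600,
                           interictal_pre_buffer_s = 5 * 3600,
                           interictal_post_buffer_s = 3 * 3600) {
  p <- list(leading_gap_s = leading_gap_s, preictal_len_s = preictal_len_s,
            postictal_len_s = postictal_len_s,
            interictal_pre_buffer_s = interictal_pre_buffer_s,
            interictal_post_buffer_s = interictal_post_buffer_s)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1 || v <= 0,
                 logical(1))))
    stop("all staging durations must be single positive numbers")
  if (preictal_len_s > interictal_post_buffer_s)
    stop("preictal_len_s must not exceed interictal_post_buffer_s ",
         "(preictal and interictal time could otherwise overlap)")
  structure(p, class = "staging_policy")
}

.check_events <- function(events) {
  if (nrow(events) == 0) return(invisible(events))
  if (any(events$offset_s <= events$onset_s))
    stop("seizure events must satisfy offset_s > onset_s")
  if (is.unsorted(events$onset_s, strictly = TRUE) && nrow(events) > 1)
    stop("seizure events must be sorted by onset")
  if (nrow(events) > 1 &&
      any(events$onset_s[-1] < events$offset_s[-nrow(events)]))
    stop("seizure events must be non-overlapping")
  invisible(events)
}

# Total recorded seconds inside [a, b).
.recorded_overlap <- function(spans, a, b) {
  if (is.null(spans)) return(b - a)   # treat the timeline as fully recorded
  sum(pmax(0, pmin(spans$end_s, b) - pmax(spans$start_s, a)))
}

#' Mark leading seizures
#'
#' A seizure is leading when its onset lies more than `leading_gap_s` after
#' the previous seizure's offset. The first seizure of a subject is leading
#' only when a full preictal window (`preictal_len_s`) before its onset is
#' recorded: a predictor cannot be evaluated on preictal time that was never
#' measured.
#'
#' @param events data frame with `onset_s`, `offset_s`, sorted,
#'   non-overlapping.
#' @param policy a [staging_policy()].
#' @param recorded_spans optional data frame (`start_s`, `end_s`) of recorded
#'   intervals; when `NULL` the timeline is assumed recorded from 0 onward.
#' @return `events` with a logical `leading` column.
#' @export
select_leading_seizures <- function(events, policy = staging_policy(),
                                    recorded_spans = NULL) {
  .check_events(events)
  n <- nrow(events)
  events$leading <- logical(n)
  if (n == 0) return(events)
  pre_rec <- .recorded_overlap(recorded_spans,
                               events$onset_s[1] - policy$preictal_len_s,
                               events$onset_s[1])
  events$leading[1] <- pre_rec >= policy$preictal_len_s
  if (n > 1)
    events$leading[-1] <-
      (events$onset_s[-1] - events$offset_s[-n]) > policy$leading_gap_s
  events
}

#' Label the recorded timeline with seizure stages
#'
#' Tiles every recorded second with exactly one stage. Candidate zones are
#' ictal `[onset, offset)`, preictal `[onset - preictal_len, onset)` for
#' leading seizures only, postictal `[offset, offset + postictal_len)` for
#' every seizure, and interictal for time at least
#' `interictal_pre_buffer_s` after the previous offset *and*
#' `interictal_post_buffer_s` before the next onset. Recorded time matching
#' none of these is an excluded buffer. Conflicts resolve by precedence
#' ICTAL > PREICTAL > POSTICTAL > EXCLUDED > INTERICTAL, so preictal data for
#' a predictable seizure is never sacrificed to the previous seizure's
#' postictal window, while interictal purity is preserved.
#'
#' @param recorded_spans data frame (`start_s`, `end_s`) of recorded
#'   half-open intervals, sorted, non-overlapping.
#' @param events seizure data frame (`onset_s`, `offset_s`); a `leading`
#'   column is computed with [select_leading_seizures()] if absent.
#' @param policy a [staging_policy()].
#' @return data frame (`stage`, `start_s`, `end_s`) tiling the recorded
#'   timeline, sorted, with adjacent equal-stage intervals merged within
#'   each recorded span.
#' @export
assign_stages <- function(recorded_spans, events, policy = staging_policy()) {
  spans <- recorded_spans[order(recorded_spans$start_s), , drop = FALSE]
  if (nrow(spans) > 1 && any(spans$start_s[-1] < spans$end_s[-nrow(spans)]))
    stop("recorded spans must be non-overlapping and sorted")
  .check_events(events)
  if (is.null(events$leading))
    events <- select_leading_seizures(events, policy, spans)

  ## candidate zones, one data frame per stage
  zone <- function(stage, s, e) {
    keep <- e > s
    data.frame(stage = rep(stage, sum(keep)), start_s = s[keep], end_s = e[keep])
  }
  ict <- zone("ICTAL", events$onset_s, events$offset_s)
  pre <- zone("PREICTAL",
              events$onset_s[events$leading] - policy$preictal_len_s,
              events$onset_s[events$leading])
  post <- zone("POSTICTAL", events$offset_s,
               events$offset_s + policy$postictal_len_s)
  ## interictal = complement of the union of forbidden buffers
  forb <- zone("FORBIDDEN",
               events$onset_s - policy$interictal_post_buffer_s,
               events$offset_s + policy$interictal_pre_buffer_s)

  cand <- rbind(ict, pre, post)
  cuts <- sort(unique(c(spans$start_s, spans$end_s,
                        cand$start_s, cand$end_s,
                        forb$start_s, forb$end_s)))
  covers <- function(z, m) {
    if (nrow(z) == 0) return(rep(FALSE, length(m)))
    vapply(m, function(t) any(z$start_s <= t & t < z$end_s), logical(1))
  }

  out <- list()
  for (i in seq_len(nrow(spans))) {
    b <- sort(unique(c(spans$start_s[i], spans$end_s[i],
                       cuts[cuts > spans$start_s[i] & cuts < spans$end_s[i]])))
    if (length(b) < 2) next
    mid <- (head(b, -1) + tail(b, -1)) / 2
    st <- rep("INTERICTAL", length(mid))
    st[covers(forb, mid)] <- "EXCLUDED"
    st[covers(post, mid)] <- "POSTICTAL"
    st[covers(pre, mid)] <- "PREICTAL"
    st[covers(ict, mid)] <- "ICTAL"
    ## merge adjacent equal stages
    r <- rle(st)
    e_idx <- cumsum(r$lengths)
    s_idx <- c(1L, head(e_idx, -1) + 1L)
    out[[i]] <- data.frame(stage = r$values,
                           start_s = b[s_idx], end_s = b[e_idx + 1L])
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(stage = character(), start_s = numeric(),
                         end_s = numeric())
  rownames(res) <- NULL
  res
}

#' Summarize staged time per stage
#' @param stages data frame from [assign_stages()].
#' @return named numeric vector of seconds per stage.
#' @export
stage_durations <- function(stages) {
  d <- tapply(stages$end_s - stages$start_s, stages$stage, sum)
  out <- setNames(numeric(length(STAGES)), STAGES)
  out[names(d)] <- d
  out
}
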