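#' Pipeline run configuration
#'
#' One auditable object holding every constant of the method: the task,
#' the analysis band, the window length, the staging policy, the model and
#' the evaluation parameters. A run's results are reproducible from this
#' object plus the input files.
#'
#' @param task 2 (preictal vs interictal) or 3 (+ postictal).
#' @param band analysis band name (default `"gamma"`).
#' @param window_s sample window length in seconds.
#' @param staging a [staging_policy()].
#' @param model a [model_config()]; its `n_classes` is forced to `task`.
#' @param sop_s,sph_s seizure occurrence period / prediction horizon.
#' @param alarm_window_min,alarm_frac alarm rule: fraction of preictal
#'   predictions that must be strictly exceeded in the trailing window.
#' @param refractory_s post-alarm dead time (default SPH + SOP).
#' @param mtpw_lengths segment lengths scanned for the MTPW curve.
#' @param segment_len_s segment length for headline segment metrics.
#' @param split `"first_k"` or `"loo_by_seizure"`.
#' @param k training seizures for the `first_k` split.
#' @param train_on training-set recipe for the 2-class `first_k` split:
#'   `"preictal+interictal"` (default) trains on the first seizures'
#'   preictal hours; `"postictal+interictal"` instead uses their postictal
#'   hours as the positive class -- the variant motivated by the
#'   observation that post- and pre-seizure EEG share gamma-band structure
#'   while the post-seizure baseline may drift from the pre-seizure one.
#' @param channels optional channel labels the classifier requires;
#'   records missing any of them are skipped with a warning (never
#'   zero-filled). `NULL` uses every channel of every record.
#' @param amp_max_uv,hf_frac EMG rejection thresholds
#'   (see [reject_emg_artifacts()]).
#' @param balance undersample interictal training data.
#' @param seed seed for balancing and any other pipeline-level randomness.
#' @return list of class `run_config`.
#' @export
run_config <- function(task = 2, band = "gamma", window_s = 5,
                       staging = staging_policy(),
                       model = model_config(n_classes = task),
                       sop_s = 1200, sph_s = 1800, alarm_window_min = 10,
                       alarm_frac = 0.70, refractory_s = sop_s + sph_s,
                       mtpw_lengths = seq(5, 150, by = 5),
                       segment_len_s = 120, split = c("first_k",
                                                      "loo_by_seizure"),
                       k = 2, train_on = c("preictal+interictal",
                                           "postictal+interictal"),
                       channels = NULL, amp_max_uv = 500, hf_frac = 0.85,
                       balance = TRUE, seed = 1) {
  split <- match.arg(split)
  train_on <- match.arg(train_on)
  if (!(task %in% c(2, 3))) stop("task must be 2 or 3")
  if (train_on == "postictal+interictal" && task != 2)
    stop("the postictal+interictal training recipe applies to the 2-class task")
  model$n_classes <- as.integer(task)
  structure(list(task = as.integer(task), band = band, window_s = window_s,
                 staging = staging, model = model, sop_s = sop_s,
                 sph_s = sph_s, alarm_window_min = alarm_window_min,
                 alarm_frac = alarm_frac, refractory_s = refractory_s,
                 mtpw_lengths = mtpw_lengths, segment_len_s = segment_len_s,
                 split = split, k = k, train_on = train_on,
                 channels = channels, amp_max_uv = amp_max_uv,
                 hf_frac = hf_frac, balance = balance,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file with keys matching [run_config()] arguments;
#'   `staging` and `model` may be nested maps.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$staging)) y$staging <- do.call(staging_policy, y$staging)
  if (!is.null(y$model)) {
    preset <- y$model$preset %||% "full"
    y$model$preset <- NULL
    y$model <- do.call(if (preset == "reduced") reduced_model_config
                       else model_config, y$model)
  }
  do.call(run_config, y)
}

# Ingest a subject directory: summary + EDFs -> records, events, spans.
.ingest_subject <- function(dir, summary_path = NULL) {
  if (is.null(summary_path)) {
    cand <- list.files(dir, pattern = "summary.*\\.txt$", full.names = TRUE)
    if (length(cand) != 1)
      stop("expected exactly one summary file in ", dir)
    summary_path <- cand
  }
  ann <- parse_seizure_summary(summary_path)
  ann$dir <- dir
  ann
}

# Filter + segment + artifact-reject every record of a subject for one band.
.subject_samples <- function(ann, stages, config) {
  keep_stages <- if (config$task == 3 ||
                     config$train_on == "postictal+interictal")
    CLASS_STAGES_3 else c("PREICTAL", "INTERICTAL")
  iv <- stages[stages$stage %in% keep_stages, , drop = FALSE]
  parts <- list(); rejected <- list()
  for (i in seq_len(nrow(ann$records))) {
    r <- ann$records[i, ]
    ## skip records that contain no usable stage time
    if (!any(iv$end_s > r$start_s & iv$start_s < r$end_s)) next
    rec <- tryCatch(
      read_edf(file.path(ann$dir, paste0(r$record_id, ".edf")),
               channel_selection = config$channels,
               t0 = r$start_s, record_id = r$record_id),
      error = function(e) {
        if (grepl("not present", conditionMessage(e))) {
          warning("skipping record ", r$record_id, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        } else stop(e)
      })
    if (is.null(rec)) next
    rec <- bandpass_filter(rec, config$band)
    ss <- segment_recording(rec, iv, config$window_s)
    if (n_samples(ss) == 0) next
    scr <- reject_emg_artifacts(ss, config$amp_max_uv, config$hf_frac)
    parts[[length(parts) + 1L]] <- scr$kept
    rejected[[length(rejected) + 1L]] <- scr$rejected
  }
  if (length(parts) == 0) stop("no usable samples in subject")
  list(samples = do.call(bind_samples, parts),
       rejected = do.call(rbind, rejected))
}

# Hours of evaluated non-ictal test recording: the FPR denominator
# (interictal only for the 2-class task, interictal + postictal for
# 3-class).
.evaluated_hours <- function(meta, window_s, task) {
  st <- if (task == 2) "INTERICTAL" else c("INTERICTAL", "POSTICTAL")
  sum(meta$stage %in% st) * window_s / 3600
}

#' Run the full prediction pipeline on one subject
#'
#' Ingests EDF records and seizure annotations, labels the timeline,
#' filters to the configured band, windows and screens the samples, trains
#' the LSTM on the configured split, and evaluates at segment level
#' (majority-vote fusion, MTPW scan) and event level (alarms under
#' SOP/SPH, FPR, warning times, random-predictor significance).
#'
#' @param subject either a directory containing EDF files and one summary
#'   text file, or the list returned by [generate_subject()].
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, results, alarm and
#'   rejection logs, and the run manifest are written there as JSON/CSV.
#' @return list of class `pipeline_result`; see the elements written under
#'   `segment`, `mtpw`, `event`, `counts`, `history`.
#' @export
run_pipeline <- function(subject, config = run_config(), out_dir = NULL) {
  dir <- if (is.list(subject)) subject$dir else subject
  ann <- .ingest_subject(dir)
  spans <- recorded_spans(ann$records)
  events <- select_leading_seizures(ann$events, config$staging, spans)
  stages <- assign_stages(spans, events, config$staging)

  if (config$task == 3) {
    post_s <- stage_durations(stages)[["POSTICTAL"]]
    if (post_s < config$alarm_window_min * 60)
      stop("insufficient postictal data for the 3-class task (",
           round(post_s), " s recorded)")
  }

  got <- .subject_samples(ann, stages, config)
  samples <- got$samples

  if (config$split == "first_k") {
    sp <- split_first_k_seizures(samples, events, config$k, config$staging)
    train <- sp$train; test <- sp$test
    if (config$train_on == "postictal+interictal") {
      ## the first seizures' postictal hours stand in as the positive class
      train <- subset_samples(train, train$meta$stage != "PREICTAL")
      if (!any(train$meta$stage == "POSTICTAL"))
        stop("insufficient postictal data for the postictal+interictal recipe")
      train$meta$stage[train$meta$stage == "POSTICTAL"] <- "PREICTAL"
      test <- subset_samples(test, test$meta$stage != "POSTICTAL")
    }
    if (config$balance) train <- balance_classes(train, config$seed)
    model <- train_lstm(train, config$model)
    pred <- predict_samples(model, test)
    test_meta <- cbind(test$meta, label = pred$label)
    test_seizures <- events[events$leading &
                              events$onset_s >= sp$boundary_s, , drop = FALSE]
    history <- model$history
  } else {
    cv <- loocv_by_seizure(samples, events, config$model, config$staging)
    test_meta <- do.call(rbind, cv$rounds)
    test_seizures <- cv$seizures
    history <- NULL
  }
  test_meta <- test_meta[order(test_meta$start_s), , drop = FALSE]

  seg5 <- segment_metrics(test_meta$stage, test_meta$label, config$task)
  mt <- mtpw_scan(test_meta$stage, test_meta$label, config$mtpw_lengths,
                  config$window_s, config$task)
  segL <- {
    f <- .fuse_stream(test_meta$stage, test_meta$label,
                      as.integer(config$segment_len_s / config$window_s),
                      config$task)
    segment_metrics(f$true, f$pred, config$task)
  }

  alarms <- raise_alarms(test_meta$label, test_meta$start_s,
                         config$window_s, config$alarm_window_min,
                         config$alarm_frac, config$refractory_s)
  event <- score_events(alarms, test_seizures, config$sop_s, config$sph_s,
                        .evaluated_hours(test_meta, config$window_s,
                                         config$task))

  drift <- NULL
  post <- test_meta$stage == "POSTICTAL"
  if (any(post)) {
    off <- vapply(test_meta$start_s[post], function(t) {
      prev <- events$offset_s[events$offset_s <= t]
      t - max(prev)
    }, numeric(1))
    drift <- postictal_drift_profile(test_meta$label[post], off)
  }

  res <- structure(list(
    config = config, stages = stages, events = events,
    counts = list(samples_per_stage = table(samples$meta$stage),
                  n_rejected = nrow(got$rejected),
                  n_train = if (config$split == "first_k") n_samples(train)
                            else NA_integer_,
                  n_test = nrow(test_meta)),
    history = history, predictions = test_meta,
    segment = list(sample_level = seg5, fused = segL,
                   segment_len_s = config$segment_len_s),
    mtpw = mt, alarms = alarms, event = event,
    postictal_drift = drift, rejected = got$rejected),
    class = "pipeline_result")
  if (!is.null(out_dir)) .write_results(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (", x$config$task, "-class, band ", x$config$band,
      ")\n", sep = "")
  s <- x$segment$fused
  cat(sprintf("  segment (%ds): sensitivity %.4f, specificity %.4f (n=%d)\n",
              x$config$segment_len_s, s$sensitivity, s$specificity, s$n))
  print(x$event)
  invisible(x)
}

.write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jj <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            dataframe = "columns",
                                            force = TRUE)
  seg <- res$segment$fused
  jj(list(task = res$config$task, band = res$config$band,
          segment_len_s = res$config$segment_len_s,
          sensitivity = seg$sensitivity, specificity = seg$specificity,
          per_class_TPR = as.list(seg$per_class_TPR),
          event = res$event[c("M", "m", "sensitivity", "FPR", "P", "p",
                              "evaluated_hours")],
          mean_warning_time_s = mean(res$event$warning_times_s, na.rm = TRUE),
          counts = lapply(res$counts, function(z)
            if (inherits(z, "table")) as.list(z) else z)),
     "results.json")
  write.csv(res$mtpw$curve, file.path(out_dir, "mtpw_curve.csv"),
            row.names = FALSE)
  write.csv(res$alarms, file.path(out_dir, "alarms.csv"), row.names = FALSE)
  write.csv(res$predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  if (!is.null(res$history))
    write.csv(res$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)
  if (!is.null(res$rejected) && nrow(res$rejected))
    write.csv(res$rejected, file.path(out_dir, "rejected.csv"),
              row.names = FALSE)
  manifest <- res$config
  class(manifest) <- NULL
  manifest$staging <- unclass(manifest$staging)
  manifest$model <- unclass(manifest$model)
  jj(manifest, "manifest.json")
  invisible(out_dir)
}

#' Per-band comparison of sample-level metrics
#'
#' Runs the 2-class training and sample-level evaluation once per standard
#' EEG band with shared seeds and returns a five-row comparison table; on
#' band-limited contrasts this reproduces the band selection experiment
#' (the band carrying the contrast wins).
#'
#' @param subject as in [run_pipeline()].
#' @param config a [run_config()]; its `band` is ignored.
#' @return data frame: `band`, `sensitivity`, `specificity`, `n_test`.
#' @export
compare_bands <- function(subject, config = run_config()) {
  dir <- if (is.list(subject)) subject$dir else subject
  ann <- .ingest_subject(dir)
  spans <- recorded_spans(ann$records)
  events <- select_leading_seizures(ann$events, config$staging, spans)
  stages <- assign_stages(spans, events, config$staging)
  rows <- lapply(eeg_bands(config$model$fs)$name, function(bn) {
    cfg <- config
    cfg$band <- bn
    got <- .subject_samples(ann, stages, cfg)
    sp <- split_first_k_seizures(got$samples, events, cfg$k, cfg$staging)
    train <- if (cfg$balance) balance_classes(sp$train, cfg$seed)
             else sp$train
    model <- train_lstm(train, cfg$model)
    pred <- predict_samples(model, sp$test)
    m <- segment_metrics(sp$test$meta$stage, pred$label, cfg$task)
    data.frame(band = bn, sensitivity = m$sensitivity,
               specificity = m$specificity, n_test = m$n)
  })
  do.call(rbind, rows)
}
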