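#' LSTM classifier configuration
#'
#' The network maps one filtered window -- `input_len` time steps of
#' `n_channels` features -- through an LSTM layer, a dropout layer on its
#' final hidden state, a fully connected layer of width `n_classes` and a
#' softmax. Defaults mirror the reference architecture: 5-s windows at
#' 256 Hz (1280 x 23 input), 128 memory units, dropout 0.5.
#'
#' Optimizer settings (Adam, learning rate 1e-3, batch 64, at most 30
#' epochs, early stopping with patience 5 on a 10% validation split) are
#' exposed here. `time_stride` subsamples the window's time axis before the
#' LSTM (stride 1 = the full sequence); per-window band power, the quantity
#' the classifier exploits, is invariant to this decimation, which is what
#' makes a fast reduced profile possible.
#'
#' @param fs,window_s window geometry; `input_len = fs * window_s /
#'   time_stride`.
#' @param n_channels EEG channels per window.
#' @param lstm_units LSTM memory units.
#' @param dropout dropout probability in `[0, 1)`.
#' @param n_classes 2 (preictal vs interictal) or 3 (+ postictal).
#' @param lr,batch_size,max_epochs,patience Adam/early-stop settings.
#' @param val_frac fraction of training data held out for early stopping.
#' @param time_stride temporal subsampling factor of the input window.
#' @param normalize apply per-channel z-scoring (statistics from the
#'   training split only).
#' @param seed RNG seed for initialization, shuffling, dropout and the
#'   validation split.
#' @return list of class `model_config`.
#' @export
model_config <- function(fs = 256, window_s = 5, n_channels = 23,
                         lstm_units = 128, dropout = 0.5, n_classes = 2,
                         lr = 1e-3, batch_size = 64, max_epochs = 30,
                         patience = 5, val_frac = 0.1, time_stride = 1,
                         normalize = TRUE, seed = 1) {
  if (!(n_classes %in% c(2, 3))) stop("n_classes must be 2 or 3")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (lstm_units < 1) stop("lstm_units must be >= 1")
  if ((fs * window_s) %% time_stride != 0)
    stop("time_stride must divide fs * window_s")
  structure(list(fs = fs, window_s = window_s, n_channels = n_channels,
                 input_len = as.integer(fs * window_s / time_stride),
                 lstm_units = as.integer(lstm_units), dropout = dropout,
                 n_classes = as.integer(n_classes), lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_frac = val_frac,
                 time_stride = as.integer(time_stride),
                 normalize = normalize, seed = as.integer(seed)),
            class = "model_config")
}

#' Reduced profile for CPU-scale runs
#'
#' Same architecture family at a size that trains in seconds to minutes on
#' one core: 32 memory units, temporal stride 8 (160 time steps per 5-s
#' window at 256 Hz) and at most 10 epochs.
#'
#' @param ... overrides passed to [model_config()].
#' @export
reduced_model_config <- function(...) {
  args <- list(...)
  defaults <- list(lstm_units = 32, time_stride = 8, max_epochs = 10,
                   patience = 3)
  do.call(model_config, utils::modifyList(defaults, args))
}

.class_levels <- function(n_classes)
  if (n_classes == 2) CLASS_STAGES_2 else CLASS_STAGES_3

#' Build an untrained LSTM model
#'
#' Instantiates the layer stack (input, LSTM, dropout, fully connected,
#' softmax) with Glorot-uniform weights from the config's seed.
#'
#' @param config a [model_config()].
#' @return list of class `lstm_model` with `params` and `config`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  params <- .lstm_init(config$n_channels, config$lstm_units,
                       config$n_classes, config$seed)
  structure(list(params = params, config = config,
                 classes = .class_levels(config$n_classes)),
            class = "lstm_model")
}

# Strided model-input array from a sample set.
.model_input <- function(samples, config) {
  if (dim(samples$x)[2] != config$n_channels)
    stop("sample channel count (", dim(samples$x)[2],
         ") does not match the model (", config$n_channels, ")")
  stride <- config$time_stride
  x <- samples$x[seq(1, dim(samples$x)[1], by = stride), , , drop = FALSE]
  if (dim(x)[1] != config$input_len)
    stop("sample window length does not match the model input length")
  x
}

.encode_labels <- function(stages, classes) {
  y <- match(stages, classes) - 1L
  if (anyNA(y))
    stop("sample stages ", paste(unique(stages[is.na(y)]), collapse = ", "),
         " not covered by the model's classes (", paste(classes, collapse = ", "), ")")
  y
}

#' Train the LSTM on labeled samples
#'
#' Fits per-channel normalization on the training split, holds out
#' `val_frac` of the samples (seeded) for early stopping, and trains with
#' Adam under gradient clipping. Deterministic given the config seed.
#'
#' @param samples a [sample_set()] with at least two classes present.
#' @param config a [model_config()]; `n_channels` defaults to the data.
#' @return list of class `trained_lstm`: `params`, `config`, `classes`,
#'   `mu`/`sd` normalization vectors, `history` (per-epoch loss/accuracy)
#'   and `best_epoch`.
#' @export
train_lstm <- function(samples, config = model_config()) {
  classes <- .class_levels(config$n_classes)
  y <- .encode_labels(samples$meta$stage, classes)
  if (length(unique(y)) < 2)
    stop("training requires at least two classes; got only ",
         classes[unique(y) + 1L])
  x <- .model_input(samples, config)
  n <- dim(x)[3]

  idx <- with_seed(config$seed, sample.int(n))
  n_val <- floor(config$val_frac * n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  tr_idx <- idx[setdiff(seq_len(n), seq_len(n_val))]
  if (config$normalize) {
    xt <- x[, , tr_idx, drop = FALSE]
    mu <- apply(xt, 2, mean)
    sdv <- pmax(apply(xt, 2, sd), .Machine$double.eps)
  } else {
    mu <- rep(0, dim(x)[2]); sdv <- rep(1, dim(x)[2])
  }

  init <- .lstm_init(dim(x)[2], config$lstm_units, config$n_classes,
                     config$seed)
  fit <- .lstm_fit(x, y, tr_idx - 1L, val_idx - 1L, init, mu, sdv,
                   lr = config$lr, dropout = config$dropout,
                   batch = config$batch_size, max_epochs = config$max_epochs,
                   patience = config$patience, seed = config$seed)
  structure(list(params = fit$params, config = config, classes = classes,
                 mu = mu, sd = sdv, history = fit$history,
                 best_epoch = fit$best_epoch),
            class = "trained_lstm")
}

#' @export
print.trained_lstm <- function(x, ...) {
  h <- x$history
  cat(sprintf("<trained_lstm: %d units, %d classes, %d epochs (best %d), val acc %.3f>\n",
              x$config$lstm_units, x$config$n_classes, nrow(h), x$best_epoch,
              h$val_acc[x$best_epoch]))
  invisible(x)
}

#' Per-sample class probabilities and labels
#'
#' Applies the trained network; argmax ties resolve to INTERICTAL (the
#' non-alarm class, listed first).
#'
#' @param model a `trained_lstm`.
#' @param samples a [sample_set()].
#' @return list with `prob` (n x classes matrix), `label` (character) and
#'   the sample `meta`.
#' @export
predict_samples <- function(model, samples) {
  stopifnot(inherits(model, "trained_lstm"))
  if (n_samples(samples) == 0) {
    return(list(prob = matrix(numeric(0), 0, length(model$classes),
                              dimnames = list(NULL, model$classes)),
                label = character(0), meta = samples$meta))
  }
  x <- .model_input(samples, model$config)
  prob <- .lstm_prob(x, model$params, model$mu, model$sd)
  colnames(prob) <- model$classes
  label <- model$classes[max.col(prob, ties.method = "first")]
  list(prob = prob, label = label, meta = samples$meta)
}

#' Chronological split on the first k leading seizures
#'
#' Training data are all samples generated by the first `k` leading seizures
#' (their preictal/postictal windows) plus interictal samples occurring
#' before the (k+1)-th leading seizure's preictal window; everything later
#' is test. This mimics clinical deployment: a predictor is fitted on a
#' patient's first seizures and evaluated on the rest.
#'
#' @param samples a [sample_set()].
#' @param events seizure data frame with a `leading` column (see
#'   [select_leading_seizures()]).
#' @param k number of leading seizures in the training part.
#' @param policy the [staging_policy()] (for the preictal length).
#' @return list with `train`, `test` (disjoint sample sets) and
#'   `boundary_s`, the timeline second separating them.
#' @export
split_first_k_seizures <- function(samples, events, k = 2,
                                   policy = staging_policy()) {
  lead <- events[events$leading, , drop = FALSE]
  if (nrow(lead) < k + 1)
    stop("need at least k + 1 = ", k + 1, " leading seizures, found ",
         nrow(lead))
  boundary <- lead$onset_s[k + 1] - policy$preictal_len_s
  in_train <- samples$meta$start_s < boundary
  list(train = subset_samples(samples, in_train),
       test = subset_samples(samples, !in_train),
       boundary_s = boundary)
}

#' Stratified k-fold cross-validation at sample level
#'
#' Folds are stratified by stage and seeded. Inside every fold the training
#' split is independently class-balanced and normalized, so no statistic
#' leaks from held-out samples.
#'
#' @param samples a [sample_set()].
#' @param k number of folds.
#' @param config a [model_config()].
#' @param balance balance classes inside each training split.
#' @return list with `folds` (per-fold [segment_metrics()] results on the
#'   held-out samples) and `predictions` (meta + `fold`, `label`).
#' @export
kfold_cv <- function(samples, k = 10, config = model_config(),
                     balance = TRUE) {
  st <- samples$meta$stage
  if (any(table(st) < k))
    stop("need at least k = ", k, " samples in every class")
  fold <- integer(length(st))
  with_seed(config$seed, {
    for (cls in unique(st)) {
      i <- which(st == cls)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  preds <- character(length(st))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- subset_samples(samples, fold != f)
    if (balance) tr <- balance_classes(tr, seed = config$seed + f)
    fit <- train_lstm(tr, config)
    p <- predict_samples(fit, subset_samples(samples, fold == f))
    preds[fold == f] <- p$label
    folds[[f]] <- segment_metrics(st[fold == f], p$label,
                                  n_classes = config$n_classes)
  }
  list(folds = folds,
       predictions = cbind(samples$meta, fold = fold, label = preds))
}

# Attach each sample to its nearest leading seizure (preictal/postictal by
# containment, interictal by onset distance).
.assign_to_seizure <- function(meta, lead, policy) {
  n <- nrow(meta)
  sz <- integer(n)
  for (j in seq_len(n)) {
    t <- meta$start_s[j]
    hit <- switch(meta$stage[j],
      PREICTAL = which(lead$onset_s - policy$preictal_len_s <= t &
                         t < lead$onset_s),
      POSTICTAL = which(lead$offset_s <= t &
                          t < lead$offset_s + policy$postictal_len_s),
      integer(0))
    sz[j] <- if (length(hit)) hit[1] else which.min(abs(lead$onset_s - t))
  }
  sz
}

#' Leave-one-seizure-out cross-validation
#'
#' One round per leading seizure: the model is trained on the samples
#' attached to the other seizures (class-balanced) and predicts the held-out
#' seizure's preictal hour plus its share of the interictal (and postictal)
#' data. The subject's result is the average over rounds.
#'
#' @param samples a [sample_set()].
#' @param events seizure data frame with `leading` column.
#' @param config a [model_config()].
#' @param policy the [staging_policy()].
#' @return list with `rounds` (per-round prediction frames: meta + `label`)
#'   and `seizures` (the leading events).
#' @export
loocv_by_seizure <- function(samples, events, config = model_config(),
                             policy = staging_policy()) {
  lead <- events[events$leading, , drop = FALSE]
  if (nrow(lead) < 2) stop("need at least 2 leading seizures")
  sz <- .assign_to_seizure(samples$meta, lead, policy)
  rounds <- vector("list", nrow(lead))
  for (i in seq_len(nrow(lead))) {
    tr <- balance_classes(subset_samples(samples, sz != i),
                          seed = config$seed + i)
    fit <- train_lstm(tr, config)
    te <- subset_samples(samples, sz == i)
    p <- predict_samples(fit, te)
    rounds[[i]] <- cbind(te$meta, label = p$label, round = i)
  }
  list(rounds = rounds, seizures = lead)
}
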