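test_that("model outputs are probability vectors of the configured width", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  ss <- make_samples(c("PREICTAL", "INTERICTAL"), n_time = 80, n_ch = 3,
                     fs = 16)
  fit <- structure(list(params = m$params, config = cfg, classes = m$classes,
                        mu = rep(0, 3), sd = rep(1, 3)),
                   class = "trained_lstm")
  p <- predict_samples(fit, ss)
  expect_equal(ncol(p$prob), 2)
  expect_equal(rowSums(p$prob), rep(1, 2), tolerance = 1e-6)
  # zero input still yields a valid probability vector
  ss$x[] <- 0
  p0 <- predict_samples(fit, ss)
  expect_equal(rowSums(p0$prob), rep(1, 2), tolerance = 1e-6)

  cfg3 <- tiny_model_config(n_classes = 3)
  m3 <- build_model(cfg3)
  expect_equal(ncol(m3$params$Wy), 3)
  expect_error(model_config(dropout = 1.0), "dropout")
  expect_error(model_config(n_classes = 4), "n_classes")
})

test_that("a linearly separable contrast is learned almost perfectly", {
  # classes differ by a +-5 sd mean offset: a perfect classifier exists
  n <- 200
  stages <- rep(c("PREICTAL", "INTERICTAL"), each = n)
  ss <- make_samples(stages, n_time = 80, n_ch = 3, fs = 16, seed = 13)
  ss$x[, , stages == "PREICTAL"] <- ss$x[, , stages == "PREICTAL"] + 5
  fit <- train_lstm(ss, tiny_model_config())
  expect_gte(max(fit$history$train_acc), 0.95)
  p <- predict_samples(fit, ss)
  expect_gte(mean(p$label == stages), 0.95)
})

test_that("indistinguishable classes stay at chance accuracy", {
  accs <- vapply(1:5, function(s) {
    ss <- make_samples(rep(c("PREICTAL", "INTERICTAL"), each = 60),
                       n_time = 80, n_ch = 3, fs = 16, seed = 100 + s)
    fit <- train_lstm(ss, tiny_model_config(seed = s, max_epochs = 3))
    p <- predict_samples(fit, ss)
    mean(p$label == ss$meta$stage)
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("degenerate training inputs error", {
  ss <- make_samples(rep("PREICTAL", 10), n_time = 80, n_ch = 3, fs = 16)
  expect_error(train_lstm(ss, tiny_model_config()), "two classes")
  ss2 <- make_samples(c("PREICTAL", "INTERICTAL"), n_time = 80, n_ch = 2,
                      fs = 16)
  expect_error(train_lstm(ss2, tiny_model_config()), "channel count")
})

test_that("training is deterministic given the seed", {
  ss <- make_samples(rep(c("PREICTAL", "INTERICTAL"), each = 40),
                     n_time = 80, n_ch = 3, fs = 16, seed = 2)
  f1 <- train_lstm(ss, tiny_model_config(max_epochs = 2))
  f2 <- train_lstm(ss, tiny_model_config(max_epochs = 2))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("prediction handles empty input and preserves order", {
  ss <- make_samples(rep(c("PREICTAL", "INTERICTAL"), each = 30),
                     n_time = 80, n_ch = 3, fs = 16, seed = 3)
  fit <- train_lstm(ss, tiny_model_config(max_epochs = 1))
  empty <- subset_samples(ss, integer(0))
  p <- predict_samples(fit, empty)
  expect_equal(length(p$label), 0)
  expect_equal(nrow(p$prob), 0)
})

test_that("first-k split keeps later seizures' samples out of training", {
  ev <- data.frame(onset_s = c(7200, 21600, 36000, 50400),
                   offset_s = c(7230, 21630, 36030, 50430),
                   leading = TRUE)
  starts <- c(3600, 18000, 32400, 46800,       # preictal windows (1 h before)
              100, 14000, 28000, 43000)        # interictal-ish times
  stages <- c(rep("PREICTAL", 4), rep("INTERICTAL", 4))
  ss <- make_samples(stages, n_time = 20, n_ch = 2, fs = 4, start_s = starts)
  sp <- split_first_k_seizures(ss, ev, k = 2)
  # test preictal samples come only from seizures 3-4
  test_pre <- sp$test$meta$start_s[sp$test$meta$stage == "PREICTAL"]
  expect_setequal(test_pre, c(32400, 46800))
  # disjointness on (record_id, start_s)
  key <- function(m) paste(m$record_id, m$start_s)
  expect_length(intersect(key(sp$train$meta), key(sp$test$meta)), 0)
  # k equal to the number of leading seizures leaves no test seizure
  expect_error(split_first_k_seizures(ss, ev, k = 4), "leading seizures")
})

test_that("stratified k-fold bookkeeping tests every sample exactly once", {
  stages <- rep(c("PREICTAL", "INTERICTAL"), each = 50)
  ss <- make_samples(stages, n_time = 40, n_ch = 2, fs = 8, seed = 4)
  ss$x[, , stages == "PREICTAL"] <- ss$x[, , stages == "PREICTAL"] + 5
  cv <- kfold_cv(ss, k = 10,
                 tiny_model_config(n_channels = 2, window_s = 5, fs = 8,
                                   max_epochs = 3, batch_size = 16))
  expect_length(cv$folds, 10)
  expect_equal(as.numeric(table(cv$predictions$fold)), rep(10, 10))
  expect_true(all(cv$predictions$label != ""))
  # separable contrast: high mean fold accuracy
  acc <- mean(cv$predictions$label == stages)
  expect_gte(acc, 0.9)
  expect_error(kfold_cv(subset_samples(ss, c(1:6, 51:56)), k = 10,
                        tiny_model_config()), "every class")
})

test_that("leave-one-seizure-out predicts each held-out preictal hour once", {
  ev <- data.frame(onset_s = c(7200, 21600, 36000),
                   offset_s = c(7230, 21630, 36030), leading = TRUE)
  pre_starts <- as.vector(vapply(ev$onset_s, function(o)
    seq(o - 600, o - 5, by = 5)[1:20], numeric(20)))
  int_starts <- c(seq(0, 95, by = 5), seq(14000, 14095, by = 5),
                  seq(28000, 28095, by = 5))
  stages <- c(rep("PREICTAL", 60), rep("INTERICTAL", 60))
  ss <- make_samples(stages, n_time = 20, n_ch = 2, fs = 4,
                     start_s = c(pre_starts, int_starts))
  # interictal blocks attach unevenly to seizures, so some rounds train
  # with fewer interictal than preictal samples (warned, all kept)
  cv <- suppressWarnings(
    loocv_by_seizure(ss, ev,
                     tiny_model_config(n_channels = 2, fs = 4,
                                       max_epochs = 1, batch_size = 16)))
  expect_length(cv$rounds, 3)                  # one round per leading seizure
  all_pre <- do.call(rbind, cv$rounds)
  all_pre <- all_pre[all_pre$stage == "PREICTAL", ]
  expect_equal(nrow(all_pre), 60)              # each preictal sample once
  expect_equal(anyDuplicated(all_pre$start_s), 0)
  for (i in 1:3) {
    rp <- cv$rounds[[i]]
    pre_i <- rp$start_s[rp$stage == "PREICTAL"]
    expect_true(all(pre_i >= ev$onset_s[i] - 3600 & pre_i < ev$onset_s[i]))
  }
  expect_error(loocv_by_seizure(subset_samples(ss, 1:20), ev[1, ],
                                tiny_model_config()), "2 leading")
})

test_that("normalization statistics never leak from held-out samples", {
  stages <- rep(c("PREICTAL", "INTERICTAL"), each = 30)
  ss <- make_samples(stages, n_time = 40, n_ch = 2, fs = 8, seed = 6)
  # make held-out data wildly offset: if its statistics leaked into the
  # normalizer, the training-set mean under the fit would shift
  fit <- train_lstm(ss, tiny_model_config(n_channels = 2, fs = 8,
                                          window_s = 5, max_epochs = 1))
  ss_shift <- ss
  ss_shift$x <- ss$x + 100
  fit2 <- train_lstm(ss, tiny_model_config(n_channels = 2, fs = 8,
                                           window_s = 5, max_epochs = 1))
  expect_identical(fit$mu, fit2$mu)   # mu computed from training split only
  p1 <- predict_samples(fit, ss)
  p2 <- predict_samples(fit, ss_shift)
  expect_false(identical(p1$prob, p2$prob))  # stats applied, not refitted
})
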