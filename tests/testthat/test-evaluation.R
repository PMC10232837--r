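test_that("segment fusion follows the strict over-half / over-third rules", {
  seg <- c(rep("PREICTAL", 13), rep("INTERICTAL", 11))
  expect_equal(classify_segment(seg, 2), "PREICTAL")        # 13 > 12
  seg12 <- c(rep("PREICTAL", 12), rep("INTERICTAL", 12))
  expect_equal(classify_segment(seg12, 2), "INTERICTAL")    # exactly half
  seg3 <- c(rep("PREICTAL", 9), rep("POSTICTAL", 10), rep("INTERICTAL", 5))
  expect_equal(classify_segment(seg3, 3), "PREICTAL")       # 9 > 8 = 24/3
  seg8 <- c(rep("PREICTAL", 8), rep("POSTICTAL", 10), rep("INTERICTAL", 6))
  expect_equal(classify_segment(seg8, 3), "POSTICTAL")      # exactly third
  expect_error(classify_segment(character(0)), "empty")
})

test_that("segment fusion equals exhaustive enumeration for all n <= 12", {
  for (n in 1:12) {
    for (npre in 0:n) {
      rest <- n - npre
      for (npost in 0:rest) {
        labels <- c(rep("PREICTAL", npre), rep("POSTICTAL", npost),
                    rep("INTERICTAL", rest - npost))
        expect_identical(classify_segment(labels, 3), oracle_classify(labels, 3))
        labels2 <- c(rep("PREICTAL", npre), rep("INTERICTAL", rest))
        expect_identical(classify_segment(labels2, 2),
                         oracle_classify(labels2, 2))
      }
    }
  }
})

test_that("segment metrics implement the confusion-count definitions", {
  true <- c(rep("PREICTAL", 10), rep("INTERICTAL", 10))
  pred <- c(rep("PREICTAL", 9), "INTERICTAL",
            rep("INTERICTAL", 8), rep("PREICTAL", 2))
  m <- segment_metrics(true, pred)
  expect_equal(c(m$TP, m$FN, m$TN, m$FP), c(9, 1, 8, 2))
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  all_right <- segment_metrics(true, true)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  expect_error(segment_metrics(true, pred[-1]), "length")
  expect_error(segment_metrics(c(true, "WEIRD"), c(pred, "WEIRD")), "unknown")
})

test_that("confusion counts match a brute-force recount on random labels", {
  lev3 <- c("INTERICTAL", "PREICTAL", "POSTICTAL")
  preictal:::with_seed(31, {
    true <- sample(lev3, 500, replace = TRUE)
    pred <- sample(lev3, 500, replace = TRUE)
  })
  m <- segment_metrics(true, pred, n_classes = 3)
  expect_equal(m$TP, sum(true == "PREICTAL" & pred == "PREICTAL"))
  expect_equal(m$FP, sum(true != "PREICTAL" & pred == "PREICTAL"))
  expect_equal(m$TN, sum(true != "PREICTAL" & pred != "PREICTAL"))
  expect_equal(m$FN, sum(true == "PREICTAL" & pred != "PREICTAL"))
  expect_equal(m$TP + m$FP + m$TN + m$FN, m$n)
  for (cl in lev3)
    expect_equal(m$per_class_TPR[[cl]],
                 mean(pred[true == cl] == cl))
})

test_that("the MTPW curve matches the binomial closed form", {
  # i.i.d. per-sample accuracy 0.8, pure preictal truth: fused sensitivity
  # at L = 120 s (24 samples) is the Bin(24, 0.8) upper tail at 13
  n_seg <- 2000
  truth <- rep("PREICTAL", n_seg * 24)
  pred <- preictal:::with_seed(17,
    ifelse(rbinom(length(truth), 1, 0.8) == 1, "PREICTAL", "INTERICTAL"))
  mt <- mtpw_scan(truth, pred, window_lengths = c(60, 120, 150))
  sens120 <- mt$curve$sensitivity[mt$curve$length_s == 120]
  expected <- pbinom(12, 24, 0.8, lower.tail = FALSE)
  mc_se <- sqrt(expected * (1 - expected) / n_seg)
  expect_lt(abs(sens120 - expected), 3 * mc_se)
})

test_that("perfect predictions give a flat curve at 1 and minimal MTPW", {
  truth <- rep(c("PREICTAL", "INTERICTAL"), each = 600)
  mt <- mtpw_scan(truth, truth)
  expect_true(all(mt$curve$sensitivity == 1))
  expect_true(all(mt$curve$specificity == 1))
  expect_equal(mt$mtpw_s, 5)
  expect_error(mtpw_scan(truth, truth, window_lengths = 7), "multiples")
})

test_that("alarms require strictly more than the threshold fraction", {
  times <- seq(0, by = 5, length.out = 120)
  mk <- function(npre) c(rep("PREICTAL", npre), rep("INTERICTAL", 120 - npre))
  a85 <- raise_alarms(mk(85), times)      # 85/120 = 70.8% > 70%
  expect_equal(nrow(a85), 1)
  expect_equal(a85$time_s, times[120] + 5)
  a84 <- raise_alarms(mk(84), times)      # exactly 70%: no alarm
  expect_equal(nrow(a84), 0)
  expect_warning(raise_alarms(mk(10)[1:50], times[1:50]), "shorter")
})

test_that("the refractory period deduplicates alarms", {
  # two supra-threshold epochs 20 min apart within a 50-min refractory
  pred <- c(rep("PREICTAL", 120), rep("INTERICTAL", 120),
            rep("PREICTAL", 120))
  times <- seq(0, by = 5, length.out = length(pred))
  a <- raise_alarms(pred, times, refractory_s = 3000)
  expect_equal(nrow(a), 1)
  # with a short refractory both epochs alarm
  a2 <- raise_alarms(pred, times, refractory_s = 600)
  expect_gte(nrow(a2), 2)
  # gaps reset the window: preictal run split by a recording gap
  pred3 <- rep("PREICTAL", 150)
  times3 <- c(seq(0, by = 5, length.out = 100),
              seq(10000, by = 5, length.out = 50))
  expect_equal(nrow(raise_alarms(pred3, times3)), 0)
})

test_that("SOP/SPH scoring matches the interval definition", {
  # alarm at t=0, onset 40 min later: onset in [1800, 3000) -> correct
  al <- data.frame(time_s = 0)
  sz <- data.frame(onset_s = 2400)
  r <- score_events(al, sz, sop_s = 1200, sph_s = 1800, evaluated_hours = 1)
  expect_equal(r$m, 1)
  expect_equal(r$warning_times_s, 2400)
  expect_equal(r$n_false, 0)
  # onset during the SPH: false alarm and unpredicted seizure
  r2 <- score_events(al, data.frame(onset_s = 900), 1200, 1800, 1)
  expect_equal(r2$m, 0)
  expect_equal(r2$n_false, 1)
  expect_equal(r2$FPR, 1)
  expect_error(score_events(al, sz, sop_s = -1, sph_s = 1800, 1), "positive")
})

test_that("event scoring matches a brute-force pairing oracle", {
  oracle_score <- function(at, onsets, sop, sph) {
    correct <- outer(at, onsets, function(t, o) o >= t + sph & o < t + sph + sop)
    list(m = sum(apply(correct, 2, any)),
         n_false = sum(!apply(correct, 1, any)),
         warning = vapply(seq_along(onsets), function(s) {
           k <- which(correct[, s])
           if (length(k)) onsets[s] - at[min(k)] else NA_real_
         }, numeric(1)))
  }
  for (seed in 1:20) {
    preictal:::with_seed(seed, {
      at <- sort(runif(sample(1:5, 1), 0, 20000))
      on <- sort(runif(sample(1:3, 1), 0, 25000))
    })
    r <- score_events(data.frame(time_s = at), data.frame(onset_s = on),
                      1200, 1800, evaluated_hours = 10)
    o <- oracle_score(at, on, 1200, 1800)
    expect_equal(r$m, o$m)
    expect_equal(r$n_false, o$n_false)
    expect_equal(r$warning_times_s, o$warning)
    expect_equal(r$n_false + (length(at) - o$n_false), length(at))
    # correct alarms have warning times inside [SPH, SPH+SOP)
    wt <- r$warning_times_s[!is.na(r$warning_times_s)]
    expect_true(all(wt >= 1800 & wt < 3000))
  }
})

test_that("the chance alarm probability follows 1 - exp(-FPR * SOP)", {
  expect_equal(random_predictor_alarm_prob(0, 1200), 0)
  expect_gt(random_predictor_alarm_prob(1e6, 1200), 1 - 1e-12)
  # FPR 0.29/h, SOP 20 min: 1 - exp(-0.29/3); reference value frozen from
  # an independent 30-digit evaluation
  expect_equal(random_predictor_alarm_prob(0.29, 1200),
               0.0921414247726355, tolerance = 1e-12)
  # exact complement identity
  for (fpr in c(0.1, 0.29, 2))
    expect_equal(random_predictor_alarm_prob(fpr, 1200) +
                   exp(-fpr * 1200 / 3600), 1)
  expect_error(random_predictor_alarm_prob(-1, 1200), "FPR")
})

test_that("the random-predictor p-value equals exhaustive enumeration", {
  enum_p <- function(P, M, m) {
    if (M == 0) return(if (m == 0) 1 else 0)
    outcomes <- as.matrix(expand.grid(rep(list(0:1), M)))
    probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, P, 1 - P)))
    sum(probs[rowSums(outcomes) >= m])
  }
  expect_equal(random_predictor_pvalue(0.37, 5, 0), 1)
  expect_equal(random_predictor_pvalue(0.5, 3, 2), 0.5)
  for (seed in 1:20) {
    preictal:::with_seed(seed, {
      M <- sample(1:8, 1); m <- sample(0:M, 1); P <- runif(1)
    })
    expect_equal(random_predictor_pvalue(P, M, m), enum_p(P, M, m),
                 tolerance = 1e-12)
  }
  # monotonicity: p non-decreasing in P, non-increasing in m
  ps <- vapply(seq(0, 1, 0.1), random_predictor_pvalue, numeric(1),
               M = 6, m = 3)
  expect_true(all(diff(ps) >= -1e-12))
  pm <- vapply(0:6, function(m) random_predictor_pvalue(0.4, 6, m),
               numeric(1))
  expect_true(all(diff(pm) <= 1e-12))
  expect_error(random_predictor_pvalue(1.2, 3, 1), "P must")
  expect_error(random_predictor_pvalue(0.5, 3, 4), "m <= M")
})

test_that("the postictal drift profile counts preictal fractions per bin", {
  pred <- c(rep("PREICTAL", 30), rep("INTERICTAL", 90),
            rep("INTERICTAL", 50))
  toff <- c(seq(0, by = 5, length.out = 120),
            seq(7200, by = 5, length.out = 50))
  d <- postictal_drift_profile(pred, toff)
  expect_equal(d$bin_start_s, c(0, 7200))      # empty bin 1 h omitted
  expect_equal(d$frac_preictal, c(0.25, 0))
  expect_equal(d$n, c(120, 50))
  all_int <- postictal_drift_profile(rep("INTERICTAL", 10), 1:10)
  expect_true(all(all_int$frac_preictal == 0))
  expect_error(postictal_drift_profile("PREICTAL", -5), ">= 0")
  # independent recount on a randomized stream
  preictal:::with_seed(8, {
    pr <- sample(c("PREICTAL", "INTERICTAL"), 500, replace = TRUE)
    tt <- runif(500, 0, 4 * 3600)
  })
  d2 <- postictal_drift_profile(pr, tt)
  for (i in seq_len(nrow(d2))) {
    sel <- floor(tt / 3600) * 3600 == d2$bin_start_s[i]
    expect_equal(d2$frac_preictal[i], mean(pr[sel] == "PREICTAL"))
  }
})

test_that("stream fusion agrees with per-chunk classify_segment", {
  lev <- c("PREICTAL", "INTERICTAL", "POSTICTAL")
  for (seed in 1:5) {
    preictal:::with_seed(seed, {
      true <- rep(sample(lev, 6, replace = TRUE), times = sample(5:40, 6))
      pred <- sample(lev, length(true), replace = TRUE)
    })
    for (nc in 2:3) {
      f <- preictal:::.fuse_stream(true, pred, 6L, nc)
      # reference: chunk every stage-pure run by hand
      r <- rle(true); ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      ref <- character(0)
      for (i in seq_along(r$values)) {
        nseg <- r$lengths[i] %/% 6L
        for (s in seq_len(nseg)) {
          a <- starts[i] + (s - 1L) * 6L
          ref <- c(ref, classify_segment(pred[a:(a + 5L)], nc))
        }
      }
      expect_identical(f$pred, ref)
    }
  }
})
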