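pol <- staging_policy()

test_that("leading selection follows the 60-min gap rule", {
  ev <- data.frame(onset_s = c(7200, 11200), offset_s = c(7240, 11240))
  # gap 11200 - 7240 = 3960 s > 3600 s: both leading (1 h recorded before 1st)
  out <- select_leading_seizures(ev, pol)
  expect_identical(out$leading, c(TRUE, TRUE))
  # gap 2960 s: second not leading
  ev2 <- data.frame(onset_s = c(7200, 10200), offset_s = c(7240, 10240))
  expect_identical(select_leading_seizures(ev2, pol)$leading, c(TRUE, FALSE))
  # boundary: gap exactly 3600 s is not "more than 60 min"
  ev3 <- data.frame(onset_s = c(7200, 10840), offset_s = c(7240, 10880))
  expect_identical(select_leading_seizures(ev3, pol)$leading, c(TRUE, FALSE))
})

test_that("a first seizure without a fully recorded preictal hour is not leading", {
  ev <- data.frame(onset_s = 1800, offset_s = 1830)   # 30 min of recording
  spans <- data.frame(start_s = 0, end_s = 7200)
  expect_false(select_leading_seizures(ev, pol, spans)$leading)
  # brute-force: no 1-h window before onset fits in the recording
  expect_lt(preictal:::.recorded_overlap(spans, 1800 - 3600, 1800), 3600)
  # with >= 1 h recorded before onset it is leading
  ev2 <- data.frame(onset_s = 3600, offset_s = 3630)
  expect_true(select_leading_seizures(ev2, pol, spans)$leading)
})

test_that("single-seizure 12-h recording is staged exactly", {
  spans <- data.frame(start_s = 0, end_s = 12 * 3600)
  ev <- data.frame(onset_s = 36000, offset_s = 36060)
  st <- assign_stages(spans, ev, pol)
  expect_equal(st[st$stage == "PREICTAL", c("start_s", "end_s")],
               data.frame(start_s = 32400, end_s = 36000),
               ignore_attr = TRUE)
  expect_equal(st[st$stage == "ICTAL", c("start_s", "end_s")],
               data.frame(start_s = 36000, end_s = 36060),
               ignore_attr = TRUE)
  expect_equal(st[st$stage == "POSTICTAL", c("start_s", "end_s")],
               data.frame(start_s = 36060, end_s = 39660),
               ignore_attr = TRUE)
  # interictal: >= 3 h before onset; after the seizure 5-h buffer exceeds
  # the remaining recording so only the leading block survives
  inter <- st[st$stage == "INTERICTAL", ]
  expect_equal(inter$start_s, 0)
  expect_equal(inter$end_s, 36000 - 3 * 3600)
  # per-second oracle agrees everywhere
  expect_identical(stages_per_second(st)$stage,
                   oracle_stage_per_second(spans, ev, pol)$stage)
})

test_that("empty event list yields one interictal block", {
  spans <- data.frame(start_s = 0, end_s = 7200)
  st <- assign_stages(spans, data.frame(onset_s = numeric(0),
                                        offset_s = numeric(0)), pol)
  expect_identical(st$stage, "INTERICTAL")
  expect_equal(st$end_s - st$start_s, 7200)
})

test_that("close seizures leave no interictal and preictal wins over postictal", {
  spans <- data.frame(start_s = 0, end_s = 6 * 3600)
  # second onset 70 min after first offset: not leading, gap < buffers
  ev <- data.frame(onset_s = c(7200, 7260 + 4200), offset_s = c(7260, 11520))
  st <- assign_stages(spans, ev, pol)
  oracle <- oracle_stage_per_second(spans, ev, pol)
  expect_identical(stages_per_second(st)$stage, oracle$stage)
  # no interictal time between the two seizures
  between <- oracle$stage[oracle$second >= 7260 & oracle$second < 11460]
  expect_false(any(between == "INTERICTAL"))

  # a leading second seizure 90 min after the first: its preictal overlaps
  # the first seizure's postictal window and takes precedence there
  ev2 <- data.frame(onset_s = c(7200, 7260 + 5400), offset_s = c(7260, 12700))
  st2 <- assign_stages(spans, ev2, pol)
  oracle2 <- oracle_stage_per_second(spans, ev2, pol)
  expect_identical(stages_per_second(st2)$stage, oracle2$stage)
  pre2 <- st2[st2$stage == "PREICTAL", ]   # both seizures leading here
  expect_equal(pre2$start_s[2], 12660 - 3600)
  post1 <- st2[st2$stage == "POSTICTAL", ]
  expect_equal(post1$end_s[1], 12660 - 3600)  # truncated by preictal
})

test_that("stage intervals tile the recorded timeline on random schedules", {
  for (seed in 1:25) {
    sc <- random_schedule(seed)
    st <- assign_stages(sc$spans, sc$events, pol)
    # tiling: total staged time equals recorded time, no overlaps
    expect_equal(sum(st$end_s - st$start_s),
                 sum(sc$spans$end_s - sc$spans$start_s))
    st_o <- st[order(st$start_s), ]
    expect_true(all(st_o$start_s[-1] >= st_o$end_s[-nrow(st_o)] - 1e-9))
    # preictal never overlaps ictal/postictal (by per-second comparison)
    expect_identical(stages_per_second(st)$stage,
                     oracle_stage_per_second(sc$spans, sc$events, pol)$stage)
  }
})

test_that("leading-gap and buffer monotonicity hold", {
  for (seed in 1:10) {
    sc <- random_schedule(seed)
    if (nrow(sc$events) == 0) next
    tight <- select_leading_seizures(sc$events, pol, sc$spans)
    loose <- select_leading_seizures(
      sc$events, staging_policy(leading_gap_s = 1800), sc$spans)
    # shrinking the gap threshold never removes a leading seizure
    expect_true(all(loose$leading >= tight$leading))
    # growing the buffers never adds interictal time
    big <- staging_policy(interictal_pre_buffer_s = 6 * 3600,
                          interictal_post_buffer_s = 4 * 3600)
    d1 <- stage_durations(assign_stages(sc$spans, sc$events, pol))
    d2 <- stage_durations(assign_stages(sc$spans, sc$events, big))
    expect_lte(d2[["INTERICTAL"]], d1[["INTERICTAL"]] + 1e-9)
  }
})

test_that("policy guards reject inconsistent settings", {
  expect_error(staging_policy(preictal_len_s = 4 * 3600),
               "interictal_post_buffer_s")
  expect_error(staging_policy(postictal_len_s = 0), "positive")
  ev <- data.frame(onset_s = c(100, 50), offset_s = c(160, 90))
  expect_error(select_leading_seizures(ev, pol), "sorted")
})
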