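test_that("session key count tracks rate x duration", {
  log <- generate_session(typist_profile(typing_speed = 250, seed = 2),
                          duration_ms = 900000)
  n_pairs <- nrow(log$events) / 2
  expect_gt(n_pairs, 3750 * 0.9)
  expect_lt(n_pairs, 3750 * 1.1)
  # matched pairs, no orphans, strictly positive holds
  s <- extract_hold_times(log)
  d <- attr(s, "diagnostics")
  expect_equal(d$n_matched * 2, d$n_events)
  expect_equal(d$orphan_down + d$orphan_up + d$autorepeat + d$zero_hold, 0L)
})

test_that("identical seeds give byte-identical logs, different seeds differ", {
  prof <- typist_profile(seed = 77)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_keystroke_log(generate_session(prof, duration_ms = 120000), f1)
  write_keystroke_log(generate_session(prof, duration_ms = 120000), f2)
  expect_identical(readLines(f1), readLines(f2))

  other <- generate_session(prof, duration_ms = 120000, seed = 78)
  write_keystroke_log(other, f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("the generator is calibrated to its own targets", {
  # realized median hold time across 100 rested sessions near the target
  prof <- typist_profile(base_median_ht = 100, seed = 1)
  meds <- vapply(1:100, function(s) {
    log <- generate_session(prof, duration_ms = 900000, seed = 5000 + s)
    stats::median(extract_hold_times(log)$ht)
  }, 1)
  expect_equal(mean(meds), 100, tolerance = 0.02)

  # realized typing speed near the target
  speeds <- vapply(1:30, function(s) {
    log <- generate_session(typist_profile(typing_speed = 180, seed = 1),
                            duration_ms = 900000, seed = 7000 + s)
    nrow(log$events) / 2 / 15
  }, 1)
  expect_equal(mean(speeds), 180, tolerance = 0.03)
})

test_that("cohorts have the full 2x2 design and an honest manifest", {
  cohort <- generate_cohort(n_subjects = 4, master_seed = 3,
                            duration_ms = 120000)
  expect_length(cohort$logs, 16L)
  states <- vapply(cohort$logs, function(l) l$state, "")
  reps <- vapply(cohort$logs, function(l) l$repetition, 1L)
  subj <- vapply(cohort$logs, function(l) l$subject_id, "")
  expect_equal(as.integer(table(states)), c(8L, 8L))
  expect_equal(as.integer(table(reps)), c(8L, 8L))
  expect_equal(length(unique(subj)), 4L)
  expect_equal(nrow(cohort$manifest$profiles), 4L)
  expect_true(all(cohort$manifest$profiles$typing_speed >= 126 &
                    cohort$manifest$profiles$typing_speed <= 281))

  # same master seed reproduces the cohort exactly
  again <- generate_cohort(n_subjects = 4, master_seed = 3,
                           duration_ms = 120000)
  expect_identical(cohort$logs[[7]]$events, again$logs[[7]]$events)

  expect_error(generate_cohort(n_subjects = 1), "at least 2")
})

test_that("a cohort round-trips through a directory of log files", {
  cohort <- generate_cohort(n_subjects = 2, master_seed = 5,
                            duration_ms = 90000)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  expect_length(files, 8L)
  back <- read_keystroke_log(file.path(dir, "S01_rested_r1.csv"))
  expect_equal(back$events, cohort$logs[["S01_rested_r1"]]$events)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("impairment effect validates its factor directions", {
  expect_error(impairment_effect(ht_shift = 0.9), ">= 1")
  expect_error(impairment_effect(instability_gain = 0.5), ">= 1")
  expect_error(impairment_effect(speed_factor = 1.2), "<= 1")
  expect_error(typist_profile(typing_speed = 50), "plausible band")
})
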