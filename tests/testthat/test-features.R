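# Feature derivation: bed/wake run detection, interruption accounting,
# deviation features, prior-day activity, and the row invariants.

test_that("the worked night yields the documented bed and wake windows", {
  st <- figure1_states()
  # night starts at 10:20 PM: first >= 4 adjacent sleeping windows
  expect_equal(detect_bed_time(st, 4), 4L)        # window 4 = 10:20 PM
  # wake-up at 9:20 AM: start of the terminal awake run (window 136)
  expect_equal(detect_wake_up_time(st, 4, 4L), 136L)
  f <- sleepverse:::night_features(st, 4)
  expect_equal(f$sleep_time, (136 - 4) * 5 / 60)
  expect_equal(f$n_interruptions, 1L)
  expect_equal(f$interruptions_duration, 10)
  expect_equal(f$total_sleep, 130 * 5 / 60)
})

test_that("run detection handles boundaries and missing cases", {
  expect_true(is.na(detect_bed_time(rep("awake", 144), 3)))
  # run of exactly k-1 sleeping windows does not qualify
  st <- states_rle("a", 10, "s", 3, "a", 121, "s", 5, "a", 5)
  expect_equal(detect_bed_time(st, 4), 134L)
  expect_equal(detect_bed_time(st, 3), 10L)
  # sleeping through 10 AM: wake not found
  st2 <- states_rle("a", 4, "s", 140)
  expect_true(is.na(detect_wake_up_time(st2, 3, detect_bed_time(st2, 3))))
  # a mid-night awake run of >= k is an interruption; terminal run wins
  st3 <- states_rle("a", 2, "s", 30, "a", 5, "s", 99, "a", 8)
  expect_equal(detect_wake_up_time(st3, 4, 2L), 136L)
  expect_error(detect_wake_up_time(st3, 4, NA_integer_), "contract violation")
  # leading missing prefix does not start a run
  st4 <- states_rle("m", 6, "s", 130, "a", 8)
  expect_equal(detect_bed_time(st4, 3), 6L)
})

test_that("interruption accounting matches the brute-force run scan", {
  # constructed example: 20 sleep, 2 awake, 30 sleep, 1 awake, 40 sleep,
  # terminal awake (k = 3)
  st <- states_rle("a", 2, "s", 20, "a", 2, "s", 30, "a", 1, "s", 40, "a", 49)
  f <- sleepverse:::night_features(st, 3)
  expect_equal(f$bed_window, 2L)
  expect_equal(f$wake_window, 95L)
  expect_equal(f$n_interruptions, 2L)
  expect_equal(f$interruptions_duration, 15)
  bf <- bf_interruptions(st, f$bed_window, f$wake_window)
  expect_equal(f$n_interruptions, bf$n)
  expect_equal(f$interruptions_duration, bf$duration_windows * 5)

  # uninterrupted sleep: identities hold
  st2 <- states_rle("a", 4, "s", 132, "a", 8)
  f2 <- sleepverse:::night_features(st2, 3)
  expect_equal(f2$n_interruptions, 0L)
  expect_equal(f2$interruptions_duration, 0)
  expect_equal(f2$sleep_time, f2$total_sleep)

  # all-awake grid: total sleep 0, bed missing
  f3 <- sleepverse:::night_features(rep("awake", 144), 3)
  expect_equal(f3$total_sleep, 0)
  expect_true(is.na(f3$bed_window))
})

test_that("run detection and interruptions match brute force on random grids", {
  set.seed(501)
  for (rep in 1:400) {
    st <- random_states()
    for (k in 3:5) {
      bed <- detect_bed_time(st, k)
      expect_identical(bed, bf_bed(st, k))
      if (!is.na(bed)) {
        wake <- detect_wake_up_time(st, k, bed)
        expect_identical(wake, bf_wake(st, k, bed))
        if (!is.na(wake)) {
          f <- sleepverse:::night_features(st, k)
          bf <- bf_interruptions(st, bed, wake)
          expect_equal(f$n_interruptions, bf$n)
          expect_equal(f$interruptions_duration, bf$duration_windows * 5)
        }
      }
    }
  }
})

test_that("feature-row invariants hold on random grids; bed time antitone in k", {
  set.seed(502)
  for (rep in 1:200) {
    st <- random_states()
    prev_bed <- -1L
    for (k in 3:5) {
      f <- sleepverse:::night_features(st, k)
      bed <- detect_bed_time(st, k)
      # antitone: larger k never yields an earlier bed time
      if (!is.na(bed) && prev_bed >= 0L) expect_gte(bed, prev_bed)
      if (!is.na(bed)) prev_bed <- bed
      if (!is.na(f$bed_window) && !is.na(f$wake_window)) {
        expect_gt(f$wake_window, f$bed_window)
        expect_equal(f$sleep_time, (f$wake_window - f$bed_window) * 5 / 60)
        expect_lte(f$interruptions_duration, f$sleep_time * 60)
        expect_lte(f$sleep_time - f$interruptions_duration / 60,
                   f$total_sleep + 1e-9)
        expect_identical(f$n_interruptions == 0L, f$interruptions_duration == 0)
      }
    }
  }
})

test_that("deviation features recentre hours and demean per participant", {
  expect_equal(recentre_hours(22), 0)
  expect_equal(recentre_hours(10), 12)
  expect_equal(recentre_hours(CLOCK("2018-03-05 22:20:00")), 1 / 3)

  # bed times 23:00 and 01:00 -> recentred 1 and 3, deviations -1 and +1
  rows <- data.table(participant_id = "p1",
                     night_date = as.Date("2018-03-05") + 0:1,
                     config_id = "charging", k_adjacent = 3L,
                     bed_window = c(12L, 36L), wake_window = c(110L, 112L))
  out <- deviation_features(rows)
  expect_equal(out$dev_avg_bed_time, c(-1, 1))

  # identical bed times every night -> zero deviations
  rows2 <- data.table(participant_id = "p2", night_date = as.Date("2018-03-05") + 0:3,
                      config_id = "charging", k_adjacent = 3L,
                      bed_window = 15L, wake_window = 100L)
  expect_true(all(deviation_features(rows2)$dev_avg_bed_time == 0))
})

test_that("prior-day activity sums walking and cycling episodes", {
  day <- as.Date("2018-03-05")
  # no walking/cycling labels but other data present -> 0
  ev0 <- mk_events("p1", "2018-03-05 14:00:00", "activity", "Still")
  expect_equal(compute_user_active(ev0, "p1", day), 0)
  # no activity data that day -> missing
  expect_true(is.na(compute_user_active(ev0, "p1", day + 1)))
  # Walking at 14:00, Still at 14:30 -> 30 min
  ev1 <- mk_events("p1", c("2018-03-05 14:00:00", "2018-03-05 14:30:00"),
                   "activity", c("Walking", "Still"))
  expect_equal(compute_user_active(ev1, "p1", day), 30)
  # Walking 14:00, Cycling 14:20, Still 14:30 -> contiguous episodes merge
  ev2 <- mk_events("p1", c("2018-03-05 14:00:00", "2018-03-05 14:20:00",
                           "2018-03-05 14:30:00"),
                   "activity", c("Walking", "Cycling", "Still"))
  expect_equal(compute_user_active(ev2, "p1", day), 30)
  # trailing active episode closes at the start of the night (10 PM)
  ev3 <- mk_events("p1", "2018-03-05 21:50:00", "activity", "Walking")
  expect_equal(compute_user_active(ev3, "p1", day), 10)
})
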