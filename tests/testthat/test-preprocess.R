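# Cleaning rules: sparse/dead streams, gap outliers, centring, the 12-s
# screen filter, and the per-sensor sleep classification.

min5 <- function(n) CLOCK("2018-03-05 12:00:00") + (0:(n - 1)) * 180

test_that("sparse and dead streams are removed with reasons", {
  ev <- rbind(
    mk_events("p1", min5(9), "light", "5"),            # sparse: 9 obs
    mk_events("p2", min5(12), "accelerometer", "0"),   # dead: all zero
    mk_events("p3", min5(10), "light", c(rep("0", 9), "4")))  # boundary: kept
  out <- drop_sparse_or_dead(ev)
  expect_equal(sort(unique(out$events$participant_id)), "p3")
  expect_equal(nrow(out$events), 10L)
  expect_setequal(out$report$rule, c("sparse", "dead sensor"))
  expect_equal(out$report[participant_id == "p1", rule], "sparse")
  # idempotent: a second pass removes nothing
  again <- drop_sparse_or_dead(out$events)
  expect_equal(again$events, out$events)
  expect_equal(nrow(again$report), 0L)
})

test_that("gap outliers follow the boxplot rule on min-neighbour gaps", {
  # evenly spaced: nothing removed
  ev <- mk_events("p1", min5(30), "light", "5")
  expect_equal(nrow(drop_gap_outliers(ev)), 30L)

  # 50 events 3 min apart plus one 6 h away: the isolated event is removed
  times <- c(CLOCK("2018-03-05 08:00:00") + (0:49) * 180,
             CLOCK("2018-03-05 20:00:00"))
  ev2 <- mk_events("p1", times, "light", "5")
  kept <- drop_gap_outliers(ev2)
  expect_equal(nrow(kept), 50L)
  expect_false(CLOCK("2018-03-05 20:00:00") %in% kept$timestamp)
  expect_equal(which(!bf_gap_keep(as.numeric(times))), 51L)

  # two isolated events near each other survive the min-gap definition
  times3 <- c(CLOCK("2018-03-05 08:00:00") + (0:49) * 180,
              CLOCK("2018-03-05 20:00:00"),
              CLOCK("2018-03-05 20:02:00"))
  ev3 <- mk_events("p1", times3, "light", "5")
  expect_equal(nrow(drop_gap_outliers(ev3)), 52L)

  # < 4 events: passed through with a warning
  expect_warning(out <- drop_gap_outliers(mk_events("p1", min5(3), "light", "5")),
                 "fewer than 4")
  expect_equal(nrow(out), 3L)
})

test_that("gap-outlier removal matches the brute-force boxplot oracle", {
  set.seed(401)
  for (rep in 1:300) {
    n <- sample(4:40, 1L)
    times <- sort(round(cumsum(rexp(n, 1 / 5)) * 60))
    times <- times + seq_len(n) * 1e-3  # break exact ties
    ev <- mk_events("p", CLOCK("2018-03-05 00:00:00") + times, "light", "1")
    kept <- suppressWarnings(drop_gap_outliers(ev))
    expect_equal(as.numeric(kept$timestamp),
                 as.numeric(ev$timestamp)[bf_gap_keep(times)])
  }
})

test_that("accelerometer centring does the arithmetic", {
  ev <- mk_events("p1", min5(3), "accelerometer", c("0.1", "0.2", "0.6"))
  out <- center_accelerometer(ev)
  expect_equal(as.numeric(out$value), c(0.2, 0.1, 0.3))
  # constant stream collapses to zero; symmetric pair to equal magnitudes
  cst <- center_accelerometer(mk_events("p1", min5(4), "accelerometer", "0.3"))
  expect_true(all(as.numeric(cst$value) == 0))
  sym <- center_accelerometer(mk_events("p1", min5(2), "accelerometer", c("-1", "1")))
  expect_equal(as.numeric(sym$value), c(1, 1))
  # per participant, and other sensors untouched
  mix <- rbind(mk_events("p1", min5(2), "accelerometer", c("1", "3")),
               mk_events("p2", min5(2), "accelerometer", c("10", "14")),
               mk_events("p1", min5(2), "light", c("7", "9")))
  got <- center_accelerometer(mix)
  expect_equal(as.numeric(got[sensor == "accelerometer" & participant_id == "p1", value]), c(1, 1))
  expect_equal(as.numeric(got[sensor == "accelerometer" & participant_id == "p2", value]), c(2, 2))
  expect_equal(got[sensor == "light", value], c("7", "9"))
})

test_that("screen flashes under 12 s are removed after duplicate collapse", {
  t0 <- CLOCK("2018-03-05 23:00:00")
  ev <- mk_events("p1", t0 + c(0, 5), "screen", c("on", "off"))
  expect_equal(nrow(filter_screen_flashes(ev)), 0L)       # 5 s flash

  ev2 <- mk_events("p1", t0 + c(0, 30), "screen", c("on", "off"))
  expect_equal(nrow(filter_screen_flashes(ev2)), 2L)      # 30 s interaction

  ev3 <- mk_events("p1", t0 + c(0, 10, 20, 30), "screen",
                   c("off", "off", "on", "on"))
  out3 <- filter_screen_flashes(ev3)
  expect_equal(out3$value, c("off", "on"))                # duplicate collapse
  expect_equal(out3$timestamp, t0 + c(0, 20))             # first of each run

  # idempotence
  expect_equal(filter_screen_flashes(out3), out3)
  mixed <- mk_events("p1", t0 + c(0, 100, 104, 200, 500), "screen",
                     c("off", "on", "off", "on", "off"))
  once <- filter_screen_flashes(mixed)
  expect_equal(once$value, c("off", "on", "off"))
  expect_equal(filter_screen_flashes(once), once)
})

test_that("classification follows the sleep rules with strict thresholds", {
  cfg <- function(id) sensor_configs()[config_id == id]
  expect_false(classify_instant(cfg("accelerometer_0.25"), "0.3"))
  expect_true(classify_instant(cfg("accelerometer_0.5"), "0.3"))
  expect_false(classify_instant(cfg("light_8"), "8"))     # strict less-than
  expect_true(classify_instant(cfg("light_8"), "7.999"))
  expect_true(classify_instant(cfg("activity"), "Still"))
  expect_false(classify_instant(cfg("activity"), "Walking"))
  expect_true(classify_instant(cfg("charging"), "true"))
  expect_true(classify_instant(cfg("screen"), "off"))
  expect_true(classify_instant(cfg("wifi"), "true"))
  expect_error(classify_instant(cfg("activity"), "napping"), "contract violation")

  # monotone in the threshold: raising it never flips sleeping -> awake
  set.seed(7)
  vals <- as.character(round(runif(200, 0, 20), 3))
  for (sen in c("accelerometer", "light")) {
    th <- sort(sensor_configs()[sensor == sen, threshold])
    prev <- NULL
    for (t in th) {
      cur <- classify_instant(list(sensor = sen, threshold = t), vals)
      if (!is.null(prev)) expect_true(all(cur[prev]))
      prev <- cur
    }
  }
})

test_that("exactly ten sensor configurations exist", {
  sc <- sensor_configs()
  expect_equal(nrow(sc), 10L)
  expect_equal(sum(sc$sensor == "accelerometer"), 3L)
  expect_equal(sum(sc$sensor == "light"), 3L)
  expect_equal(anyDuplicated(sc$config_id), 0L)
})
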