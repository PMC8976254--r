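# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

library(data.table)

CLOCK <- function(x) as.POSIXct(x, tz = "UTC")

# Run-length state vector, e.g. states_rle("a", 4, "s", 132, "a", 8).
states_rle <- function(...) {
  args <- list(...)
  map <- c(a = "awake", s = "sleeping", m = "missing")
  out <- character(0)
  for (i in seq(1, length(args), by = 2))
    out <- c(out, rep(map[[args[[i]]]], args[[i + 1]]))
  out
}

# The worked night: asleep from 10:20 PM (window 4) with one mid-night
# interruption far from the edges, awake from 9:20 AM (window 136).
figure1_states <- function() states_rle("a", 4, "s", 60, "a", 2, "s", 70, "a", 8)

# Random night grids with realistic run structure (seeded by the caller).
random_states <- function() {
  n <- 0L
  runs_v <- character(0); runs_l <- integer(0)
  val <- sample(c("awake", "sleeping"), 1L)
  while (n < 144L) {
    len <- sample(1:40, 1L)
    runs_v <- c(runs_v, val); runs_l <- c(runs_l, len)
    n <- n + len
    val <- if (val == "awake") "sleeping" else "awake"
  }
  st <- rep(runs_v, runs_l)[1:144]
  if (runif(1) < 0.3) st[seq_len(sample(1:20, 1L))] <- "missing"  # leading gap
  st
}

# Event-table builder with second-resolution character or POSIXct times.
mk_events <- function(pid, times, sensor, values) {
  data.table(participant_id = pid,
             timestamp = if (inherits(times, "POSIXct")) times else CLOCK(times),
             sensor = sensor, value = as.character(values))
}

# Small simulated world shared by cheap tests.
tiny_params <- function(...) {
  do.call(sim_params, utils::modifyList(
    list(n_participants = 3L, n_days = 4L, seed = 11L), list(...)))
}

# Cached full-scale study for the acceptance tests: one stream simulation,
# reused across criteria (outcomes are regenerated per seed).
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!is.null(.acceptance_cache$fix)) return(.acceptance_cache$fix)
  params <- sim_params(seed = 20260911L)
  schedules <- simulate_schedules(params)
  events <- simulate_sensor_streams(schedules, params)
  clean <- preprocess_events(events)
  sensors <- c("accelerometer_0.5", "charging", "light_12", "activity", "screen")
  features <- compute_feature_table(
    clean$events, configs = sensor_configs()[config_id %in% sensors],
    k_values = 3L)
  .acceptance_cache$fix <- list(params = params, schedules = schedules,
                                features = features, sensors = sensors)
  .acceptance_cache$fix
}
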