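# Synthetic study generator.
#
# Emulates a two-week smartphone sensing study: per participant-night a
# ground-truth sleep schedule (bed time, wake time, nightly interruptions),
# six sensor event streams sampled irregularly around that schedule, and
# self-report outcomes (morning sleep quality, daily negative affect, one
# depression score) generated from the true sleep features with
# configurable effect sizes and noise.

#' Simulation parameters
#'
#' Builds a validated parameter object for the synthetic study generator.
#' Defaults emulate the observed sampling regime (events every 2.9 min on
#' average, SD 6.72 min, no gap above 15 min), uncalibrated accelerometers
#' (per-participant offset), nightly charging/Wi-Fi habits, and
#' notification-driven screen flashes shorter than 12 s.
#'
#' @param n_participants Number of participants.
#' @param n_days Number of study days (>= 2; default 14, a two-week study).
#' @param mean_sampling_interval,sampling_interval_sd Location and scale
#'   (minutes) of the normal distribution of inter-event intervals, which is
#'   truncated to (0.1, 15\] so that no gap exceeds 15 minutes.
#' @param accel_offset_sd SD (m/s^2) of the per-participant accelerometer
#'   calibration offset.
#' @param accel_sleep_noise_sd,accel_wake_noise_sd Accelerometer noise SDs
#'   (m/s^2) around the offset while asleep / awake.
#' @param light_night_lux,light_day_lux Typical illuminance while asleep /
#'   awake (lux).
#' @param sensor_flip_prob Probability that a sampled reading contradicts
#'   the true sleep state.
#' @param notification_flash_rate Expected number of sub-12-second screen-on
#'   flashes per night (Poisson).
#' @param bed_time_mean,bed_time_sd,wake_time_mean,wake_time_sd Clock-hour
#'   location/scale of true bed and wake times; draws are clipped into the
#'   10 PM - 10 AM night.
#' @param interruption_rate Expected number of nightly sleep interruptions
#'   (Poisson per night).
#' @param interruption_duration_range Min/max interruption duration, minutes.
#' @param effect_sizes Named list `ssq`/`na`/`depression`, each a named
#'   numeric vector of per-feature linear coefficients on true sleep
#'   features (names among sleep_time, total_sleep, dev_avg_bed_time,
#'   dev_avg_wake_up_time, n_interruptions, interruptions_duration).
#' @param noise_sd Named vector of residual SDs per outcome.
#' @param baselines Named vector of outcome intercepts (0-100 scale).
#' @param participant_intercept_sd Between-person SD of the random intercept
#'   for SSQ and NA.
#' @param missing_ssq_prob Probability a morning SSQ beep is missed.
#' @param p_female Probability a participant is female (study sample was
#'   36 F / 14 M).
#' @param activity_walk_prob,activity_cycle_prob Probability that an awake
#'   activity-recognition sample reads Walking / Cycling.
#' @param seed Integer seed; every downstream generator derives from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_participants = 50L,
                       n_days = 14L,
                       mean_sampling_interval = 2.9,
                       sampling_interval_sd = 6.72,
                       accel_offset_sd = 0.3,
                       accel_sleep_noise_sd = 0.05,
                       accel_wake_noise_sd = 0.5,
                       light_night_lux = 1,
                       light_day_lux = 200,
                       sensor_flip_prob = 0.02,
                       notification_flash_rate = 2,
                       bed_time_mean = 23.5,
                       bed_time_sd = 0.75,
                       wake_time_mean = 7.5,
                       wake_time_sd = 0.75,
                       interruption_rate = 1,
                       interruption_duration_range = c(5, 30),
                       effect_sizes = list(
                         ssq = c(sleep_time = 4),
                         na = c(n_interruptions = 3),
                         depression = c(sleep_time = -3)),
                       noise_sd = c(ssq = 10, na = 10, depression = 10),
                       baselines = c(ssq = 50, na = 50, depression = 50),
                       participant_intercept_sd = 8,
                       missing_ssq_prob = 0.3,
                       p_female = 0.72,
                       activity_walk_prob = 0.10,
                       activity_cycle_prob = 0.05,
                       seed = 1L) {
  p <- as.list(environment())
  if (!is.numeric(p$n_participants) || p$n_participants < 1)
    stop_config("n_participants", "must be >= 1")
  if (!is.numeric(p$n_days) || p$n_days < 2)
    stop_config("n_days", "must be >= 2 (hold-out split needs two weeks)")
  for (f in c("sensor_flip_prob", "missing_ssq_prob", "p_female",
              "activity_walk_prob", "activity_cycle_prob"))
    assert_prob(p[[f]], f)
  for (f in c("sampling_interval_sd", "accel_offset_sd",
              "accel_sleep_noise_sd", "accel_wake_noise_sd", "bed_time_sd",
              "wake_time_sd", "participant_intercept_sd",
              "notification_flash_rate", "interruption_rate"))
    assert_nonneg(p[[f]], f)
  if (p$mean_sampling_interval <= 0 || p$mean_sampling_interval > 15)
    stop_config("mean_sampling_interval", "must be in (0, 15] minutes")
  known <- setdiff(FEATURES, "user_active")
  for (oc in names(p$effect_sizes)) {
    if (!oc %in% OUTCOMES) stop_config("effect_sizes", paste("unknown outcome", oc))
    bad <- setdiff(names(p$effect_sizes[[oc]]), known)
    if (length(bad))
      stop_config("effect_sizes", paste("references unknown feature", bad[1L]))
  }
  p$n_participants <- as.integer(p$n_participants)
  p$n_days <- as.integer(p$n_days)
  p$seed <- as.integer(p$seed)
  structure(p, class = "sim_params")
}

STUDY_START <- as.Date("2018-03-05")

participant_ids <- function(n) sprintf("P%03d", seq_len(n))

# Truncated-normal draws on (lo, hi]; scale 0 collapses to the (clipped) mean.
rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(pmax(qnorm(u, mean, sd), lo), hi)
}

#' Simulate ground-truth sleep schedules
#'
#' Draws one true sleep schedule per participant-night: bed and wake times
#' (clipped into the 10 PM - 10 AM night) and a set of non-overlapping
#' interruptions strictly inside the sleep interval.  Times are stored on
#' the recentred night axis (10 PM = 0 ... 10 AM = 12 hours).
#'
#' @param params A [sim_params()] object.
#' @return A `data.table` with columns participant_id, night_date,
#'   true_bed (recentred hours), true_wake (recentred hours), and
#'   interruptions (list column of data.frames with start_h, duration_min).
#' @export
simulate_schedules <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 1L))
  pid <- participant_ids(params$n_participants)
  grid <- data.table::CJ(participant_id = pid,
                         night_date = STUDY_START + 0:(params$n_days - 1L))
  n <- nrow(grid)
  bed_r  <- rtnorm(n, recentre_hours(params$bed_time_mean), params$bed_time_sd,
                   0, 10)
  wake_r <- rtnorm(n, recentre_hours(params$wake_time_mean), params$wake_time_sd,
                   0, 12)
  wake_r <- pmin(pmax(wake_r, bed_r + 1), 12)  # wake strictly after bed
  dlo <- params$interruption_duration_range[1L]
  dhi <- params$interruption_duration_range[2L]
  n_int <- rpois(n, params$interruption_rate)
  interruptions <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_int[i]
    empty <- data.frame(start_h = numeric(), duration_min = numeric())
    if (k == 0L) { interruptions[[i]] <- empty; next }
    # draw, order, keep non-overlapping interruptions inside (bed, wake)
    st <- sort(runif(k, bed_r[i] + 0.05, wake_r[i] - 0.05))
    du <- runif(k, dlo, dhi)
    keep_s <- numeric(0); keep_d <- numeric(0); last_end <- bed_r[i]
    for (j in seq_len(k)) {
      en <- st[j] + du[j] / 60
      if (st[j] > last_end + 0.01 && en < wake_r[i] - 0.01) {
        keep_s <- c(keep_s, st[j]); keep_d <- c(keep_d, du[j])
        last_end <- en
      }
    }
    interruptions[[i]] <- if (length(keep_s))
      data.frame(start_h = keep_s, duration_min = keep_d) else empty
  }
  grid[, `:=`(true_bed = bed_r, true_wake = wake_r,
              interruptions = interruptions)]
  grid[]
}

#' True per-night sleep features from schedules
#'
#' The features the outcome generator (and parameter-recovery tests) treat
#' as ground truth: sleep duration, interruption count/duration, total
#' sleep, and signed deviations from each participant's average bed and
#' wake time on the recentred night axis.
#'
#' @param schedules Output of [simulate_schedules()].
#' @return A `data.table`, one row per participant-night.
#' @export
true_features <- function(schedules) {
  tf <- schedules[, .(
    participant_id, night_date,
    sleep_time = true_wake - true_bed,
    n_interruptions = vapply(interruptions, nrow, 0L),
    interruptions_duration = vapply(interruptions,
                                    function(d) sum(d$duration_min), 0),
    bed_r = true_bed, wake_r = true_wake)]
  tf[, total_sleep := sleep_time - interruptions_duration / 60]
  tf[, dev_avg_bed_time := bed_r - mean(bed_r), by = participant_id]
  tf[, dev_avg_wake_up_time := wake_r - mean(wake_r), by = participant_id]
  tf[, c("bed_r", "wake_r") := NULL]
  tf[]
}

# Renewal event times (minutes from origin) covering span_min minutes.
renewal_times <- function(span_min, mean_iv, sd_iv) {
  n_guess <- ceiling(span_min / max(mean_iv, 0.5)) + 30L
  t <- cumsum(rtnorm(n_guess, mean_iv, sd_iv, 0.1, 15))
  while (t[length(t)] < span_min)
    t <- c(t, t[length(t)] + cumsum(rtnorm(n_guess, mean_iv, sd_iv, 0.1, 15)))
  t[t <= span_min]
}

# TRUE where recentred hour rh falls inside a scheduled interruption.
in_interruption <- function(rh, ints) {
  if (nrow(ints) == 0L) return(rep(FALSE, length(rh)))
  out <- rep(FALSE, length(rh))
  for (j in seq_len(nrow(ints)))
    out <- out | (rh >= ints$start_h[j] &
                  rh < ints$start_h[j] + ints$duration_min[j] / 60)
  out
}

#' Simulate sensor event streams
#'
#' Generates, per participant, a continuous irregular event stream for each
#' of the six sensors across the whole study (a renewal process with
#' truncated-normal inter-event intervals, so no gap exceeds 15 minutes).
#' During true sleep the sampled values satisfy every sleep rule at its
#' strictest threshold (|accelerometer - offset| < 0.25 m/s^2, charging,
#' < 8 lux, "Still", screen off, Wi-Fi connected); awake values violate
#' every rule at its most lenient threshold.  Each sample is flipped to the
#' opposite state's distribution independently with `sensor_flip_prob`, and
#' notification flashes inject screen-on runs shorter than 12 s into true
#' sleep.
#'
#' @param schedules Output of [simulate_schedules()].
#' @param params The same [sim_params()] object.
#' @return An event `data.table` (participant_id, timestamp, sensor, value)
#'   as consumed by the preprocessing stage.
#' @export
simulate_sensor_streams <- function(schedules, params) {
  stopifnot(inherits(params, "sim_params"), nrow(schedules) > 0L)
  set.seed(derive_seed(params$seed, 2L))
  pid <- unique(schedules$participant_id)
  offsets <- setNames(rnorm(length(pid), 0, params$accel_offset_sd), pid)
  first_day <- min(schedules$night_date)
  # day 1 streams open at 10 AM: the preceding night is outside the study
  origin <- as_clock(paste(first_day, "10:00:00"))
  span_min <- as.numeric(difftime(
    night_start(max(schedules$night_date)) + 12 * 3600, origin, units = "mins"))

  sched_idx <- split(schedules, schedules$participant_id)
  out <- vector("list", length(pid) * 6L)
  k <- 0L
  for (p in pid) {
    sch <- sched_idx[[p]]
    for (sensor in SENSOR_KINDS) {
      tmin <- renewal_times(span_min, params$mean_sampling_interval,
                            params$sampling_interval_sd)
      ts <- origin + tmin * 60
      nw <- night_window(ts)
      rh <- nw$window * NA_real_
      ok <- !is.na(nw$window)
      rh[ok] <- recentre_hours(ts[ok])
      # true sleep state at each sample
      sleeping <- rep(FALSE, length(ts))
      m <- match(nw$night_date, sch$night_date)
      have <- ok & !is.na(m)
      idx <- which(have)
      if (length(idx)) {
        for (i in split(idx, m[have])) {
          row <- sch[m[i[1L]]]
          s <- rh[i] >= row$true_bed & rh[i] <= row$true_wake
          s[s] <- !in_interruption(rh[i][s], row$interruptions[[1L]])
          sleeping[i] <- s
        }
      }
      flip <- runif(length(ts)) < params$sensor_flip_prob
      obs <- xor(sleeping, flip)
      value <- sensor_values(sensor, obs, offsets[[p]], params)
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        participant_id = p, timestamp = ts, sensor = sensor, value = value)
    }
    # notification flashes: short screen-on runs inside true sleep
    fl <- simulate_flashes(sch, params)
    if (nrow(fl)) { k <- k + 1L; out[[k]] <- fl[, participant_id := p][] }
  }
  ev <- data.table::rbindlist(out[seq_len(k)], use.names = TRUE)
  data.table::setcolorder(ev, EVENT_COLS)
  data.table::setorder(ev, participant_id, sensor, timestamp)
  ev[]
}

# Sampled value for one sensor given the observed (possibly flipped) state.
sensor_values <- function(sensor, obs_sleeping, offset, params) {
  n <- length(obs_sleeping)
  s <- obs_sleeping
  switch(sensor,
    accelerometer = {
      v <- numeric(n)
      # asleep: strictly below the 0.25 m/s^2 threshold around the offset,
      # with margin so the rule still holds after per-participant centring
      # (centring recovers the offset only up to a small shift)
      v[s] <- offset + rtnorm(sum(s), 0, params$accel_sleep_noise_sd,
                              -0.2, 0.2)
      # awake: above the most lenient threshold (1 m/s^2), same margin
      v[!s] <- offset + sample(c(-1, 1), sum(!s), replace = TRUE) *
        (1.15 + abs(rnorm(sum(!s), 0, params$accel_wake_noise_sd)))
      as.character(signif(v, 7))
    },
    light = {
      v <- numeric(n)
      v[s] <- rtnorm(sum(s), params$light_night_lux, 2, 0, 7.99)
      v[!s] <- pmax(16, rnorm(sum(!s), params$light_day_lux,
                              params$light_day_lux / 4))
      as.character(signif(v, 7))
    },
    charging = ifelse(s, "true", "false"),
    wifi = ifelse(s, "true", "false"),
    screen = ifelse(s, "off", "on"),
    activity = {
      v <- character(n)
      v[s] <- "Still"
      pw <- params$activity_walk_prob; pc <- params$activity_cycle_prob
      v[!s] <- sample(c("Walking", "Cycling", "Other"), sum(!s),
                      replace = TRUE, prob = c(pw, pc, max(0, 1 - pw - pc)))
      v
    })
}

simulate_flashes <- function(sch, params) {
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(sch))) {
    nf <- rpois(1L, params$notification_flash_rate)
    if (nf == 0L) next
    t0 <- runif(nf, sch$true_bed[i] + 0.02, sch$true_wake[i] - 0.02)
    dur <- runif(nf, 1, 11.5)  # seconds, always below the 12 s filter
    base <- night_start(sch$night_date[i])
    for (j in seq_len(nf)) {
      on <- base + t0[j] * 3600
      k <- k + 1L
      rows[[k]] <- data.table::data.table(
        participant_id = NA_character_,
        timestamp = c(on, on + dur[j]),
        sensor = "screen", value = c("on", "off"))
    }
  }
  if (k == 0L)
    return(data.table::data.table(participant_id = character(),
                                  timestamp = as_clock(character()),
                                  sensor = character(), value = character()))
  data.table::rbindlist(rows)
}

#' Simulate self-report outcomes from true sleep features
#'
#' SSQ for the morning after night *d* and NA for the day after night *d*
#' are linear in the night's true features plus a participant random
#' intercept and residual noise, clipped to \[0, 100\].  Depression is one
#' value per participant, linear in the participant's mean true features.
#' Morning SSQ is missing with probability `missing_ssq_prob`; gender is
#' assigned for the stratified depression split.
#'
#' @param schedules Output of [simulate_schedules()].
#' @param params The same [sim_params()] object.
#' @return An `outcome_table` (see [read_outcomes()]).
#' @export
simulate_outcomes <- function(schedules, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 3L))
  tf <- true_features(schedules)
  pid <- unique(tf$participant_id)
  # effects apply to mean-centred features so the baseline is the outcome's
  # population mean and [0, 100] clipping stays rare
  lin <- function(outcome, dt) {
    b <- params$effect_sizes[[outcome]]
    v <- rep(0, nrow(dt))
    for (f in names(b)) {
      if (!f %in% names(dt)) stop_config("effect_sizes",
                                         paste("references unknown feature", f))
      v <- v + b[[f]] * (dt[[f]] - mean(dt[[f]]))
    }
    v
  }
  clip01 <- function(x) pmin(pmax(x, 0), 100)
  ic_ssq <- setNames(rnorm(length(pid), 0, params$participant_intercept_sd), pid)
  ic_na  <- setNames(rnorm(length(pid), 0, params$participant_intercept_sd), pid)
  daily <- tf[, .(participant_id, day = night_date + 1L)]
  daily[, ssq := clip01(params$baselines[["ssq"]] + ic_ssq[participant_id] +
                          lin("ssq", tf) + rnorm(.N, 0, params$noise_sd[["ssq"]]))]
  daily[, na := clip01(params$baselines[["na"]] + ic_na[participant_id] +
                         lin("na", tf) + rnorm(.N, 0, params$noise_sd[["na"]]))]
  daily[runif(.N) < params$missing_ssq_prob, ssq := NA_real_]
  pm <- tf[, lapply(.SD, mean), by = participant_id,
           .SDcols = setdiff(FEATURES, "user_active")]
  dep <- clip01(params$baselines[["depression"]] + lin("depression", pm) +
                  rnorm(nrow(pm), 0, params$noise_sd[["depression"]]))
  participants <- data.table::data.table(
    participant_id = pm$participant_id,
    depression = dep,
    gender = ifelse(runif(nrow(pm)) < params$p_female, "F", "M"))
  data.table::setorder(daily, participant_id, day)
  structure(list(daily = daily[], participants = participants[]),
            rejects = NULL, class = "outcome_table")
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: schedules, sensor streams and outcomes in one call.
#'
#' @param params A [sim_params()] object.
#' @return List with elements `schedules`, `events`, `outcomes`.
#' @export
simulate_study <- function(params = sim_params()) {
  schedules <- simulate_schedules(params)
  list(schedules = schedules,
       events = simulate_sensor_streams(schedules, params),
       outcomes = simulate_outcomes(schedules, params))
}
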