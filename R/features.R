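# Per-night sleep features derived from a carried-forward window grid.
#
# Seven features: SleepTime, TotalSleep, devAvgBedTime, devAvgWakeUpTime,
# nInterruptions, InterruptionsDuration (all from the grid) and UserActive
# (prior-day walking/cycling minutes from the activity stream).

#' Detect the bed-time window
#'
#' The first window starting a run of at least `k` consecutive sleeping
#' windows; `NA` if no such run exists.
#'
#' @param states Character vector of 144 window states (carried forward).
#' @param k Run length, 3-5.
#' @return 0-based window index or `NA`.
#' @export
detect_bed_time <- function(states, k) {
  stopifnot(k %in% K_ADJACENT)
  r <- rle(states == "sleeping")
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_integer_)
  start <- cumsum(c(0L, r$lengths))[hit[1L]]
  as.integer(start)
}

#' Detect the wake-up window
#'
#' The first window of the terminal run of at least `k` consecutive awake
#' windows extending to the end of the night, after the bed-time window.
#' `NA` when the night does not end in such a run (sleeping through 10 AM) -
#' wake-up is then "not found".  A mid-night awake run of length >= k
#' followed by more sleep is an interruption, not the wake-up.
#'
#' @param states Character vector of 144 window states.
#' @param k Run length, 3-5.
#' @param bed Bed window index from [detect_bed_time()]; must not be `NA`.
#' @return 0-based window index or `NA`.
#' @export
detect_wake_up_time <- function(states, k, bed) {
  stopifnot(k %in% K_ADJACENT)
  if (is.na(bed)) stop("contract violation: wake-up detection requires a bed time")
  r <- rle(states)
  last <- length(r$values)
  if (r$values[last] != "awake" || r$lengths[last] < k) return(NA_integer_)
  start <- sum(r$lengths[-last])
  if (start <= bed) return(NA_integer_)
  as.integer(start)
}

# Window index (0-based) -> recentred clock hours (10 PM = 0).
window_to_hours <- function(window) window * WINDOW_MIN / 60

# Features for one night's state vector; returns a one-row list.
night_features <- function(states, k) {
  bed <- detect_bed_time(states, k)
  wake <- if (is.na(bed)) NA_integer_ else detect_wake_up_time(states, k, bed)
  total_sleep <- sum(states == "sleeping") * WINDOW_MIN / 60
  if (is.na(bed) || is.na(wake)) {
    return(list(bed_window = bed, wake_window = wake,
                sleep_time = NA_real_, total_sleep = total_sleep,
                n_interruptions = NA_integer_,
                interruptions_duration = NA_real_))
  }
  seg <- states[(bed + 1L):wake]        # windows bed .. wake-1
  r <- rle(seg == "awake")
  list(bed_window = bed, wake_window = wake,
       sleep_time = (wake - bed) * WINDOW_MIN / 60,
       total_sleep = total_sleep,
       n_interruptions = as.integer(sum(r$values)),
       interruptions_duration = as.numeric(sum(seg == "awake") * WINDOW_MIN))
}

#' Compute per-night features for a grid table
#'
#' Bed/wake-derived features are missing when no qualifying run exists, but
#' TotalSleep is always reported.
#'
#' @param grid Carried-forward grid `data.table` (one or more configs).
#' @param k Run-length parameter in 3-5.
#' @return `data.table`, one row per participant-night-config with
#'   `k_adjacent = k`.
#' @export
compute_night_features <- function(grid, k) {
  g <- data.table::as.data.table(grid)
  data.table::setorder(g, participant_id, night_date, config_id, window)
  out <- g[, night_features(state, k),
           by = .(participant_id, night_date, config_id)]
  out[, k_adjacent := as.integer(k)]
  out[]
}

#' Add deviation-from-average bed and wake time features
#'
#' Bed/wake windows are mapped to recentred clock hours (10 PM = 0, ...,
#' 10 AM = 12) and expressed as the signed deviation from the participant's
#' mean over all available nights, within each sensor config and `k`.
#'
#' @param rows Feature `data.table` from [compute_night_features()].
#' @return The table with `dev_avg_bed_time` and `dev_avg_wake_up_time`
#'   columns (hours).
#' @export
deviation_features <- function(rows) {
  out <- data.table::copy(data.table::as.data.table(rows))
  dev <- function(w) {
    h <- window_to_hours(w)
    if (all(is.na(h))) h else h - mean(h, na.rm = TRUE)
  }
  out[, dev_avg_bed_time := dev(bed_window),
      by = .(participant_id, config_id, k_adjacent)]
  out[, dev_avg_wake_up_time := dev(wake_window),
      by = .(participant_id, config_id, k_adjacent)]
  out[]
}

#' Prior-day physical activity minutes
#'
#' UserActive for the night of date *D* is the time spent walking or
#' cycling during that day, i.e. between 10 AM and 10 PM of *D* (the
#' daytime between two nights).  The activity stream is a state machine: an
#' episode runs from a Walking/Cycling label to the next differing label
#' (contiguous active labels merge); a trailing active episode closes at
#' 10 PM.  Returns `NA` when the participant has no activity data that day.
#'
#' @param events Event `data.table` (activity rows are used).
#' @param participant Participant id.
#' @param day Calendar date of the day (same date as the night it precedes).
#' @return Active minutes (>= 0) or `NA`.
#' @export
compute_user_active <- function(events, participant, day) {
  ev <- data.table::as.data.table(events)
  lo <- as_clock(paste(day, "10:00:00"))
  hi <- as_clock(paste(day, "22:00:00"))
  act <- ev[sensor == "activity" & participant_id == participant &
              timestamp >= lo & timestamp < hi]
  if (nrow(act) == 0L) return(NA_real_)
  user_active_minutes(act$timestamp, act$value, hi)
}

# Episode arithmetic shared with the bulk path.
user_active_minutes <- function(timestamp, label, close_at) {
  o <- order(timestamp)
  ts <- as.numeric(timestamp)[o]
  lab <- label[o]
  active <- lab %in% c("Walking", "Cycling")
  dur <- c(diff(ts), pmax(as.numeric(close_at) - ts[length(ts)], 0)) / 60
  sum(dur[active])
}

#' Full feature table across sensor configurations and run lengths
#'
#' Classifies the cleaned events under each sensor configuration, builds
#' and carries forward the night grids, derives the per-night features for
#' each `k`, adds deviation features, and joins UserActive (shared across
#' configs).
#'
#' @param events Cleaned event `data.table` (see [preprocess_events()]).
#' @param configs Rows of [sensor_configs()] to include.
#' @param k_values Subset of 3:5.
#' @param nights Optional participant-night universe (see [build_grid()]);
#'   defaults to all nights spanned by any sensor's in-window events.
#' @return Feature `data.table`, one row per participant x night x config
#'   x k.
#' @export
compute_feature_table <- function(events, configs = sensor_configs(),
                                  k_values = K_ADJACENT, nights = NULL) {
  ev <- data.table::as.data.table(events)
  if (is.null(nights)) {
    nw <- night_window(ev$timestamp)
    nights <- unique(data.table::data.table(
      participant_id = ev$participant_id,
      night_date = nw$night_date)[!is.na(night_date)])
  }
  parts <- vector("list", nrow(configs) * length(k_values))
  i <- 0L
  for (ci in seq_len(nrow(configs))) {
    config <- configs[ci]
    cl <- classify_events(ev, config)
    grid <- carry_forward(build_grid(cl, config, nights = nights))
    for (k in k_values) {
      i <- i + 1L
      parts[[i]] <- compute_night_features(grid, k)
    }
  }
  feat <- data.table::rbindlist(parts, use.names = TRUE)
  feat <- deviation_features(feat)
  # UserActive: per participant-day, independent of config and k
  act <- ev[sensor == "activity"]
  if (nrow(act)) {
    act[, day := as.Date(timestamp, tz = TZ)]
    act <- act[timestamp >= as_clock(paste(day, "10:00:00")) &
                 timestamp < as_clock(paste(day, "22:00:00"))]
  }
  ua <- if (nrow(act)) {
    act[, .(user_active = user_active_minutes(
      timestamp, value, as_clock(paste(day[1L], "22:00:00")))),
      by = .(participant_id, day)]
  } else {
    data.table::data.table(participant_id = character(), day = as.Date(character()),
                           user_active = numeric())
  }
  feat[, day := night_date]
  feat <- merge(feat, ua, by = c("participant_id", "day"), all.x = TRUE)
  feat[, day := NULL]
  data.table::setorder(feat, participant_id, night_date, config_id, k_adjacent)
  feat[]
}
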