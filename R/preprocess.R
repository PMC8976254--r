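# Participant- and sensor-level cleaning, ending in per-instant sleep/awake
# classifications under each of the ten sensor configurations.

#' The ten sensor configurations
#'
#' Three accelerometer thresholds (0.25, 0.5, 1 m/s^2), three light
#' thresholds (8, 12, 16 lux), and the four threshold-free sensors
#' (charging, activity, screen, Wi-Fi).
#'
#' @return A `data.table` with columns config_id, sensor, threshold.
#' @export
sensor_configs <- function() {
  data.table::data.table(
    config_id = c("accelerometer_0.25", "accelerometer_0.5", "accelerometer_1",
                  "light_8", "light_12", "light_16",
                  "charging", "activity", "screen", "wifi"),
    sensor = c(rep("accelerometer", 3L), rep("light", 3L),
               "charging", "activity", "screen", "wifi"),
    threshold = c(0.25, 0.5, 1, 8, 12, 16, NA, NA, NA, NA))
}

#' Drop sparse or dead participant-sensor streams
#'
#' Removes, per participant and sensor, streams with fewer than 10
#' observations ("sparse") or whose values are all zero, indicating a
#' broken sensor ("dead sensor").  Nothing is removed silently: every
#' removal is listed in the exclusion report.
#'
#' @param events Event `data.table`.
#' @return List with `events` (retained rows) and `report` (participant_id,
#'   sensor, rule, detail).
#' @export
drop_sparse_or_dead <- function(events) {
  ev <- data.table::as.data.table(events)
  num <- suppressWarnings(as.numeric(ev$value))
  ev[, .is_zero := !is.na(num) & num == 0]
  stat <- ev[, .(n = .N, all_zero = all(.is_zero)),
             by = .(participant_id, sensor)]
  stat[, drop := n < 10L | all_zero]
  stat[, rule := data.table::fifelse(n < 10L, "sparse",
                                     data.table::fifelse(all_zero, "dead sensor", NA_character_))]
  report <- stat[drop == TRUE,
                 .(participant_id, sensor, rule,
                   detail = sprintf("%d observations%s", n,
                                    ifelse(all_zero, ", all values 0", "")))]
  keep <- stat[drop == FALSE, .(participant_id, sensor)]
  ev <- ev[keep, on = c("participant_id", "sensor")]
  ev[, .is_zero := NULL]
  list(events = ev[], report = report[])
}

# Boxplot rule on a gap vector: TRUE marks outliers above Q3 + 1.5 IQR.
gap_is_outlier <- function(gaps) {
  q <- quantile(gaps, c(0.25, 0.75), names = FALSE, type = 7)
  gaps > q[2L] + 1.5 * (q[2L] - q[1L])
}

#' Remove temporally isolated observations
#'
#' For each event the gap is the smaller of the time to its previous and to
#' its next neighbour within the participant-sensor stream; events whose
#' gap exceeds Q3 + 1.5 IQR of the stream's gaps (the standard boxplot
#' whisker) are removed.  Streams with fewer than 4 events pass through
#' unchanged with a warning (quartiles undefined).
#'
#' @param events Event `data.table`.
#' @return The filtered event `data.table`.
#' @export
drop_gap_outliers <- function(events) {
  ev <- data.table::as.data.table(events)
  data.table::setorder(ev, participant_id, sensor, timestamp)
  small <- ev[, .N, by = .(participant_id, sensor)][N < 4L]
  if (nrow(small))
    warning(sprintf("%d stream(s) with fewer than 4 events passed through unfiltered",
                    nrow(small)))
  ev[, .keep := {
    if (.N < 4L) rep(TRUE, .N) else {
      tt <- as.numeric(timestamp)
      d <- diff(tt)
      gap <- pmin(c(Inf, d), c(d, Inf))
      !gap_is_outlier(gap)
    }
  }, by = .(participant_id, sensor)]
  out <- ev[.keep == TRUE]
  out[, .keep := NULL]
  out[]
}

#' Centre accelerometer values per participant
#'
#' Accelerometers were uncalibrated, so values are centred per participant
#' and replaced by their absolute values; other sensors pass through
#' untouched.
#'
#' @param events Event `data.table`.
#' @return Event `data.table` with transformed accelerometer values (>= 0).
#' @export
center_accelerometer <- function(events) {
  ev <- data.table::copy(data.table::as.data.table(events))
  idx <- ev$sensor == "accelerometer"
  if (any(idx)) {
    acc <- ev[idx]
    acc[, num := as.numeric(value)]
    acc[, num := abs(num - mean(num)), by = participant_id]
    ev[idx, value := as.character(signif(acc$num, 10))]
  }
  ev[]
}

#' Filter notification flashes from the screen stream
#'
#' Screen events are a state machine with frequent duplicate entries.
#' Consecutive same-state events are collapsed to the first, then every
#' on -> off pair lasting less than 12 seconds is removed (notification
#' flashes, brief time checks).  Non-screen events pass through.
#'
#' @param events Event `data.table`.
#' @return Event `data.table` with flashes removed.
#' @export
filter_screen_flashes <- function(events) {
  ev <- data.table::as.data.table(events)
  scr <- ev[sensor == "screen"]
  rest <- ev[sensor != "screen"]
  if (nrow(scr) == 0L) return(ev[])
  data.table::setorder(scr, participant_id, timestamp)
  scr[, .keep := value != data.table::shift(value, fill = ""),
      by = participant_id]
  scr <- scr[.keep == TRUE][, .keep := NULL]
  scr[, .flash := {
    nxt_t <- data.table::shift(as.numeric(timestamp), type = "lead")
    nxt_v <- data.table::shift(value, type = "lead")
    short_on <- value == "on" & nxt_v == "off" &
      (nxt_t - as.numeric(timestamp)) < 12
    short_on[is.na(short_on)] <- FALSE
    # drop both members of each short on->off pair
    short_on | c(FALSE, head(short_on, -1L))
  }, by = participant_id]
  scr <- scr[.flash == FALSE][, .flash := NULL]
  # removal can create new duplicate runs (off, [on off], off): re-collapse
  scr[, .keep := value != data.table::shift(value, fill = ""),
      by = participant_id]
  scr <- scr[.keep == TRUE][, .keep := NULL]
  out <- data.table::rbindlist(list(rest, scr), use.names = TRUE)
  data.table::setorder(out, participant_id, sensor, timestamp)
  out[]
}

#' Classify one sampled value as sleeping or awake
#'
#' Applies the per-sensor sleep rule: accelerometer |value| strictly below
#' the threshold (after centring); charging; light strictly below the lux
#' threshold; activity recognition returning "Still"; screen off; connected
#' to Wi-Fi.
#'
#' @param config One row of [sensor_configs()] (or a list with `sensor` and
#'   `threshold`).
#' @param value Vector of values matching the config's sensor domain.
#' @return Logical vector, TRUE = sleeping.
#' @export
classify_instant <- function(config, value) {
  sensor <- config$sensor
  if (!sensor %in% SENSOR_KINDS) stop("contract violation: unknown sensor")
  switch(sensor,
    accelerometer = {
      v <- as.numeric(value)
      if (anyNA(v)) stop("contract violation: non-numeric accelerometer value")
      abs(v) < config$threshold
    },
    light = {
      v <- as.numeric(value)
      if (anyNA(v) || any(v < 0)) stop("contract violation: invalid lux value")
      v < config$threshold
    },
    charging = check_domain(value, c("true", "false")) == "true",
    wifi = check_domain(value, c("true", "false")) == "true",
    screen = check_domain(value, c("on", "off")) == "off",
    activity = check_domain(value, ACTIVITY_LABELS) == "Still")
}

check_domain <- function(value, domain) {
  if (!all(value %in% domain))
    stop("contract violation: value outside sensor domain")
  value
}

#' Full cleaning pipeline
#'
#' Runs, in order: sparse/dead stream removal, gap-outlier removal,
#' per-participant accelerometer centring, and screen-flash filtering.
#' Each operation is idempotent.
#'
#' @param events Raw event `data.table`.
#' @return List with `events` (cleaned) and `report` (exclusion report).
#' @export
preprocess_events <- function(events) {
  s <- drop_sparse_or_dead(events)
  ev <- suppressWarnings(drop_gap_outliers(s$events))
  ev <- center_accelerometer(ev)
  ev <- filter_screen_flashes(ev)
  list(events = ev, report = s$report)
}
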