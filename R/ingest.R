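# Reading, writing and validating the tabular formats.
#
# Sensor events travel as one long CSV with the fixed header
# participant_id,timestamp,sensor,value (timestamps ISO-8601, local clock).
# Values are kept as character in the long table; sensor-specific parsing
# happens where a value is consumed.

EVENT_COLS <- c("participant_id", "timestamp", "sensor", "value")

# Value-domain check per sensor kind; returns TRUE for admissible values.
value_ok <- function(sensor, value) {
  num <- suppressWarnings(as.numeric(value))
  out <- logical(length(value))
  i <- sensor == "accelerometer"
  out[i] <- !is.na(num[i])
  i <- sensor == "light"
  out[i] <- !is.na(num[i]) & num[i] >= 0
  i <- sensor %in% c("charging", "wifi")
  out[i] <- value[i] %in% c("true", "false")
  i <- sensor == "screen"
  out[i] <- value[i] %in% c("on", "off")
  i <- sensor == "activity"
  out[i] <- value[i] %in% ACTIVITY_LABELS
  out
}

#' Read a long-format sensor event CSV
#'
#' Expects columns `participant_id,timestamp,sensor,value` with ISO-8601
#' timestamps in local clock time.  Structural problems (unknown sensor
#' kind, unparseable timestamp) abort with the offending line numbers;
#' rows violating a value domain (e.g. negative lux) are collected into a
#' reject report attached as `attr(x, "rejects")`, never silently dropped.
#' Accepted events are returned sorted by participant, sensor, timestamp.
#'
#' @param path Path to the CSV file.
#' @return A `data.table` of events with attribute `rejects`.
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  if (!identical(names(dt), EVENT_COLS))
    stop("format error: expected header ", paste(EVENT_COLS, collapse = ","))
  if (nrow(dt) == 0L) {
    ev <- data.table::data.table(participant_id = character(),
                                 timestamp = as_clock(character()),
                                 sensor = character(), value = character())
    data.table::setattr(ev, "rejects", dt[, c(EVENT_COLS), with = FALSE])
    return(ev[])
  }
  line <- seq_len(nrow(dt)) + 1L  # header is line 1
  bad_sensor <- !dt$sensor %in% SENSOR_KINDS
  if (any(bad_sensor))
    stop(sprintf("format error: unknown sensor kind '%s' at line %d",
                 dt$sensor[bad_sensor][1L], line[bad_sensor][1L]))
  ts <- as.POSIXct(strptime(sub("T", " ", dt$timestamp, fixed = TRUE),
                            "%Y-%m-%d %H:%M:%S", tz = TZ))
  if (anyNA(ts))
    stop(sprintf("format error: unparseable timestamp '%s' at line %d",
                 dt$timestamp[is.na(ts)][1L], line[is.na(ts)][1L]))
  ok <- value_ok(dt$sensor, dt$value)
  rejects <- dt[!ok]
  rejects[, reason := "value outside sensor domain"]
  ev <- dt[ok]
  ev[, timestamp := ts[ok]]
  data.table::setorder(ev, participant_id, sensor, timestamp)
  data.table::setattr(ev, "rejects", rejects[])
  ev[]
}

#' Write sensor events to CSV
#'
#' Inverse of [read_events()]: `read_events(write_events(x, p))` returns an
#' event table identical to `x`.
#'
#' @param events Event `data.table` as produced by [read_events()] or
#'   [simulate_sensor_streams()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.table::as.data.table(events)[, EVENT_COLS, with = FALSE]
  out <- data.table::copy(out)
  out[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = TZ)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read the ESM outcome table
#'
#' One CSV with columns `participant_id,day,ssq,na,depression,gender`.
#' `ssq` and `na` vary per participant-day; `depression` and `gender` are
#' participant-level and must be constant within participant (at most one
#' depression value each).  SSQ/NA outside \[0, 100\] are rejected into the
#' reject report; inconsistent depression values are a format error.
#'
#' @param path Path to the CSV file.
#' @return An `outcome_table`: list with elements `daily` (participant_id,
#'   day, ssq, na) and `participants` (participant_id, depression, gender),
#'   plus a `rejects` attribute.
#' @export
read_outcomes <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = c("participant_id", "gender")),
                          na.strings = "")
  need <- c("participant_id", "day", "ssq", "na", "depression", "gender")
  if (!all(need %in% names(dt)))
    stop("format error: expected columns ", paste(need, collapse = ","))
  dt[, day := as.Date(day)]
  bad <- (!is.na(dt$ssq) & (dt$ssq < 0 | dt$ssq > 100)) |
         (!is.na(dt$na)  & (dt$na  < 0 | dt$na  > 100)) |
         (!is.na(dt$depression) & (dt$depression < 0 | dt$depression > 100))
  rejects <- dt[bad]
  if (nrow(rejects)) rejects[, reason := "outcome outside [0, 100]"]
  dt <- dt[!bad]
  pp <- unique(dt[, .(participant_id, depression, gender)])
  if (anyDuplicated(pp$participant_id))
    stop("format error: participant with more than one depression value: ",
         pp$participant_id[duplicated(pp$participant_id)][1L])
  daily <- dt[, .(participant_id, day, ssq, na)]
  data.table::setorder(daily, participant_id, day)
  data.table::setorder(pp, participant_id)
  structure(list(daily = daily[], participants = pp[]),
            rejects = rejects, class = "outcome_table")
}

#' Write an outcome table to CSV
#'
#' @param outcomes An `outcome_table` (see [read_outcomes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  stopifnot(inherits(outcomes, "outcome_table"))
  out <- merge(outcomes$daily, outcomes$participants, by = "participant_id")
  data.table::setorder(out, participant_id, day)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("<outcome_table>", nrow(x$daily), "participant-days,",
      nrow(x$participants), "participants\n")
  invisible(x)
}
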