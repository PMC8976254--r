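# Per-night 5-minute window grids: majority vote over classified instants,
# tie inheritance, and last-observation-carried-forward.
#
# A night grid has exactly 144 windows covering 10 PM - 10 AM; window 0 is
# [22:00, 22:05).  States are "sleeping", "awake" or "missing"; after
# carry-forward, "missing" survives only as a leading prefix.

STATE_LEVELS <- c("missing", "awake", "sleeping")

# Sensors whose stream is a state machine: between events the last emitted
# state persists, so an empty window inherits one implied observation at
# its start.
STATE_MACHINE_SENSORS <- c("screen", "charging", "wifi")

#' Classify a sensor stream per instant
#'
#' @param events Cleaned event `data.table`.
#' @param config One row of [sensor_configs()].
#' @return `data.table` (participant_id, timestamp, sleeping) for the
#'   config's sensor.
#' @export
classify_events <- function(events, config) {
  ev <- data.table::as.data.table(events)[sensor == config$sensor]
  ev[, .(participant_id, timestamp,
         sleeping = classify_instant(config, value))]
}

# Majority vote with tie inheritance over one night's vote counts.
# votes: integer matrix-like vectors n_sleep, n_awake, implied (0/1/2 state
# for empty windows, 0 = none).  Returns integer states 0/1/2.
resolve_night <- function(n_sleep, n_awake, implied) {
  st <- integer(length(n_sleep))
  st[n_sleep > n_awake] <- 2L
  st[n_awake > n_sleep] <- 1L
  empty <- n_sleep + n_awake == 0L
  st[empty] <- implied[empty]           # implied observation or 0 (missing)
  tie <- !empty & n_sleep == n_awake
  if (any(tie)) {
    prev <- 0L
    for (i in seq_along(st)) {
      if (tie[i]) st[i] <- prev         # first-window tie stays missing (0)
      prev <- st[i]
    }
  }
  st
}

#' Build per-night window grids for one sensor configuration
#'
#' Each 5-minute window takes the majority state of the observations
#' timestamped inside it.  A tie inherits the previous window's resolved
#' state (missing for a first-window tie).  Windows without observations
#' are missing, except for the state-machine sensors (screen, charging,
#' Wi-Fi) where the last emitted state before the window start contributes
#' one implied observation.
#'
#' @param classified Output of [classify_events()].
#' @param config The [sensor_configs()] row used.
#' @param nights Optional `data.table` (participant_id, night_date) fixing
#'   the participant-night universe; defaults to every night with at least
#'   one in-window observation.
#' @return A grid `data.table`: participant_id, night_date, config_id,
#'   window (0-143), state ("sleeping"/"awake"/"missing"), before
#'   carry-forward.
#' @export
build_grid <- function(classified, config, nights = NULL) {
  cl <- data.table::as.data.table(classified)
  nw <- night_window(cl$timestamp)
  cl[, `:=`(night_date = nw$night_date, window = nw$window)]
  inw <- cl[!is.na(window)]
  votes <- inw[, .(n_sleep = sum(sleeping), n_awake = sum(!sleeping)),
               by = .(participant_id, night_date, window)]
  if (is.null(nights))
    nights <- unique(inw[, .(participant_id, night_date)])
  skel <- nights[, data.table::CJ(window = 0:(N_WINDOWS - 1L)),
                 by = .(participant_id, night_date)]
  grid <- merge(skel, votes, by = c("participant_id", "night_date", "window"),
                all.x = TRUE)
  grid[is.na(n_sleep), `:=`(n_sleep = 0L, n_awake = 0L)]
  grid[, implied := 0L]
  if (config$sensor %in% STATE_MACHINE_SENSORS && nrow(cl) > 0L) {
    # last emitted state at each empty window's start (LOCF over the stream)
    data.table::setorder(cl, participant_id, timestamp)
    empt <- grid[n_sleep + n_awake == 0L]
    if (nrow(empt)) {
      empt[, wstart := night_start(night_date) + window * WINDOW_MIN * 60]
      streams <- split(cl, by = "participant_id")
      empt[, implied := {
        s <- streams[[.BY$participant_id]]
        if (is.null(s)) rep(0L, .N) else {
          i <- findInterval(as.numeric(wstart), as.numeric(s$timestamp))
          data.table::fifelse(i == 0L, 0L,
                              data.table::fifelse(s$sleeping[pmax(i, 1L)], 2L, 1L))
        }
      }, by = participant_id]
      grid[empt, on = c("participant_id", "night_date", "window"),
           implied := i.implied]
    }
  }
  data.table::setorder(grid, participant_id, night_date, window)
  grid[, state := STATE_LEVELS[resolve_night(n_sleep, n_awake, implied) + 1L],
       by = .(participant_id, night_date)]
  grid[, config_id := config$config_id]
  grid[, .(participant_id, night_date, config_id, window, state)]
}

# LOCF over one night's state vector; leading missing windows remain.
carry_forward_states <- function(state) {
  miss <- state == "missing"
  if (all(miss) || !any(miss)) return(state)
  idx <- cummax(seq_along(state) * !miss)  # last non-missing position so far
  out <- state
  fill <- miss & idx > 0L
  out[fill] <- state[idx[fill]]
  out
}

#' Carry the last observed state forward over missing windows
#'
#' Every missing window after the first non-missing one takes the preceding
#' window's state; leading missing windows remain missing.  All-missing
#' nights are returned unchanged and flagged in the `unusable` attribute.
#'
#' @param grid Grid `data.table` from [build_grid()].
#' @return The grid with carried-forward states; attribute `unusable` lists
#'   all-missing participant-nights.
#' @export
carry_forward <- function(grid) {
  g <- data.table::copy(data.table::as.data.table(grid))
  data.table::setorder(g, participant_id, night_date, config_id, window)
  g[, state := carry_forward_states(state),
    by = .(participant_id, night_date, config_id)]
  unusable <- g[, .(all_missing = all(state == "missing")),
                by = .(participant_id, night_date, config_id)][all_missing == TRUE]
  data.table::setattr(g, "unusable",
                      unusable[, .(participant_id, night_date, config_id)])
  g[]
}

#' Export grids as 144-character state strings
#'
#' One row per participant-night with states encoded `s`/`a`/`m`; useful
#' for fixtures and debugging.
#'
#' @param grid Grid `data.table`.
#' @return `data.table` (participant_id, night_date, config_id, states).
#' @export
grid_to_string <- function(grid) {
  g <- data.table::as.data.table(grid)
  data.table::setorder(g, participant_id, night_date, config_id, window)
  g[, .(states = paste(substr(state, 1L, 1L), collapse = "")),
    by = .(participant_id, night_date, config_id)]
}

# Inverse helper for tests/fixtures: "samm..." -> state vector.
string_to_states <- function(s) {
  map <- c(s = "sleeping", a = "awake", m = "missing")
  unname(map[strsplit(s, "")[[1L]]])
}
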