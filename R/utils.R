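# Shared constants and small helpers.

# Night definition: 10 PM to 10 AM next day, 144 five-minute windows.
NIGHT_START_HOUR <- 22L
NIGHT_HOURS      <- 12L
WINDOW_MIN       <- 5L
N_WINDOWS        <- NIGHT_HOURS * 60L %/% WINDOW_MIN  # 144

SENSOR_KINDS <- c("accelerometer", "charging", "light", "activity", "screen", "wifi")

ACTIVITY_LABELS <- c("Still", "Walking", "Cycling", "Other")

FEATURES <- c("sleep_time", "total_sleep", "dev_avg_bed_time",
              "dev_avg_wake_up_time", "n_interruptions",
              "interruptions_duration", "user_active")

OUTCOMES <- c("ssq", "na", "depression")

MODEL_KINDS <- c("mixed_effects", "knn", "svm_radial", "xgboost", "gam_splines")

OUTLIER_KINDS <- c("none", "median_3sd", "median_3mad", "isolation_forest")

K_ADJACENT <- 3:5

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats median sd rnorm runif rpois rbinom predict quantile
#'   complete.cases coef lm cor cor.test anova setNames pnorm qnorm vcov
#' @importFrom utils head tail
NULL

# Timestamps are local clock times; we store them as POSIXct in UTC so no
# daylight-saving arithmetic ever shifts a night boundary.
TZ <- "UTC"

as_clock <- function(x) {
  if (is.character(x)) x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, tz = TZ)
}

#' Recentre a clock time onto the night axis
#'
#' Maps clock hours onto the 12-hour night scale where 10 PM = 0,
#' 11 PM = 1, ..., 10 AM = 12.  Accepts POSIXct or numeric hours-of-day
#' (0-24).
#'
#' @param x POSIXct times or numeric hours of day.
#' @return Numeric hours on the recentred scale.
#' @export
recentre_hours <- function(x) {
  if (inherits(x, "POSIXct")) {
    lt <- as.POSIXlt(x, tz = TZ)
    x <- lt$hour + lt$min / 60 + lt$sec / 3600
  }
  ifelse(x >= NIGHT_START_HOUR, x - NIGHT_START_HOUR, x + 24 - NIGHT_START_HOUR)
}

# Night membership: the night labelled D covers [D 22:00, D+1 10:00).
night_start <- function(night_date) as_clock(paste(night_date, "22:00:00"))

# Window index (0-based) of a timestamp within its night, or NA if outside
# the 10 PM - 10 AM range.  Also returns the night date.
night_window <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = TZ)
  hod <- lt$hour + lt$min / 60 + lt$sec / 3600
  in_evening <- hod >= NIGHT_START_HOUR
  in_morning <- hod < (NIGHT_START_HOUR + NIGHT_HOURS - 24)
  night_date <- as.Date(timestamp, tz = TZ)
  night_date[in_morning] <- night_date[in_morning] - 1L
  rh <- recentre_hours(hod)
  window <- as.integer(floor(rh * 60 / WINDOW_MIN))
  window[!(in_evening | in_morning)] <- NA_integer_
  night_date[!(in_evening | in_morning)] <- NA
  list(night_date = night_date, window = window)
}

# Deterministic child seed (kept < 2^31).
derive_seed <- function(seed, salt) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(salt) %% 2011L
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a probability in [0, 1]")
  invisible(x)
}

assert_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_config(field, "must be a non-negative number")
  invisible(x)
}
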