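#' @useDynLib sleepverse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @keywords internal
"_PACKAGE"

# data.table columns referenced non-standardly
utils::globalVariables(c(
  ".", ".I", ".N", ".BY", ".SD", "participant_id", "timestamp", "sensor",
  "value", "reason", "night_date", "window", "state", "config_id",
  "n_sleep", "n_awake", "implied", "wstart", "i.implied", ".keep",
  ".flash", ".is_zero", "all_zero", "n", "rule", "detail", "num",
  "bed_window", "wake_window", "k_adjacent", "day", "user_active",
  "dev_avg_bed_time", "dev_avg_wake_up_time", "total_sleep", "sleep_time",
  "interruptions_duration", "n_interruptions", "true_bed", "true_wake",
  "interruptions", "bed_r", "wake_r", "ssq", "na", "depression", "gender",
  "day_idx", "split", "y", "feature", "outcome", "model", "outlier", "k",
  "r2_validation", "r2_train", "status", ".complexity", "p", "p_adjusted",
  "significant", "val_obs", "val_pred", "drop"))
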