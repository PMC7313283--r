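# Canonical measurement schema for the daily wearable record.
#
# Variable names follow the device-export convention: snake_case with a
# domain prefix (walk_, physicalactivity_, heartrate_, sleep_). Times are
# seconds, distances metres, heart rates beats per minute.

wb_count_vars <- c(
  "walk_steps", "stairs_floor_changes_up",
  "sleep_deep_count", "sleep_light_count", "sleep_rem_count",
  "sleep_wake_count", "sleep_awake_count", "sleep_restless_count",
  "sleep_asleep_count"
)

wb_time_vars <- c(
  "still_time",
  "physicalactivity_soft_time", "physicalactivity_moderate_time",
  "physicalactivity_intense_time",
  "heartrate_cardio_time", "heartrate_peak_time",
  "sleep_time", "sleep_deep_time", "sleep_light_time", "sleep_rem_time",
  "sleep_wake_time", "sleep_awake_time", "sleep_restless_time",
  "sleep_asleep_time"
)

wb_hr_vars <- c("heartrate_resting", "heartrate_avg", "heartrate_max")

wb_other_vars <- c(
  "walk_distance", "elevation",
  "still_calories", "total_calories", "physicalactivity_calories",
  "sleep_efficiency"
)

# sleep phase durations that must not exceed total sleep_time
wb_sleep_phase_vars <- c(
  "sleep_deep_time", "sleep_light_time", "sleep_rem_time",
  "sleep_wake_time", "sleep_awake_time", "sleep_restless_time",
  "sleep_asleep_time"
)

#' Measurement variables recognised in daily wearable records
#'
#' Returns the canonical set of per-day measurement column names the package
#' reads, writes and validates: step and distance counters, activity time by
#' intensity (seconds), calorie totals, heart-rate summaries (bpm) and
#' sleep-phase times/counts (seconds/counts).
#'
#' @return A character vector of column names.
#' @export
#' @examples
#' daily_variables()
daily_variables <- function() {
  c(wb_count_vars, wb_time_vars, wb_hr_vars, wb_other_vars)
}

wb_genders <- c("male", "female", "unspecified")
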