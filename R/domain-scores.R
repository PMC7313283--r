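#' Walking-activity score from mean daily steps
#'
#' Classifies habitual walking volume on the standard pedometer bands:
#' sedentary (< 5,000 steps/day) 1, lowly active (5,000-7,499) 2, somewhat
#' active (7,500-9,999) 3, active (10,000-12,499) 4, highly active (12,500
#' or more) 5. Band lower bounds are inclusive ("or more" phrasing), so
#' exactly 12,500 scores 5.
#'
#' @param mean_daily_steps Non-negative mean steps per day (vectorised).
#' @return Integer score(s) 1-5 (`NA` in, `NA` out).
#' @export
#' @examples
#' score_walking(c(3000, 7500, 13000))
score_walking <- function(mean_daily_steps) {
  if (any(!is.na(mean_daily_steps) & mean_daily_steps < 0)) {
    abort("score_walking(): mean_daily_steps must be >= 0")
  }
  out <- findInterval(mean_daily_steps, c(5000, 7500, 10000, 12500)) + 1L
  out[is.na(mean_daily_steps)] <- NA_integer_
  out
}

#' Physical-activity score from weekly minutes
#'
#' Scores weekly exercise volume against aerobic-activity guideline bands.
#' Vigorous minutes count double (75 vigorous is equivalent to 150 moderate),
#' so the banded quantity is the moderate-equivalent total
#' `m = moderate + 2 * vigorous` minutes/week: meets guidelines (m >= 150) 4,
#' certain activity (60-149) 3, low activity (30-59) 2, inactive (< 30) 1.
#'
#' @param weekly_moderate_min Moderate-intensity minutes per week, >= 0.
#' @param weekly_vigorous_min Vigorous-intensity minutes per week, >= 0.
#' @return Integer score(s) 1-4 (`NA` for missing input).
#' @export
#' @examples
#' score_physical_activity(150, 0)  # meets guidelines
#' score_physical_activity(60, 10)  # 80 moderate-equivalent -> 3
score_physical_activity <- function(weekly_moderate_min, weekly_vigorous_min = 0) {
  if (any(!is.na(weekly_moderate_min) & weekly_moderate_min < 0) ||
      any(!is.na(weekly_vigorous_min) & weekly_vigorous_min < 0)) {
    abort("score_physical_activity(): minutes must be >= 0")
  }
  m <- weekly_moderate_min + 2 * weekly_vigorous_min
  out <- findInterval(m, c(30, 60, 150)) + 1L
  out[is.na(m)] <- NA_integer_
  out
}

#' Sleep-duration score from age and mean daily sleep
#'
#' Scores average sleep duration per 24 h against the age-stratified
#' recommendation table ([sleep_norms()]): 2 in the recommended band, 1.75 in
#' the flanking "considered appropriate" (mildly risky) bands, and 1
#' elsewhere (not recommended). The asymmetric 1/1.75/2 scale reflects that
#' chronic under- and over-sleep carry elevated metabolic and cardiac risk,
#' with the steeper penalty on leaving the appropriate range entirely.
#'
#' @param age Age(s) in years; ages beyond the oldest bracket use the
#'   older-adults row.
#' @param mean_daily_sleep_h Mean sleep duration(s), hours in \[0, 24\].
#' @param norms A sleep norm table from [sleep_norms()].
#' @return Score(s) in \{1, 1.75, 2\} (`NA` for missing input).
#' @export
#' @examples
#' score_sleep(30, c(6, 8, 11))  # 1.75, 2, 1
score_sleep <- function(age, mean_daily_sleep_h, norms = sleep_norms()) {
  n <- max(length(age), length(mean_daily_sleep_h))
  age <- rep_len(age, n)
  h <- rep_len(mean_daily_sleep_h, n)
  if (any(!is.na(h) & (h < 0 | h > 24))) {
    abort("score_sleep(): mean_daily_sleep_h must be in [0, 24]")
  }
  if (any(!is.na(age) & age < 0)) {
    abort("score_sleep(): age must be >= 0")
  }
  # age category: lower bound inclusive; above the oldest bracket -> last row
  idx <- findInterval(age, norms$age_min)
  idx[!is.na(idx) & idx < 1] <- 1L
  row <- norms[idx, ]
  score <- dplyr::case_when(
    h >= row$rec_lo & h <= row$rec_hi ~ 2,
    h >= row$app_lo & h <= row$app_hi ~ 1.75,
    TRUE ~ 1
  )
  score[is.na(h) | is.na(age)] <- NA_real_
  score
}

#' Non-exercise VO2max estimate from heart-rate ratio
#'
#' Estimates maximal oxygen uptake from the ratio of maximal to resting heart
#' rate: `VO2max ~ (hr_max / hr_rest) * 15.3` mL/(kg*min). A crude but
#' device-friendly estimator: both rates are routinely reported by wrist-worn
#' trackers with no exercise test required.
#'
#' @param hr_max Maximal heart rate(s), bpm.
#' @param hr_rest Resting heart rate(s), bpm, > 0.
#' @return VO2max estimate(s) in mL/(kg*min).
#' @export
#' @examples
#' estimate_vo2max(hr_max = 190, hr_rest = 60)  # 48.45
estimate_vo2max <- function(hr_max, hr_rest) {
  if (any(!is.na(hr_rest) & hr_rest <= 0)) {
    abort("estimate_vo2max(): hr_rest must be > 0")
  }
  if (any(!is.na(hr_max) & !is.na(hr_rest) & hr_max < hr_rest)) {
    warn("estimate_vo2max(): hr_max below hr_rest; estimate computed anyway")
  }
  (hr_max / hr_rest) * 15.3
}

#' Cardio-respiratory fitness score from VO2max
#'
#' Maps a VO2max estimate to the 1-7 fitness category (1 very low .. 7 elite)
#' for the person's gender and age using a normative cut-point table
#' ([vo2max_norms()]). Ages outside the table's coverage clamp to the nearest
#' bracket; for `gender = "unspecified"` the male and female cut-points are
#' averaged rather than refusing to score.
#'
#' @param vo2max VO2max estimate(s), mL/(kg*min).
#' @param age Age(s) in years.
#' @param gender `"male"`, `"female"` or `"unspecified"` (recycled).
#' @param norms A norm table from [vo2max_norms()].
#' @return Integer score(s) 1-7 (`NA` for missing input).
#' @export
#' @examples
#' score_vo2max(48.45, age = 30, gender = "female")
score_vo2max <- function(vo2max, age, gender = "unspecified",
                         norms = vo2max_norms()) {
  n <- max(length(vo2max), length(age), length(gender))
  vo2max <- rep_len(vo2max, n)
  age <- rep_len(age, n)
  gender <- rep_len(gender, n)
  bad <- setdiff(unique(gender[!is.na(gender)]), wb_genders)
  if (length(bad) > 0) {
    abort(paste0("score_vo2max(): unknown gender value(s): ",
                 paste(bad, collapse = ", ")))
  }
  cuts_for <- function(g, a) {
    sub <- norms[norms$gender == g, ]
    a <- min(max(a, min(sub$age_min)), max(sub$age_max) - 1e-9)
    row <- sub[findInterval(a, sub$age_min), ]
    as.numeric(row[paste0("cut", 1:6)])
  }
  vapply(seq_len(n), function(i) {
    if (is.na(vo2max[i]) || is.na(age[i])) return(NA_integer_)
    g <- if (is.na(gender[i])) "unspecified" else gender[i]
    cuts <- if (g == "unspecified") {
      (cuts_for("male", age[i]) + cuts_for("female", age[i])) / 2
    } else {
      cuts_for(g, age[i])
    }
    findInterval(vo2max[i], cuts) + 1L
  }, integer(1))
}

#' Score domain indices for every person-period
#'
#' The main scoring verb: joins per-period summaries of the daily records
#' (see [aggregate_records()]) with person profiles and applies the four
#' domain scorers, yielding one row per person-period with the walking,
#' physical-activity, sleep and cardio-fitness indices. Periods whose data
#' coverage falls below `min_coverage` keep their row but score `NA`
#' (flagged `complete = FALSE`); no partial or extrapolated scoring is done
#' for them.
#'
#' @param records Validated daily records ([read_daily_records()]).
#' @param profiles Person profiles ([read_profiles()]).
#' @param period `"monthly"` (calendar months) or `"weekly"` (ISO weeks).
#' @param min_coverage Minimum fraction of period days with data; defaults to
#'   4/7 for weekly and 15/31 for monthly periods.
#' @param sleep_norms,vo2max_norms Norm tables; packaged defaults.
#' @param vo2_rest Summary of resting heart rate over the period used in the
#'   VO2max estimate: window `"mean"` (default) or `"min"`.
#' @return A tibble with one row per person-period: period metadata
#'   (`period`, `period_start`, `n_days`, `coverage`, `complete`), the
#'   scoring inputs (`mean_daily_steps`, `weekly_moderate_min`,
#'   `weekly_vigorous_min`, `mean_sleep_h`, `hr_rest`, `hr_max`, `vo2max`)
#'   and the indices `i_walk` (1-5), `i_activity` (1-4), `i_sleep`
#'   (1/1.75/2), `i_cardio` (1-7).
#' @export
score_indices <- function(records, profiles,
                          period = c("monthly", "weekly"),
                          min_coverage = NULL,
                          sleep_norms = wearwell::sleep_norms(),
                          vo2max_norms = wearwell::vo2max_norms(),
                          vo2_rest = c("mean", "min")) {
  period <- rlang::arg_match(period)
  vo2_rest <- rlang::arg_match(vo2_rest)
  profiles <- validate_profiles(profiles)
  inputs <- period_inputs(records, period, min_coverage, vo2_rest)
  df <- dplyr::left_join(inputs, profiles, by = "person_id")
  if (anyNA(df$age)) {
    abort(paste0("score_indices(): no profile for person ",
                 df$person_id[which(is.na(df$age))[1]]))
  }
  df <- dplyr::mutate(df,
    hr_max = dplyr::if_else(
      is.na(.data$hr_max_obs),
      220 - .data$age,
      .data$hr_max_obs
    ),
    vo2max = dplyr::if_else(
      !is.na(.data$hr_rest) & .data$hr_rest > 0,
      (.data$hr_max / .data$hr_rest) * 15.3,
      NA_real_
    ),
    i_walk = score_walking(.data$mean_daily_steps),
    i_activity = score_physical_activity(
      dplyr::coalesce(.data$weekly_moderate_min,
                      ifelse(is.na(.data$weekly_vigorous_min), NA_real_, 0)),
      dplyr::coalesce(.data$weekly_vigorous_min, 0)
    ),
    i_sleep = score_sleep(.data$age, .data$mean_sleep_h, norms = sleep_norms),
    i_cardio = score_vo2max(.data$vo2max, .data$age, .data$gender,
                            norms = vo2max_norms)
  )
  dplyr::select(df,
    "person_id", "period", "period_start", "n_days", "coverage", "complete",
    "age", "gender",
    "mean_daily_steps", "weekly_moderate_min", "weekly_vigorous_min",
    "mean_sleep_h", "hr_rest", "hr_max", "vo2max",
    "i_walk", "i_activity", "i_sleep", "i_cardio"
  )
}
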