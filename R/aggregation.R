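period_label <- function(date, period) {
  if (period == "weekly") {
    sprintf("%d-W%02d", lubridate::isoyear(date), lubridate::isoweek(date))
  } else {
    format(date, "%Y-%m")
  }
}

period_start <- function(date, period) {
  if (period == "weekly") {
    lubridate::floor_date(date, "week", week_start = 1)
  } else {
    lubridate::floor_date(date, "month")
  }
}

period_length <- function(start, period) {
  if (period == "weekly") rep(7L, length(start))
  else as.integer(lubridate::days_in_month(start))
}

default_min_coverage <- function(period) {
  if (period == "weekly") 4 / 7 else 15 / 31
}

#' Aggregate daily records into period summaries
#'
#' Summarises every measurement variable per person and calendar period into
#' its mean per contributing day, total, and the count of days with data.
#' Periods are ISO weeks (Mon-Sun, labelled `2019-W09`) or calendar months
#' (`2019-03`) so period labels are reproducible across runs. `coverage` is
#' the fraction of the period's calendar days with any record; periods below
#' `min_coverage` are kept but flagged `missing = TRUE` and their statistics
#' withheld (`NA`), since a handful of days cannot stand in for a week or a
#' month.
#'
#' @param records Validated daily records.
#' @param period `"monthly"` or `"weekly"`.
#' @param min_coverage Minimum coverage fraction in (0, 1\]; defaults to 4/7
#'   (weekly) or 15/31 (monthly).
#' @return A long tibble: `person_id`, `period`, `period_start`, `variable`,
#'   `mean`, `total`, `n_days`, `coverage`, `missing`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   person_id = "p1",
#'   date = as.Date("2019-03-04") + 0:6,  # one full ISO week
#'   walk_steps = 10000
#' )
#' aggregate_records(rec, period = "weekly")
aggregate_records <- function(records, period = c("monthly", "weekly"),
                              min_coverage = NULL) {
  period <- rlang::arg_match(period)
  min_coverage <- min_coverage %||% default_min_coverage(period)
  if (min_coverage <= 0 || min_coverage > 1) {
    abort("aggregate_records(): min_coverage must be in (0, 1]")
  }
  df <- validate_daily_records(records)
  vars <- intersect(daily_variables(), names(df))
  if (nrow(df) == 0 || length(vars) == 0) {
    return(tibble::tibble(person_id = character(), period = character(),
                          period_start = as.Date(character()),
                          variable = character(), mean = numeric(),
                          total = numeric(), n_days = integer(),
                          coverage = numeric(), missing = logical()))
  }
  # duplicated person-days are rejected by validation, so each day counts once
  df$period <- period_label(df$date, period)
  df$period_start <- period_start(df$date, period)
  long <- tidyr::pivot_longer(
    df[c("person_id", "period", "period_start", "date", vars)],
    dplyr::all_of(vars), names_to = "variable", values_to = "value"
  )
  cov <- df |>
    dplyr::distinct(.data$person_id, .data$period, .data$period_start,
                    .data$date) |>
    dplyr::count(.data$person_id, .data$period, .data$period_start,
                 name = "days_present") |>
    dplyr::mutate(coverage = .data$days_present /
                    period_length(.data$period_start, .env$period))
  out <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$person_id, .data$period, .data$period_start,
                    .data$variable) |>
    dplyr::summarise(mean = mean(.data$value), total = sum(.data$value),
                     n_days = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(cov, by = c("person_id", "period", "period_start")) |>
    dplyr::mutate(missing = .data$coverage < .env$min_coverage) |>
    dplyr::select(-"days_present")
  low <- out$missing
  out$mean[low] <- NA_real_
  out$total[low] <- NA_real_
  dplyr::arrange(out, .data$person_id, .data$period_start, .data$variable)
}

# Wide per-period scoring inputs derived from the daily records: mean daily
# steps, weekly-equivalent activity minutes (mean daily minutes x 7, so a
# short or partially covered period is not under-counted), mean sleep hours,
# and the heart-rate summaries feeding the VO2max estimate.
period_inputs <- function(records, period, min_coverage, vo2_rest) {
  min_coverage <- min_coverage %||% default_min_coverage(period)
  if (min_coverage <= 0 || min_coverage > 1) {
    abort("min_coverage must be in (0, 1]")
  }
  df <- validate_daily_records(records)
  col_or_na <- function(nm) {
    if (nm %in% names(df)) df[[nm]] else rep(NA_real_, nrow(df))
  }
  base <- tibble::tibble(
    person_id = df$person_id,
    date = df$date,
    steps = col_or_na("walk_steps"),
    mod_s = col_or_na("physicalactivity_moderate_time"),
    vig_s = col_or_na("physicalactivity_intense_time"),
    sleep_s = col_or_na("sleep_time"),
    hr_rest = col_or_na("heartrate_resting"),
    hr_max = col_or_na("heartrate_max")
  )
  if (nrow(base) == 0) {
    return(tibble::tibble(person_id = character(), period = character(),
                          period_start = as.Date(character()),
                          n_days = integer(), coverage = numeric(),
                          complete = logical(),
                          mean_daily_steps = numeric(),
                          weekly_moderate_min = numeric(),
                          weekly_vigorous_min = numeric(),
                          mean_sleep_h = numeric(), hr_rest = numeric(),
                          hr_max_obs = numeric()))
  }
  base$period <- period_label(base$date, period)
  base$period_start <- period_start(base$date, period)
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  min_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  rest_fun <- if (vo2_rest == "min") min_na else mean_na
  out <- base |>
    dplyr::group_by(.data$person_id, .data$period, .data$period_start) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$date),
      mean_daily_steps = mean_na(.data$steps),
      weekly_moderate_min = mean_na(.data$mod_s / 60) * 7,
      weekly_vigorous_min = mean_na(.data$vig_s / 60) * 7,
      mean_sleep_h = mean_na(.data$sleep_s / 3600),
      hr_rest = rest_fun(.data$hr_rest),
      hr_max_obs = max_na(.data$hr_max),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      coverage = .data$n_days / period_length(.data$period_start, .env$period),
      complete = .data$coverage >= .env$min_coverage
    )
  stat_cols <- c("mean_daily_steps", "weekly_moderate_min",
                 "weekly_vigorous_min", "mean_sleep_h", "hr_rest",
                 "hr_max_obs")
  out[!out$complete, stat_cols] <- NA_real_
  dplyr::arrange(out, .data$person_id, .data$period_start)
}

#' Standard (z) score against a norm group
#'
#' Places a value relative to a stratum of reference values:
#' `z = (value - center) / spread`. The centre can be the stratum mean
#' (default), median or geometric mean, and the spread the standard deviation
#' (default) or standard error, so the comparison can be matched to the
#' variable's distribution.
#'
#' @param value Value(s) to score (vectorised).
#' @param stratum_values Numeric vector of at least 2 reference values.
#' @param center One of `"mean"`, `"median"`, `"geometric_mean"`.
#' @param spread One of `"sd"`, `"se"`.
#' @return Standard score(s); `NA` when the stratum spread is zero (an
#'   undefined score, not an error).
#' @export
#' @examples
#' standard_score(12, stratum_values = c(8, 10, 12))
standard_score <- function(value, stratum_values,
                           center = c("mean", "median", "geometric_mean"),
                           spread = c("sd", "se")) {
  center <- rlang::arg_match(center)
  spread <- rlang::arg_match(spread)
  x <- stratum_values[!is.na(stratum_values)]
  if (length(x) < 2) {
    abort("standard_score(): stratum needs at least 2 non-missing values")
  }
  ctr <- switch(center,
    mean = mean(x),
    median = stats::median(x),
    geometric_mean = {
      if (any(x <= 0)) {
        abort("standard_score(): geometric mean needs positive stratum values")
      }
      exp(mean(log(x)))
    }
  )
  spr <- switch(spread, sd = stats::sd(x), se = stats::sd(x) / sqrt(length(x)))
  if (!is.finite(spr) || spr == 0) {
    return(rep(NA_real_, length(value)))
  }
  (value - ctr) / spr
}

#' Stratified standard scores for period summaries
#'
#' Adds a `z` column to a long period-summary table ([aggregate_records()]),
#' scoring each person-period mean within a norm group. Default strata are
#' gender crossed with decade-of-age bands; a stratum with fewer than
#' `min_stratum` members falls back to the whole sample for that variable.
#'
#' @param summaries Long summary tibble with `person_id`, `variable`, `mean`.
#' @param profiles Person profiles providing `age` and `gender`.
#' @param center,spread Passed to [standard_score()].
#' @param min_stratum Minimum persons per stratum before falling back.
#' @return `summaries` with `norm_group`, `norm_n` and `z` columns added.
#' @export
add_standard_scores <- function(summaries, profiles,
                                center = "mean", spread = "sd",
                                min_stratum = 5) {
  profiles <- validate_profiles(profiles)
  profiles$norm_group <- paste0(profiles$gender, ":",
                                (profiles$age %/% 10) * 10, "s")
  df <- dplyr::left_join(summaries, profiles[c("person_id", "norm_group")],
                         by = "person_id")
  df |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(g, key) {
      g |>
        dplyr::group_by(.data$norm_group) |>
        dplyr::group_modify(function(s, skey) {
          n_persons <- dplyr::n_distinct(s$person_id)
          ref <- if (n_persons >= min_stratum) s$mean else g$mean
          grp_n <- sum(!is.na(ref))
          s$norm_n <- grp_n
          s$z <- if (grp_n >= 2) {
            standard_score(s$mean, ref, center = center, spread = spread)
          } else {
            NA_real_
          }
          s
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
}

#' Weighted linear aggregation of standard scores
#'
#' Combines normalised indicator values into one composite by a weighted
#' arithmetic mean; weights are renormalised to sum to one, so the result
#' always lies between the smallest and largest input score.
#'
#' @param scores Numeric standard scores (`NA`s dropped with their weights).
#' @param weights Positive weights, recycled; equal by default.
#' @return A single number, or `NA` when no usable score remains.
#' @export
#' @examples
#' linear_aggregate(c(2, 0, 1), weights = c(1, 1, 2))  # 1
linear_aggregate <- function(scores, weights = NULL) {
  if (length(scores) == 0) return(NA_real_)
  weights <- weights %||% rep(1, length(scores))
  if (length(weights) != length(scores)) {
    abort("linear_aggregate(): weights must cover all supplied scores")
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    abort("linear_aggregate(): weights must be finite and > 0")
  }
  keep <- !is.na(scores)
  if (!any(keep)) return(NA_real_)
  weighted.mean(scores[keep], weights[keep])
}
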