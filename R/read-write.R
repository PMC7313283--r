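#' Read daily wearable records from CSV
#'
#' Reads a person-day table of wearable measurements. The file must have a
#' header with `person_id`, `date` and any subset of [daily_variables()].
#' Validation enforces the record invariants: non-negative times and counts,
#' integer counts, heart rates in (0, 250), sleep-phase times no larger than
#' total `sleep_time`, and at most one row per person-day. Empty cells stay
#' missing (`NA`); they are never coerced to zero.
#'
#' @param path Path to a CSV file.
#' @param schema_strict If `TRUE`, columns outside the recognised schema are
#'   an error; otherwise they are dropped with a warning.
#' @return A tibble with one row per person-day, `date` as `Date`, and one
#'   numeric column per measurement present in the file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("person_id,date,walk_steps", "p1,2019-03-02,10250"), f)
#' read_daily_records(f)
read_daily_records <- function(path, schema_strict = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          person_id = readr::col_character(),
                          date = readr::col_character(),
                          .default = readr::col_double()
                        ))
  required <- c("person_id", "date")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(paste0("daily records file lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(names(df), c(required, daily_variables()))
  if (length(unknown) > 0) {
    if (schema_strict) {
      abort(paste0("unknown column(s) in strict mode: ",
                   paste(unknown, collapse = ", ")))
    }
    warn(paste0("ignoring unknown column(s): ", paste(unknown, collapse = ", ")))
    df <- dplyr::select(df, -dplyr::all_of(unknown))
  }
  df$date <- parse_iso_date(df$date, context = "daily records")
  validate_daily_records(df)
}

parse_iso_date <- function(x, context) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad) > 0 || anyNA(x)) {
    row <- if (length(bad) > 0) bad[1] else which(is.na(x))[1]
    abort(sprintf("%s: malformed or missing date in row %d", context, row))
  }
  d
}

#' Validate a tibble of daily wearable records
#'
#' Applies the schema invariants to an in-memory record table (as produced by
#' [read_daily_records()] or [generate_cohort()]). Called automatically by the
#' reader; exported so generated or hand-built cohorts can be checked too.
#'
#' @param records A data frame with `person_id`, `date` and measurement columns.
#' @return The validated records as a tibble, invisibly unchanged.
#' @export
validate_daily_records <- function(records) {
  df <- tibble::as_tibble(records)
  if (any(is.na(df$person_id) | df$person_id == "")) {
    abort(sprintf("empty person_id in row %d",
                  which(is.na(df$person_id) | df$person_id == "")[1]))
  }
  dup <- duplicated(df[c("person_id", "date")])
  if (any(dup)) {
    abort(sprintf("duplicate person-day in row %d (%s, %s)",
                  which(dup)[1], df$person_id[which(dup)[1]],
                  format(df$date[which(dup)[1]])))
  }
  check_nonneg <- intersect(c(wb_count_vars, wb_time_vars, wb_other_vars),
                            names(df))
  for (v in check_nonneg) {
    bad <- which(!is.na(df[[v]]) & df[[v]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative value of %s in row %d", v, bad[1]))
    }
  }
  for (v in intersect(wb_count_vars, names(df))) {
    bad <- which(!is.na(df[[v]]) & df[[v]] != round(df[[v]]))
    if (length(bad) > 0) {
      abort(sprintf("non-integer count %s in row %d", v, bad[1]))
    }
  }
  for (v in intersect(wb_hr_vars, names(df))) {
    bad <- which(!is.na(df[[v]]) & (df[[v]] <= 0 | df[[v]] >= 250))
    if (length(bad) > 0) {
      abort(sprintf("heart rate %s out of (0, 250) in row %d", v, bad[1]))
    }
  }
  if ("sleep_time" %in% names(df)) {
    for (v in intersect(wb_sleep_phase_vars, names(df))) {
      bad <- which(!is.na(df[[v]]) & !is.na(df$sleep_time) &
                     df[[v]] > df$sleep_time)
      if (length(bad) > 0) {
        abort(sprintf("%s exceeds sleep_time in row %d", v, bad[1]))
      }
    }
  }
  df
}

#' Write daily wearable records to CSV
#'
#' Inverse of [read_daily_records()]: a written collection reads back
#' identically on all fields.
#'
#' @param records A validated record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_records <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path, na = "")
  invisible(path)
}

#' Read person profiles from CSV
#'
#' Profiles carry the socio-demographic fields the scoring rules stratify by:
#' `person_id`, `age` (integer years, 0-130) and `gender`
#' (`male`/`female`/`unspecified`; missing becomes `unspecified`).
#'
#' @param path Path to a CSV with columns `person_id,age,gender`.
#' @return A tibble with one row per person.
#' @export
read_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          person_id = readr::col_character(),
                          age = readr::col_double(),
                          gender = readr::col_character()
                        ))
  miss <- setdiff(c("person_id", "age"), names(df))
  if (length(miss) > 0) {
    abort(paste0("profiles file lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"gender" %in% names(df)) df$gender <- "unspecified"
  validate_profiles(df)
}

validate_profiles <- function(profiles) {
  df <- tibble::as_tibble(profiles)
  if (any(is.na(df$person_id) | df$person_id == "")) {
    abort("profiles: empty person_id")
  }
  if (anyDuplicated(df$person_id) > 0) {
    abort("profiles: duplicate person_id")
  }
  if (any(is.na(df$age) | df$age < 0 | df$age > 130)) {
    abort("profiles: age must be in [0, 130]")
  }
  df$gender[is.na(df$gender)] <- "unspecified"
  bad <- setdiff(unique(df$gender), wb_genders)
  if (length(bad) > 0) {
    abort(paste0("profiles: unknown gender value(s): ",
                 paste(bad, collapse = ", ")))
  }
  df
}

#' Read intra-daily measurements from CSV
#'
#' Long-format sub-daily stream (typically one reading per 15 minutes) with
#' columns `person_id,timestamp,variable,value`. Timestamps are timezone-naive
#' local time at minute resolution or coarser.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `person_id`, `timestamp` (`POSIXct`), `variable`,
#'   `value`.
#' @export
read_intraday_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          person_id = readr::col_character(),
                          timestamp = readr::col_character(),
                          variable = readr::col_character(),
                          value = readr::col_double()
                        ))
  miss <- setdiff(c("person_id", "timestamp", "variable", "value"), names(df))
  if (length(miss) > 0) {
    abort(paste0("intraday file lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) {
    abort(sprintf("intraday: malformed timestamp in row %d", which(is.na(ts))[1]))
  }
  if (any(!is.na(df$value) & df$value < 0)) {
    abort(sprintf("intraday: negative value in row %d",
                  which(!is.na(df$value) & df$value < 0)[1]))
  }
  df$timestamp <- ts
  df
}
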