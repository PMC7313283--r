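# Programmatic equivalents of the command-line subcommands; the shipped
# Rscript (inst/cli/wearwell.R) is a thin flag-parser over these.

#' Run the scoring pipeline on files
#'
#' Reads daily records and profiles, scores the four domain indices per
#' person-period, composes the well-being indicator and writes
#' `indices.csv` and `composites.csv` into `out_dir`. A run summary
#' (persons, periods, uncomposed periods) is reported via `inform()`.
#'
#' @param records_path,profiles_path Input CSVs.
#' @param out_dir Output directory (created if needed).
#' @param period `"monthly"` or `"weekly"`.
#' @param min_coverage Optional coverage threshold (see [score_indices()]).
#' @param weights_path Optional YAML weights file; packaged defaults if
#'   `NULL`.
#' @param sleep_norms_path,vo2max_norms_path Optional alternative norm
#'   tables.
#' @param root_mode Composite root mode (see [compose_wb_value()]).
#' @return Invisibly, the composed series tibble.
#' @export
run_score <- function(records_path, profiles_path, out_dir,
                      period = c("monthly", "weekly"),
                      min_coverage = NULL,
                      weights_path = NULL,
                      sleep_norms_path = NULL,
                      vo2max_norms_path = NULL,
                      root_mode = c("fixed_4", "weight_sum")) {
  period <- rlang::arg_match(period)
  root_mode <- rlang::arg_match(root_mode)
  records <- read_daily_records(records_path)
  profiles <- read_profiles(profiles_path)
  weights <- if (is.null(weights_path)) default_weights() else
    read_weights(weights_path)
  idx <- score_indices(records, profiles, period = period,
                       min_coverage = min_coverage,
                       sleep_norms = sleep_norms(sleep_norms_path),
                       vo2max_norms = vo2max_norms(vo2max_norms_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(idx, file.path(out_dir, "indices.csv"), na = "")
  if (nrow(idx) == 0) {
    warn("run_score(): no scoreable person-periods in input")
    series <- compose_wb(idx, weights = weights, root_mode = root_mode)
  } else {
    series <- composite_series(idx, weights = weights, root_mode = root_mode)
  }
  write_composites(series, file.path(out_dir, "composites.csv"))
  inform(sprintf(
    "scored %d person(s), %d period(s); %d period(s) without a composite",
    dplyr::n_distinct(idx$person_id), nrow(idx), sum(!series$composed)
  ))
  invisible(series)
}

#' Run the validation pipeline on files
#'
#' Reads a composite table and questionnaire responses, scores the
#' instrument, pairs responses with composite periods and writes the pairs
#' CSV, scatter plot and JSON correlation report via [scatter_export()].
#'
#' @param composites_path Composite CSV from [run_score()].
#' @param responses_path Questionnaire response CSV.
#' @param instrument `"ess"` or `"eq5"`.
#' @param out_dir Output directory.
#' @param window_policy,horizon_days See [pair_responses()].
#' @param eq5_polarity See [read_responses()].
#' @return Invisibly, the `wb_correlation` result.
#' @export
run_validate <- function(composites_path, responses_path,
                         instrument = c("ess", "eq5"), out_dir,
                         window_policy = c("nearest_period", "same_month"),
                         horizon_days = 45,
                         eq5_polarity = c("best_high", "worst_high")) {
  instrument <- rlang::arg_match(instrument)
  composites <- read_composites(composites_path)
  resp <- read_responses(responses_path, instrument = instrument,
                         eq5_polarity = eq5_polarity)
  scored <- if (instrument == "ess") score_ess(resp) else score_eq5(resp)
  pairs <- pair_responses(scored, composites, window_policy = window_policy,
                          horizon_days = horizon_days)
  res <- suppressWarnings(correlate_pairs(pairs))
  if (nrow(pairs) > 0) {
    scatter_export(pairs, out_dir, name = paste0("validation_", instrument))
  } else {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(instrument = instrument, n = 0L, r = NA, p_value = NA,
           policy = window_policy[1]),
      file.path(out_dir, paste0("validation_", instrument, "_report.json")),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    warn("run_validate(): no validation pairs; correlation undefined")
  }
  invisible(res)
}

#' Generate and write a synthetic cohort
#'
#' @param config A [cohort_config()] (or a plain list of its arguments).
#' @param out_dir Output directory for the four CSVs ([write_cohort()]).
#' @return Invisibly, the generated cohort list.
#' @export
run_simulate <- function(config = cohort_config(), out_dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, out_dir)
  inform(sprintf("simulated %d person(s), %d daily record(s)",
                 nrow(cohort$profiles), nrow(cohort$daily)))
  invisible(cohort)
}
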