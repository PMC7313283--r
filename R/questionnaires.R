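#' Read questionnaire responses from CSV
#'
#' Loads responses for one of the two supported instruments from a CSV with
#' `person_id`, `timestamp` and either the 15 item columns `q1..q15` (each
#' rated 0 strongly disagree .. 4 strongly agree) for the well-being survey,
#' or the five dimension columns `d1..d5` plus `hsa` (health-state
#' assessment, 0-100) for the five-dimension health-status instrument. An
#' optional `instrument` column restricts rows to the requested instrument.
#'
#' Dimension polarity for the health-status instrument: this package codes
#' dimensions 1 = worst .. 5 = best. Files using the conventional level
#' coding (1 = no problems .. 5 = extreme problems) can be ingested with
#' `eq5_polarity = "worst_high"`, which inverts ratings as `6 - rating`.
#'
#' @param path CSV path.
#' @param instrument `"ess"` (15-item) or `"eq5"` (5-dimension + hsa).
#' @param eq5_polarity `"best_high"` (package coding, default) or
#'   `"worst_high"` (invert on read).
#' @return A validated tibble of responses with `timestamp` parsed to `Date`.
#' @export
read_responses <- function(path, instrument = c("ess", "eq5"),
                           eq5_polarity = c("best_high", "worst_high")) {
  instrument <- rlang::arg_match(instrument)
  eq5_polarity <- rlang::arg_match(eq5_polarity)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  spec <- readr::cols(person_id = readr::col_character(),
                      timestamp = readr::col_character(),
                      .default = readr::col_double())
  if ("instrument" %in% header) {
    spec$cols$instrument <- readr::col_character()
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = spec)
  if ("instrument" %in% names(df)) {
    df <- df[!is.na(df$instrument) & df$instrument == instrument, ]
    df$instrument <- NULL
  }
  need <- c("person_id", "timestamp",
            if (instrument == "ess") paste0("q", 1:15) else
              c(paste0("d", 1:5), "hsa"))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("responses file lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  df <- df[need]
  df$timestamp <- parse_iso_date(substr(df$timestamp, 1, 10), "responses")
  if (instrument == "eq5" && eq5_polarity == "worst_high") {
    for (v in paste0("d", 1:5)) df[[v]] <- 6 - df[[v]]
  }
  if (instrument == "ess") validate_ess(df) else validate_eq5(df)
}

validate_ess <- function(df) {
  items <- paste0("q", 1:15)
  for (v in items) {
    bad <- which(is.na(df[[v]]) | df[[v]] < 0 | df[[v]] > 4 |
                   df[[v]] != round(df[[v]]))
    if (length(bad) > 0) {
      abort(sprintf("ESS item %s invalid in row %d (must be integer 0-4)",
                    v, bad[1]))
    }
  }
  tibble::as_tibble(df)
}

validate_eq5 <- function(df) {
  for (v in paste0("d", 1:5)) {
    bad <- which(is.na(df[[v]]) | df[[v]] < 1 | df[[v]] > 5 |
                   df[[v]] != round(df[[v]]))
    if (length(bad) > 0) {
      abort(sprintf("EQ5 dimension %s invalid in row %d (must be integer 1-5)",
                    v, bad[1]))
    }
  }
  bad <- which(is.na(df$hsa) | df$hsa < 0 | df$hsa > 100)
  if (length(bad) > 0) {
    abort(sprintf("EQ5 hsa invalid in row %d (must be in [0, 100])", bad[1]))
  }
  tibble::as_tibble(df)
}

#' Cumulative score of the 15-item well-being questionnaire
#'
#' The cumulative score is the plain sum of the 15 item ratings, ranging from
#' 0 (worst well-being) to 60 (optimum). Items are positional (`q1..q15`);
#' any reverse-keyed wording must be resolved before ingestion since the
#' scale is uniform here.
#'
#' @param responses A validated response tibble ([read_responses()]) or any
#'   data frame with `q1..q15`.
#' @return The input with an `ess_score` column (integer 0-60) appended.
#' @export
#' @examples
#' r <- tibble::tibble(person_id = "p1", timestamp = as.Date("2019-06-01"),
#'                     !!!stats::setNames(as.list(rep(3, 15)), paste0("q", 1:15)))
#' score_ess(r)$ess_score  # 45
score_ess <- function(responses) {
  df <- validate_ess(responses)
  df$ess_score <- as.integer(rowSums(df[paste0("q", 1:15)]))
  df
}

#' Map a 0-100 health-state assessment onto the 1-5 dimension scale
#'
#' Affine rescaling `1 + 4 * hsa / 100`, so the overall health-state rating
#' contributes to the cumulative score on the same footing as one dimension.
#'
#' @param hsa Health-state assessment(s) in \[0, 100\].
#' @return Value(s) in \[1, 5\].
#' @export
#' @examples
#' map_hsa(c(0, 50, 100))  # 1 3 5
map_hsa <- function(hsa) {
  if (any(!is.na(hsa) & (hsa < 0 | hsa > 100))) {
    abort("map_hsa(): hsa must be in [0, 100]")
  }
  1 + 4 * hsa / 100
}

#' Cumulative score of the five-dimension health-status questionnaire
#'
#' Sum of the five dimension ratings (each 1 worst .. 5 best) plus the mapped
#' health-state assessment ([map_hsa()]), giving a cumulative score from 6 to
#' 30. The mapped term is kept fractional; no rounding is applied before
#' summation.
#'
#' @param responses A validated response tibble or data frame with `d1..d5`
#'   and `hsa`.
#' @return The input with an `eq5_score` column (6-30) appended.
#' @export
#' @examples
#' r <- tibble::tibble(person_id = "p1", timestamp = as.Date("2019-06-01"),
#'                     d1 = 3, d2 = 3, d3 = 3, d4 = 3, d5 = 3, hsa = 50)
#' score_eq5(r)$eq5_score  # 18
score_eq5 <- function(responses) {
  df <- validate_eq5(responses)
  df$eq5_score <- rowSums(df[paste0("d", 1:5)]) + map_hsa(df$hsa)
  df
}
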