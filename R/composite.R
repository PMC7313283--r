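#' Composite physical well-being value from the four domain indices
#'
#' The composite indicator is the weighted geometric mean of the walking,
#' physical-activity, sleep and cardio-fitness indices:
#' \deqn{WB_{ph} = (I_w^{w_w} \cdot I_p^{w_p} \cdot I_s^{w_s} \cdot
#'   I_c^{w_c})^{1/r}}
#' with `r = 4` (`root_mode = "fixed_4"`, the literal form) or `r` equal to
#' the weight sum (`"weight_sum"`, the normalised weighted power mean). The
#' default weights sum to exactly 4, so the two modes coincide there. The
#' geometric form is deliberately sensitive to a low value in any single
#' domain and combines indices on different scales without prior
#' normalisation.
#'
#' @param i_walk,i_activity,i_sleep,i_cardio Domain index values, all > 0
#'   (vectorised; `NA` propagates).
#' @param weights Named weight vector as from [default_weights()].
#' @param root_mode `"fixed_4"` or `"weight_sum"`.
#' @return Composite value(s) `wb_ph`.
#' @export
#' @examples
#' compose_wb_value(5, 4, 1.75, 6)
compose_wb_value <- function(i_walk, i_activity, i_sleep, i_cardio,
                             weights = default_weights(),
                             root_mode = c("fixed_4", "weight_sum")) {
  root_mode <- rlang::arg_match(root_mode)
  w <- check_weights(weights)
  idx <- vctrs_recycle(i_walk, i_activity, i_sleep, i_cardio)
  bad <- !is.na(idx$a) & !is.na(idx$b) & !is.na(idx$c) & !is.na(idx$d) &
    (idx$a <= 0 | idx$b <= 0 | idx$c <= 0 | idx$d <= 0)
  if (any(bad)) {
    abort("compose_wb_value(): all indices must be > 0")
  }
  r <- if (root_mode == "fixed_4") 4 else sum(w)
  exp((w[["walking"]] * log(idx$a) + w[["activity"]] * log(idx$b) +
         w[["sleep"]] * log(idx$c) + w[["cardio"]] * log(idx$d)) / r)
}

vctrs_recycle <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  list(a = rep_len(a, n), b = rep_len(b, n), c = rep_len(c, n),
       d = rep_len(d, n))
}

check_weights <- function(weights) {
  keys <- c("walking", "activity", "sleep", "cardio")
  if (is.null(names(weights)) || !all(keys %in% names(weights))) {
    abort("weights must be named walking, activity, sleep, cardio")
  }
  w <- as.numeric(weights[keys])
  names(w) <- keys
  if (any(!is.finite(w) | w <= 0)) {
    abort("composite weights must all be finite and > 0")
  }
  w
}

#' Compose the well-being indicator for a table of domain indices
#'
#' Adds the composite `wb_ph` column to a [score_indices()] result. No
#' partial composition is done: a period missing any one of the four indices
#' gets `wb_ph = NA` and `composed = FALSE`, because silently dropping a
#' factor from a geometric mean would bias the composite upward exactly when
#' a domain is doing badly.
#'
#' @param indices A tibble with columns `i_walk`, `i_activity`, `i_sleep`,
#'   `i_cardio` (typically from [score_indices()]).
#' @param weights,root_mode See [compose_wb_value()].
#' @return `indices` with `wb_ph` and `composed` columns appended; weights
#'   and root mode are recorded as attributes `wb_weights` / `wb_root_mode`.
#' @export
compose_wb <- function(indices, weights = default_weights(),
                       root_mode = c("fixed_4", "weight_sum")) {
  root_mode <- rlang::arg_match(root_mode)
  w <- check_weights(weights)
  need <- c("i_walk", "i_activity", "i_sleep", "i_cardio")
  miss <- setdiff(need, names(indices))
  if (length(miss) > 0) {
    abort(paste0("compose_wb(): missing index column(s): ",
                 paste(miss, collapse = ", ")))
  }
  df <- tibble::as_tibble(indices)
  complete <- !Reduce(`|`, lapply(df[need], is.na))
  df$wb_ph <- NA_real_
  if (any(complete)) {
    df$wb_ph[complete] <- compose_wb_value(
      df$i_walk[complete], df$i_activity[complete],
      df$i_sleep[complete], df$i_cardio[complete],
      weights = w, root_mode = root_mode
    )
  }
  df$composed <- complete
  attr(df, "wb_weights") <- w
  attr(df, "wb_root_mode") <- root_mode
  df
}

#' Chronological composite time series
#'
#' Orders composed person-periods chronologically within person, keeping
#' periods that could not be composed as explicit `NA` gaps rather than
#' silently shortening the series.
#'
#' @param indices Domain-index tibble ([score_indices()] output).
#' @param weights,root_mode See [compose_wb_value()].
#' @return A tibble ordered by `person_id`, `period_start` with `wb_ph` and
#'   `composed`.
#' @export
composite_series <- function(indices, weights = default_weights(),
                             root_mode = c("fixed_4", "weight_sum")) {
  df <- compose_wb(indices, weights = weights, root_mode = root_mode)
  if (!"period_start" %in% names(df)) {
    abort("composite_series(): indices need a period_start column")
  }
  if (any(duplicated(df[c("person_id", "period")]))) {
    abort("composite_series(): periods must be unique per person")
  }
  dplyr::arrange(df, .data$person_id, .data$period_start)
}

#' Write a composite table to CSV
#'
#' Exports person-period indices and composite values together with the
#' weight vector and root mode used, so a written file is self-describing.
#'
#' @param composites Output of [compose_wb()] / [composite_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_composites <- function(composites, path) {
  w <- attr(composites, "wb_weights") %||% default_weights()
  rm <- attr(composites, "wb_root_mode") %||% "fixed_4"
  df <- tibble::as_tibble(composites)
  df$weight_walking <- w[["walking"]]
  df$weight_activity <- w[["activity"]]
  df$weight_sleep <- w[["sleep"]]
  df$weight_cardio <- w[["cardio"]]
  df$root_mode <- rm
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read a composite table written by [write_composites()]
#'
#' @param path CSV path.
#' @return A tibble with the composite columns; `period_start` parsed as
#'   `Date`, weights restored to the `wb_weights` attribute.
#' @export
read_composites <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("person_id", "period", "wb_ph") %in% names(df))) {
    abort("composites file needs person_id, period and wb_ph columns")
  }
  if ("period_start" %in% names(df)) {
    df$period_start <- as.Date(df$period_start)
  }
  wcols <- paste0("weight_", c("walking", "activity", "sleep", "cardio"))
  if (all(wcols %in% names(df)) && nrow(df) > 0) {
    w <- as.numeric(df[1, wcols])
    names(w) <- c("walking", "activity", "sleep", "cardio")
    attr(df, "wb_weights") <- w
  }
  df
}

#' Plot composite well-being time series
#'
#' One line per person over period start dates; uncomposed periods appear as
#' gaps.
#'
#' @param composites Output of [composite_series()].
#' @return A ggplot object.
#' @export
plot_wb_series <- function(composites) {
  df <- dplyr::filter(tibble::as_tibble(composites), .data$composed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period_start, y = .data$wb_ph,
                                   group = .data$person_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "period", y = "composite physical well-being",
                  title = "Composite well-being over time") +
    ggplot2::theme_minimal()
}
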