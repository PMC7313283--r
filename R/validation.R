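#' Pair questionnaire responses with composite periods
#'
#' Matches each scored questionnaire response to a composite value of the
#' same person: either the composite period whose midpoint is nearest to the
#' response date within `horizon_days` (`"nearest_period"`, default) or the
#' composite of the response's calendar month (`"same_month"`). Repeated
#' responses by the same person each form their own pair; responses with no
#' composable period in reach are dropped, with the dropped count reported
#' via the `dropped` attribute and a message.
#'
#' @param responses A scored response tibble ([score_ess()] / [score_eq5()]);
#'   the score column (`ess_score` or `eq5_score`) is detected automatically.
#' @param composites A composed period table ([composite_series()] or
#'   [read_composites()]).
#' @param window_policy `"nearest_period"` or `"same_month"`.
#' @param horizon_days Matching horizon for `"nearest_period"`, in days.
#' @return A tibble of validation pairs: `person_id`, `timestamp`, `score`,
#'   `instrument`, `period`, `wb_ph`, `window`; attribute `dropped` counts
#'   unmatched responses.
#' @export
pair_responses <- function(responses, composites,
                           window_policy = c("nearest_period", "same_month"),
                           horizon_days = 45) {
  window_policy <- rlang::arg_match(window_policy)
  score_col <- intersect(c("ess_score", "eq5_score"), names(responses))
  if (length(score_col) == 0) {
    abort("pair_responses(): responses must carry ess_score or eq5_score")
  }
  score_col <- score_col[1]
  instrument <- sub("_score$", "", score_col)
  comp <- tibble::as_tibble(composites)
  comp <- comp[!is.na(comp$wb_ph), ]
  resp <- tibble::as_tibble(responses)
  if (nrow(resp) == 0 || nrow(comp) == 0) {
    out <- tibble::tibble(person_id = character(),
                          timestamp = as.Date(character()),
                          score = numeric(), instrument = character(),
                          period = character(), wb_ph = numeric(),
                          window = character())
    attr(out, "dropped") <- nrow(resp)
    return(out)
  }
  plen <- as.numeric(vapply(seq_len(nrow(comp)), function(i) {
    if (grepl("W", comp$period[i], fixed = TRUE)) 7 else
      as.integer(lubridate::days_in_month(comp$period_start[i]))
  }, numeric(1)))
  comp$mid <- comp$period_start + plen / 2
  comp$month <- format(comp$period_start, "%Y-%m")
  matched <- purrr::map_dfr(seq_len(nrow(resp)), function(i) {
    cand <- comp[comp$person_id == resp$person_id[i], ]
    if (nrow(cand) == 0) return(NULL)
    if (window_policy == "same_month") {
      cand <- cand[cand$month == format(resp$timestamp[i], "%Y-%m"), ]
      if (nrow(cand) == 0) return(NULL)
      hit <- cand[1, ]
    } else {
      dist <- abs(as.numeric(resp$timestamp[i] - cand$mid))
      if (min(dist) > horizon_days) return(NULL)
      hit <- cand[which.min(dist), ]
    }
    tibble::tibble(person_id = resp$person_id[i],
                   timestamp = resp$timestamp[i],
                   score = as.numeric(resp[[score_col]][i]),
                   instrument = instrument,
                   period = hit$period, wb_ph = hit$wb_ph,
                   window = window_policy)
  })
  dropped <- nrow(resp) - nrow(matched)
  if (dropped > 0) {
    inform(sprintf("pair_responses(): %d response(s) had no composite within reach and were dropped", dropped))
  }
  attr(matched, "dropped") <- dropped
  class(matched) <- c("wb_validation_pairs", class(matched))
  matched
}

#' Correlate composite well-being with questionnaire scores
#'
#' Pearson (default) or Spearman correlation between the composite values and
#' questionnaire scores of a pair table, with the two-sided p-value from the
#' t distribution on n - 2 degrees of freedom. With fewer than 3 pairs or
#' degenerate variance on either side the result is returned as undefined
#' (`r = NA`) rather than raising.
#'
#' @param pairs Output of [pair_responses()].
#' @param method `"pearson"` or `"spearman"`.
#' @return A `wb_correlation` object: list with `r`, `p_value`, `n`,
#'   `method`, `instrument`, `window`. Has [tidy()] and [glance()] methods.
#' @export
correlate_pairs <- function(pairs, method = c("pearson", "spearman")) {
  method <- rlang::arg_match(method)
  df <- tibble::as_tibble(pairs)
  df <- df[is.finite(df$wb_ph) & is.finite(df$score), ]
  instrument <- if (nrow(df) > 0) df$instrument[1] else NA_character_
  window <- if (nrow(df) > 0) df$window[1] else NA_character_
  res <- list(r = NA_real_, p_value = NA_real_, n = nrow(df),
              method = method, instrument = instrument, window = window)
  if (nrow(df) >= 3 && stats::sd(df$wb_ph) > 0 && stats::sd(df$score) > 0) {
    ct <- stats::cor.test(df$wb_ph, df$score, method = method,
                          alternative = "two.sided", exact = FALSE)
    res$r <- unname(ct$estimate)
    res$p_value <- ct$p.value
  } else {
    warn("correlate_pairs(): fewer than 3 usable pairs or degenerate variance; correlation undefined")
  }
  structure(res, class = "wb_correlation")
}

#' @export
print.wb_correlation <- function(x, ...) {
  cat(sprintf("Composite vs %s correlation (%s)\n",
              x$instrument %||% "?", x$method))
  if (is.na(x$r)) {
    cat(sprintf("  undefined (n = %d)\n", x$n))
  } else {
    cat(sprintf("  r = %.3f, p = %.3g, n = %d\n", x$r, x$p_value, x$n))
  }
  invisible(x)
}

#' Tidy a composite-vs-questionnaire correlation
#'
#' @param x A `wb_correlation` object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `instrument`, `method`,
#'   `estimate`, `p.value`, `n`, `window`. `glance()`: the same one-row
#'   summary.
#' @method tidy wb_correlation
#' @export
tidy.wb_correlation <- function(x, ...) {
  tibble::tibble(instrument = x$instrument, method = x$method,
                 estimate = x$r, p.value = x$p_value, n = x$n,
                 window = x$window)
}

#' @rdname tidy.wb_correlation
#' @method glance wb_correlation
#' @export
glance.wb_correlation <- function(x, ...) tidy(x)

#' Scatter plot of validation pairs
#'
#' @param object A pair tibble from [pair_responses()].
#' @param ... Unused.
#' @return A ggplot: questionnaire score vs composite value with a linear
#'   trend.
#' @method autoplot wb_validation_pairs
#' @export
autoplot.wb_validation_pairs <- function(object, ...) {
  plot_validation(object)
}

#' @rdname autoplot.wb_validation_pairs
#' @param pairs A pair tibble from [pair_responses()].
#' @export
plot_validation <- function(pairs) {
  df <- tibble::as_tibble(pairs)
  lab <- if (nrow(df) > 0 && df$instrument[1] == "eq5") {
    "cumulative EQ5 score"
  } else {
    "cumulative ESS score"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$wb_ph)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::labs(x = lab, y = "composite physical well-being",
                  title = "Composite well-being vs questionnaire score") +
    ggplot2::theme_minimal()
}

#' Export validation pairs as CSV and scatter plot
#'
#' Writes the pair table (`<name>_pairs.csv`), a scatter plot
#' (`<name>_scatter.png`) and a small JSON report with the correlation
#' summary (`<name>_report.json`) into `dir`. With no pairs, nothing is
#' written and a warning is raised.
#'
#' @param pairs Output of [pair_responses()].
#' @param dir Output directory (created if needed).
#' @param name Basename stem for the three files.
#' @return Invisibly, a named list of written paths (empty on no-op).
#' @export
scatter_export <- function(pairs, dir, name = "validation") {
  df <- tibble::as_tibble(pairs)
  if (nrow(df) == 0) {
    warn("scatter_export(): no pairs to export")
    return(invisible(list()))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, "_pairs.csv"))
  png_path <- file.path(dir, paste0(name, "_scatter.png"))
  json <- file.path(dir, paste0(name, "_report.json"))
  readr::write_csv(df, csv)
  p <- plot_validation(df)
  grDevices::png(png_path, width = 1200, height = 900, res = 150)
  print(p)
  grDevices::dev.off()
  res <- suppressWarnings(correlate_pairs(df))
  jsonlite::write_json(
    list(instrument = res$instrument, n = res$n, r = res$r,
         p_value = res$p_value, policy = res$window),
    json, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(list(pairs = csv, scatter = png_path, report = json))
}
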