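make_composites <- function(persons, months = c("2019-01", "2019-02"),
                            wb = NULL) {
  grid <- tidyr::crossing(person_id = persons, period = months)
  grid$period_start <- as.Date(paste0(grid$period, "-01"))
  grid$wb_ph <- wb %||% seq(1, 4, length.out = nrow(grid))
  grid$composed <- TRUE
  grid
}
`%||%` <- function(x, y) if (is.null(x)) y else x

scored_resp <- function(person, date, score) {
  tibble::tibble(person_id = person, timestamp = as.Date(date),
                 ess_score = score)
}

test_that("responses pair with the same-month composite when asked", {
  comp <- make_composites("p1")
  resp <- scored_resp("p1", "2019-02-15", 40)
  pairs <- pair_responses(resp, comp, window_policy = "same_month")
  expect_equal(pairs$period, "2019-02")
  expect_equal(pairs$wb_ph, comp$wb_ph[comp$period == "2019-02"])
  expect_equal(pairs$score, 40)
})

test_that("nearest-period pairing respects the horizon and drops the rest", {
  comp <- make_composites("p1", months = "2019-01")
  near <- scored_resp("p1", "2019-02-10", 30)   # ~25 d from mid-January
  far <- scored_resp("p1", "2019-06-01", 30)
  p1 <- pair_responses(near, comp)
  expect_equal(nrow(p1), 1)
  expect_equal(attr(p1, "dropped"), 0)
  expect_message(p2 <- pair_responses(far, comp), "dropped")
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "dropped"), 1)
})

test_that("repeated responses each form their own pair", {
  comp <- make_composites("p1")
  resp <- dplyr::bind_rows(scored_resp("p1", "2019-01-10", 20),
                           scored_resp("p1", "2019-02-10", 50))
  pairs <- pair_responses(resp, comp, window_policy = "same_month")
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$period, c("2019-01", "2019-02"))
})

test_that("correlation matches the textbook formula and handles extremes", {
  set.seed(701)
  x <- rnorm(10)
  pairs <- tibble::tibble(person_id = sprintf("p%d", 1:10),
                          timestamp = as.Date("2019-03-01"),
                          score = 3 * x + rnorm(10), instrument = "ess",
                          period = "2019-03", wb_ph = x, window = "same_month")
  res <- correlate_pairs(pairs)
  r_oracle <- sum((x - mean(x)) * (pairs$score - mean(pairs$score))) /
    ((10 - 1) * sd(x) * sd(pairs$score))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  t_stat <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_stat), df = 8),
               tolerance = 1e-12)

  line <- dplyr::mutate(pairs, score = 2 * wb_ph + 1)
  expect_equal(correlate_pairs(line)$r, 1)
  neg <- dplyr::mutate(pairs, score = -wb_ph)
  expect_equal(correlate_pairs(neg)$r, -1)
})

test_that("correlation is symmetric and invariant to positive affine maps", {
  set.seed(702)
  pairs <- tibble::tibble(person_id = sprintf("p%d", 1:20),
                          timestamp = as.Date("2019-03-01"),
                          score = rnorm(20, 30, 8), instrument = "eq5",
                          period = "2019-03", wb_ph = rnorm(20, 2.5, 0.5),
                          window = "same_month")
  r0 <- correlate_pairs(pairs)$r
  swapped <- dplyr::mutate(pairs, tmp = score, score = wb_ph, wb_ph = tmp)
  expect_equal(correlate_pairs(swapped)$r, r0, tolerance = 1e-12)
  scaled <- dplyr::mutate(pairs, score = 0.2 * score + 7,
                          wb_ph = 3 * wb_ph - 1)
  expect_equal(correlate_pairs(scaled)$r, r0, tolerance = 1e-12)
})

test_that("degenerate inputs give an undefined correlation, not an error", {
  few <- tibble::tibble(person_id = c("a", "b"),
                        timestamp = as.Date("2019-03-01"),
                        score = c(1, 2), instrument = "ess",
                        period = "2019-03", wb_ph = c(1, 2),
                        window = "same_month")
  expect_warning(res <- correlate_pairs(few), "undefined")
  expect_true(is.na(res$r))
  expect_true(is.na(tidy(res)$estimate))
})

test_that("tidy and glance return one-row summaries", {
  set.seed(703)
  pairs <- tibble::tibble(person_id = sprintf("p%d", 1:8),
                          timestamp = as.Date("2019-03-01"),
                          score = rnorm(8), instrument = "eq5",
                          period = "2019-03", wb_ph = rnorm(8),
                          window = "nearest_period")
  res <- correlate_pairs(pairs)
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_named(td, c("instrument", "method", "estimate", "p.value", "n",
                     "window"))
  expect_equal(glance(res), td)
})

test_that("scatter export writes pairs CSV, plot and JSON report", {
  set.seed(704)
  pairs <- tibble::tibble(person_id = sprintf("p%d", 1:5),
                          timestamp = as.Date("2019-03-01"),
                          score = rnorm(5, 40, 5), instrument = "ess",
                          period = "2019-03", wb_ph = runif(5, 1, 4),
                          window = "same_month")
  dir <- withr::local_tempdir()
  out <- suppressWarnings(scatter_export(pairs, dir))
  expect_true(file.exists(out$pairs))
  expect_true(file.exists(out$scatter))
  expect_equal(nrow(readr::read_csv(out$pairs, show_col_types = FALSE)), 5)
  rep <- jsonlite::read_json(out$report)
  expect_equal(rep$n, 5)
  # duplicated pairs are kept, not deduplicated
  out2 <- suppressWarnings(scatter_export(pairs[c(1, 1), ], dir, name = "dup"))
  expect_equal(nrow(readr::read_csv(out2$pairs, show_col_types = FALSE)), 2)
  expect_warning(scatter_export(pairs[0, ], dir), "no pairs")
})

test_that("validation plot builds from a pair table", {
  pairs <- tibble::tibble(person_id = c("a", "b", "c"),
                          timestamp = as.Date("2019-03-01"),
                          score = c(10, 20, 30), instrument = "eq5",
                          period = "2019-03", wb_ph = c(1, 2, 3),
                          window = "same_month")
  p <- plot_validation(pairs)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(structure(pairs,
                                     class = c("wb_validation_pairs",
                                               class(pairs)))), "ggplot")
})
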