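# Independent interval-membership oracles built directly from the printed
# band lists, used to cross-check the vectorised scorers. Deliberately
# written as explicit per-band scans, not via findInterval.

oracle_walk <- function(steps) {
  bands <- list(list(lo = 12500, hi = Inf, score = 5L),
                list(lo = 10000, hi = 12500, score = 4L),
                list(lo = 7500, hi = 10000, score = 3L),
                list(lo = 5000, hi = 7500, score = 2L),
                list(lo = 0, hi = 5000, score = 1L))
  vapply(steps, function(s) {
    for (b in bands) if (s >= b$lo && s < b$hi) return(b$score)
    NA_integer_
  }, integer(1))
}

oracle_activity <- function(mod, vig) {
  # moderate-equivalent minutes; vigorous counts double (75 vig = 150 mod)
  bands <- list(list(lo = 150, hi = Inf, score = 4L),
                list(lo = 60, hi = 150, score = 3L),
                list(lo = 30, hi = 60, score = 2L),
                list(lo = 0, hi = 30, score = 1L))
  m <- mod + 2 * vig
  vapply(m, function(x) {
    for (b in bands) if (x >= b$lo && x < b$hi) return(b$score)
    NA_integer_
  }, integer(1))
}

# age category rows of the sleep recommendation table, completed by
# continuity: appropriate = [app_lo, rec_lo) U (rec_hi, app_hi]
sleep_rows <- list(
  list(age = c(0, 1 / 3), app_lo = 11, rec = c(14, 17), app_hi = 19),
  list(age = c(1 / 3, 1), app_lo = 10, rec = c(12, 15), app_hi = 18),
  list(age = c(1, 3), app_lo = 9, rec = c(11, 14), app_hi = 16),
  list(age = c(3, 6), app_lo = 8, rec = c(10, 13), app_hi = 14),
  list(age = c(6, 14), app_lo = 7, rec = c(9, 11), app_hi = 12),
  list(age = c(14, 18), app_lo = 7, rec = c(8, 10), app_hi = 11),
  list(age = c(18, 26), app_lo = 6, rec = c(7, 9), app_hi = 11),
  list(age = c(26, 65), app_lo = 6, rec = c(7, 9), app_hi = 10),
  list(age = c(65, Inf), app_lo = 5, rec = c(7, 8), app_hi = 9)
)

oracle_sleep <- function(age, h) {
  n <- max(length(age), length(h))
  age <- rep_len(age, n)
  h <- rep_len(h, n)
  vapply(seq_len(n), function(i) {
    row <- NULL
    for (r in sleep_rows) {
      if (age[i] >= r$age[1] && age[i] < r$age[2]) row <- r
    }
    if (is.null(row)) row <- sleep_rows[[length(sleep_rows)]]
    if (h[i] >= row$rec[1] && h[i] <= row$rec[2]) return(2)
    if ((h[i] >= row$app_lo && h[i] < row$rec[1]) ||
        (h[i] > row$rec[2] && h[i] <= row$app_hi)) return(1.75)
    1
  }, numeric(1))
}

# linear-scan lookup against the packaged cut-point file, read raw
oracle_vo2 <- function(vo2, age, gender) {
  raw <- yaml::read_yaml(system.file("extdata", "vo2max_norms_synthetic.yaml",
                                     package = "wearwell"))
  n <- max(length(vo2), length(age), length(gender))
  vo2 <- rep_len(vo2, n)
  age <- rep_len(age, n)
  gender <- rep_len(gender, n)
  cell_cuts <- function(g, a) {
    cells <- raw[[g]]
    lo <- min(vapply(cells, function(x) x$age_min, numeric(1)))
    hi <- max(vapply(cells, function(x) x$age_max, numeric(1)))
    a <- min(max(a, lo), hi - 1e-9)
    for (cell in cells) {
      if (a >= cell$age_min && a < cell$age_max) return(as.numeric(cell$cuts))
    }
    stop("no cell")
  }
  vapply(seq_len(n), function(i) {
    cuts <- if (gender[i] == "unspecified") {
      (cell_cuts("male", age[i]) + cell_cuts("female", age[i])) / 2
    } else {
      cell_cuts(gender[i], age[i])
    }
    score <- 1L
    for (ct in cuts) if (vo2[i] >= ct) score <- score + 1L
    score
  }, integer(1))
}

# constant-valued daily record stream for one person
constant_days <- function(person_id, start, n, ...) {
  vals <- list(...)
  df <- tibble::tibble(person_id = person_id,
                       date = as.Date(start) + seq_len(n) - 1L)
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  df
}

write_temp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(df, f, na = "")
  f
}
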