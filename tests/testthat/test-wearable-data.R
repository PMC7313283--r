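test_that("daily records round-trip through CSV on all fields", {
  rec <- dplyr::bind_rows(
    constant_days("p1", "2019-03-02", 3, walk_steps = c(10250L, NA, 8000L),
                  sleep_time = 28000, sleep_deep_time = c(5000, NA, 6000),
                  heartrate_resting = 55.5),
    constant_days("p2", "2019-03-02", 2, walk_steps = 0L,
                  physicalactivity_moderate_time = 1234.5)
  )
  f <- write_temp_csv(rec)
  back <- read_daily_records(f)
  expect_equal(as.data.frame(back), as.data.frame(rec))

  f2 <- tempfile(fileext = ".csv")
  write_daily_records(back, f2)
  expect_equal(read_daily_records(f2), back)
})

test_that("reader parses values, keeps NA as absent, handles empty files", {
  f <- write_temp_csv(tibble::tibble(person_id = "p1", date = "2019-03-02",
                                     walk_steps = 10250))
  rec <- read_daily_records(f)
  expect_equal(rec$walk_steps, 10250)
  expect_s3_class(rec$date, "Date")

  empty <- tempfile(fileext = ".csv")
  writeLines("person_id,date,walk_steps", empty)
  expect_equal(nrow(read_daily_records(empty)), 0)

  g <- write_temp_csv(tibble::tibble(person_id = "p1", date = "2019-03-02",
                                     walk_steps = NA, sleep_time = 100))
  expect_true(is.na(read_daily_records(g)$walk_steps))
})

test_that("schema violations are rejected with the offending row named", {
  bad_neg <- write_temp_csv(tibble::tibble(person_id = "p1",
                                           date = "2019-03-02",
                                           walk_steps = -5))
  expect_error(read_daily_records(bad_neg), "negative.*row 1")

  bad_date <- write_temp_csv(tibble::tibble(person_id = "p1",
                                            date = "03/02/2019",
                                            walk_steps = 1))
  expect_error(read_daily_records(bad_date), "malformed")

  dup <- write_temp_csv(tibble::tibble(person_id = c("p1", "p1"),
                                       date = "2019-03-02", walk_steps = 1))
  expect_error(read_daily_records(dup), "duplicate person-day")

  bad_hr <- write_temp_csv(tibble::tibble(person_id = "p1",
                                          date = "2019-03-02",
                                          heartrate_max = 300))
  expect_error(read_daily_records(bad_hr), "heart rate")

  phase <- write_temp_csv(tibble::tibble(person_id = "p1", date = "2019-03-02",
                                         sleep_time = 100,
                                         sleep_deep_time = 200))
  expect_error(read_daily_records(phase), "exceeds sleep_time")
})

test_that("unknown columns error in strict mode and warn otherwise", {
  f <- write_temp_csv(tibble::tibble(person_id = "p1", date = "2019-03-02",
                                     walk_steps = 10, bogus = 1))
  expect_error(read_daily_records(f, schema_strict = TRUE), "bogus")
  expect_warning(rec <- read_daily_records(f), "bogus")
  expect_false("bogus" %in% names(rec))
})

test_that("heart-rate zone classification matches the fractional bands", {
  expect_equal(classify_hr_zone(180, 200), "peak")    # 90%
  expect_equal(classify_hr_zone(150, 200), "cardio")  # 75%
  expect_equal(classify_hr_zone(90, 200), "below")    # 45%
  # boundaries closed on the lower bound of the higher zone
  expect_equal(classify_hr_zone(c(0.50, 0.70, 0.85) * 200, 200),
               c("fat_burn", "cardio", "peak"))
  expect_equal(classify_hr_zone(205, 200), "peak")    # above hr_max
  expect_error(classify_hr_zone(100, 0), "hr_max")
})

test_that("zones partition (0.5, 1] of hr_max with no gaps or overlaps", {
  hr_max <- 187
  fr <- seq(0.5001, 1, length.out = 2000)
  zones <- classify_hr_zone(fr * hr_max, hr_max)
  expect_true(all(zones %in% c("fat_burn", "cardio", "peak")))
  # each rate lands in exactly one zone band of the published table
  tab <- hr_zones()
  hits <- vapply(fr, function(f) {
    sum(f >= tab$lower_frac & (f < tab$upper_frac | tab$zone == "peak" & f <= 1))
  }, numeric(1))
  expect_true(all(hits == 1))
})

test_that("hr_max estimate prefers observation, falls back to 220 - age", {
  expect_equal(estimate_hr_max(age = 20), 200)
  expect_equal(estimate_hr_max(age = 0), 220)
  expect_equal(estimate_hr_max(age = 40, observed_max = 185), 185)
  ages <- 0:100
  est <- estimate_hr_max(age = ages)
  expect_true(all(diff(est) <= 0))  # non-increasing in age
  expect_error(estimate_hr_max(age = NA_real_), "age is required")
})

test_that("profiles and intraday readers validate their schemas", {
  f <- write_temp_csv(tibble::tibble(person_id = c("a", "b"), age = c(30, 70),
                                     gender = c("male", NA)))
  prof <- read_profiles(f)
  expect_equal(prof$gender, c("male", "unspecified"))
  bad <- write_temp_csv(tibble::tibble(person_id = "a", age = 200,
                                       gender = "male"))
  expect_error(read_profiles(bad), "age")

  intr <- write_temp_csv(tibble::tibble(person_id = "a",
                                        timestamp = "2019-03-02T10:15:00",
                                        variable = "walk_steps", value = 120))
  df <- read_intraday_records(intr)
  expect_s3_class(df$timestamp, "POSIXct")
  neg <- write_temp_csv(tibble::tibble(person_id = "a",
                                       timestamp = "2019-03-02T10:15:00",
                                       variable = "walk_steps", value = -1))
  expect_error(read_intraday_records(neg), "negative")
})
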