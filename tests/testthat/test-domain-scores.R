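test_that("walking score reproduces the published step bands", {
  expect_identical(score_walking(13000), 5L)
  expect_identical(score_walking(7500), 3L)
  expect_identical(score_walking(0), 1L)
  # every printed band edge, closed on the lower bound of the higher band
  expect_identical(score_walking(c(4999, 5000, 7499, 7500, 9999,
                                   10000, 12499, 12500)),
                   c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
  expect_error(score_walking(-1), ">= 0")
  expect_true(is.na(score_walking(NA)))
})

test_that("physical-activity score applies the moderate-equivalence rule", {
  expect_identical(score_physical_activity(150, 0), 4L)
  expect_identical(score_physical_activity(0, 0), 1L)
  expect_identical(score_physical_activity(60, 10), 3L)  # m = 80
  # vigorous thresholds are half the moderate ones
  expect_identical(score_physical_activity(0, c(14, 15, 29, 30, 74, 75)),
                   c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(score_physical_activity(-1, 0), ">= 0")
})

test_that("sleep score reproduces the recommendation table", {
  expect_equal(score_sleep(30, 8), 2)      # adults recommended 7-9 h
  expect_equal(score_sleep(30, 6), 1.75)   # adults appropriate 6 h
  expect_equal(score_sleep(70, 10), 1)     # older adults: more than 9 h
  # one spot check per age category, from the printed bands
  expect_equal(score_sleep(0, 15), 2)        # newborns 14-17
  expect_equal(score_sleep(0.5, 10.5), 1.75) # infants appropriate 10-11
  expect_equal(score_sleep(2, 12), 2)        # toddlers 11-14
  expect_equal(score_sleep(4, 14), 1.75)     # preschoolers appropriate 14
  expect_equal(score_sleep(10, 6), 1)        # school-aged: less than 7
  expect_equal(score_sleep(15, 9), 2)        # teenagers 8-10
  expect_equal(score_sleep(20, 10.5), 1.75)  # young adults 10-11
  expect_equal(score_sleep(40, 11), 1)       # adults: more than 10
  expect_equal(score_sleep(80, 7.5), 2)      # older adults 7-8
  expect_error(score_sleep(30, -1), "0, 24")
  expect_error(score_sleep(30, 25), "0, 24")
})

test_that("sleep score never leaves {1, 1.75, 2} and is unimodal in duration", {
  set.seed(401)
  ages <- runif(500, 0, 100)
  hrs <- runif(500, 0, 24)
  s <- score_sleep(ages, hrs)
  expect_true(all(s %in% c(1, 1.75, 2)))
  # rises to 2 across the recommended band then falls: no re-ascent
  for (age in c(0.1, 2, 10, 30, 70)) {
    prof <- score_sleep(age, seq(0.25, 24, by = 0.25))
    d <- diff(prof)
    first_desc <- match(TRUE, d < 0)
    if (!is.na(first_desc)) {
      expect_true(all(d[first_desc:length(d)] <= 0))
    }
  }
})

test_that("VO2max estimate follows the heart-rate ratio formula", {
  expect_equal(estimate_vo2max(60, 60), 15.3)
  expect_equal(estimate_vo2max(200, 50), 61.2, tolerance = 1e-12)
  expect_equal(estimate_vo2max(190, 60), 48.45, tolerance = 1e-12)
  expect_error(estimate_vo2max(100, 0), "hr_rest")
  expect_warning(v <- estimate_vo2max(50, 60), "below")
  expect_equal(v, 50 / 60 * 15.3)
})

test_that("VO2max score respects floor, ceiling and cut-point closure", {
  norms <- vo2max_norms()
  expect_identical(score_vo2max(5, 30, "male"), 1L)
  expect_identical(score_vo2max(90, 30, "male"), 7L)
  # at each cut-point the score steps up (closed lower bound)
  for (g in c("male", "female")) {
    row <- norms[norms$gender == g & norms$age_min <= 30 &
                   norms$age_max > 30, ]
    cuts <- as.numeric(row[paste0("cut", 1:6)])
    expect_identical(score_vo2max(cuts, 30, g), 2:7)
    expect_identical(score_vo2max(cuts - 1e-9, 30, g), 1:6)
  }
  # ages outside table coverage clamp to the nearest bracket
  expect_identical(score_vo2max(40, 90, "male"), score_vo2max(40, 75, "male"))
  expect_identical(score_vo2max(40, 2, "male"), score_vo2max(40, 6, "male"))
  # unspecified gender scores via averaged cut-points, never refuses
  expect_true(score_vo2max(40, 30, "unspecified") %in% 1:7)
  expect_error(score_vo2max(40, 30, "other"), "gender")
})

test_that("each scorer agrees with its band-list oracle on random inputs", {
  set.seed(402)
  n <- 10000
  steps <- runif(n, 0, 20000)
  expect_identical(score_walking(steps), oracle_walk(steps))
  mod <- runif(n, 0, 300)
  vig <- runif(n, 0, 150)
  expect_identical(score_physical_activity(mod, vig),
                   oracle_activity(mod, vig))
  ages <- runif(n, 0, 100)
  hrs <- runif(n, 0, 24)
  expect_identical(score_sleep(ages, hrs), oracle_sleep(ages, hrs))
  vo2 <- runif(n, 10, 70)
  vage <- runif(n, 6, 76)
  vg <- sample(c("male", "female", "unspecified"), n, replace = TRUE)
  expect_identical(score_vo2max(vo2, vage, vg), oracle_vo2(vo2, vage, vg))
})

test_that("scorers are monotone non-decreasing in their continuous input", {
  steps <- sort(runif(200, 0, 20000))
  expect_true(all(diff(score_walking(steps)) >= 0))
  m <- sort(runif(200, 0, 400))
  expect_true(all(diff(score_physical_activity(m, 0)) >= 0))
  for (g in c("male", "female")) {
    v <- sort(runif(200, 5, 80))
    expect_true(all(diff(score_vo2max(v, 45, g)) >= 0))
  }
})

test_that("norm tables load, validate, and reject malformed files", {
  sn <- sleep_norms()
  expect_equal(nrow(sn), 9)
  expect_true(all(sn$app_lo <= sn$rec_lo & sn$rec_hi <= sn$app_hi))
  vn <- vo2max_norms()
  expect_equal(nrow(vn), 16)
  cuts <- as.matrix(vn[paste0("cut", 1:6)])
  expect_true(all(apply(cuts, 1, function(x) all(diff(x) > 0))))

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("male:", "  - {age_min: 6, age_max: 76, cuts: [30, 20, 40, 45, 50, 55]}",
               "female:", "  - {age_min: 6, age_max: 76, cuts: [27, 32, 37, 42, 47, 52]}"),
             bad)
  expect_error(vo2max_norms(bad), "increasing")
})

test_that("score_indices joins profiles and scores the golden fixture", {
  fx <- worked_example_fixture()
  idx <- score_indices(fx$daily, fx$profiles, period = "weekly")
  got <- dplyr::distinct(idx, person_id, i_walk, i_activity, i_sleep, i_cardio)
  expect_equal(as.data.frame(got), as.data.frame(fx$expected_indices))
  expect_equal(nrow(idx), 4 * 8)  # 4 persons x 8 full ISO weeks
  expect_true(all(idx$coverage == 1))
  # observed device maximum is used for hr_max, not 220 - age
  expect_equal(unique(idx$hr_max[idx$person_id == "p_b"]), 150)
})

test_that("score_indices errors on missing profile and withholds low-coverage scores", {
  fx <- worked_example_fixture()
  expect_error(score_indices(fx$daily, fx$profiles[1:3, ], period = "weekly"),
               "no profile")
  sparse <- constant_days("p1", "2019-01-07", 2, walk_steps = 13000L)
  prof <- tibble::tibble(person_id = "p1", age = 30L, gender = "male")
  idx <- score_indices(sparse, prof, period = "weekly")  # 2/7 < 4/7
  expect_false(idx$complete)
  expect_true(is.na(idx$i_walk))
})
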