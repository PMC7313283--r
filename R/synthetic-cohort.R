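#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the parameters of the generative model behind
#' [generate_cohort()]. Every person gets a latent well-being level `L` on a
#' 0-1 scale; all wearable streams and questionnaire answers are noisy
#' monotone functions of `L`. Link strengths scale how strongly `L` drives
#' each domain (1 = full default coupling, 0 = population average with no
#' individual signal).
#'
#' @param n_persons Cohort size, >= 1.
#' @param start_date First calendar day of the observation window.
#' @param n_days Number of consecutive days generated per person.
#' @param seed Integer seed fixing all randomness of one run.
#' @param latent_mean,latent_sd Mean and sd of the latent level before
#'   truncation to \[0, 1\].
#' @param link_steps,link_activity,link_sleep,link_hr Per-domain link
#'   strengths in \[0, 1\].
#' @param missingness Probability that any person-day is absent (device not
#'   worn), in \[0, 1).
#' @param questionnaire_sd Sd of the noise added to `L` before discretising
#'   questionnaire items; larger values decouple self-report from behaviour.
#' @param step_overestimate Multiplicative device bias on step counts
#'   (consumer trackers are known to over-count; 1 = unbiased).
#' @param repeat_fraction Fraction of persons filling each questionnaire a
#'   second time.
#' @return A validated `wb_cohort_config` list.
#' @export
#' @examples
#' cohort_config(n_persons = 5, n_days = 30, seed = 42)
cohort_config <- function(n_persons = 50,
                          start_date = as.Date("2019-01-01"),
                          n_days = 180,
                          seed = 1,
                          latent_mean = 0.55,
                          latent_sd = 0.2,
                          link_steps = 1,
                          link_activity = 1,
                          link_sleep = 1,
                          link_hr = 1,
                          missingness = 0.1,
                          questionnaire_sd = 0.15,
                          step_overestimate = 1,
                          repeat_fraction = 0.15) {
  cfg <- list(n_persons = as.integer(n_persons),
              start_date = as.Date(start_date),
              n_days = as.integer(n_days), seed = as.integer(seed),
              latent_mean = latent_mean, latent_sd = latent_sd,
              link_steps = link_steps, link_activity = link_activity,
              link_sleep = link_sleep, link_hr = link_hr,
              missingness = missingness,
              questionnaire_sd = questionnaire_sd,
              step_overestimate = step_overestimate,
              repeat_fraction = repeat_fraction)
  if (is.na(cfg$n_persons) || cfg$n_persons < 1) {
    abort("cohort_config(): n_persons must be >= 1")
  }
  if (is.na(cfg$n_days) || cfg$n_days < 1) {
    abort("cohort_config(): n_days must be >= 1")
  }
  if (is.na(cfg$start_date)) abort("cohort_config(): invalid start_date")
  if (!is.finite(cfg$latent_sd) || cfg$latent_sd < 0) {
    abort("cohort_config(): latent_sd must be >= 0")
  }
  if (!is.finite(cfg$questionnaire_sd) || cfg$questionnaire_sd < 0) {
    abort("cohort_config(): questionnaire_sd must be >= 0")
  }
  for (f in c("link_steps", "link_activity", "link_sleep", "link_hr",
              "missingness", "repeat_fraction")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("cohort_config(): ", f, " must be in [0, 1]"))
    }
  }
  if (cfg$missingness >= 1) abort("cohort_config(): missingness must be < 1")
  if (!is.finite(cfg$step_overestimate) || cfg$step_overestimate <= 0) {
    abort("cohort_config(): step_overestimate must be > 0")
  }
  structure(cfg, class = "wb_cohort_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a seeded synthetic cohort
#'
#' Simulates profiles, multi-month daily wearable streams and questionnaire
#' responses that share a per-person latent well-being level `L`:
#' * steps: negative-binomial daily counts whose person mean rises from
#'   roughly 2,000 to 15,000 with `L` (times the device overestimation
#'   factor), so the cohort spans all five walking bands;
#' * activity: gamma-distributed daily moderate/vigorous seconds with weekly
#'   totals rising from 0 past the 150 min/week guideline as `L` grows,
#'   covering all four activity bands;
#' * sleep: near-normal daily sleep around a person mean that sits in the
#'   recommended band for high `L` and drifts out of band (short or long,
#'   direction random per person) for low `L`;
#' * heart rate: resting rate decreasing in `L`, maximal rate near 220 - age;
#' * questionnaires: items / dimensions / health-state assessment drawn as
#'   discretised noisy monotone functions of `L`.
#'
#' Whole person-days are dropped at the configured missingness rate. All
#' randomness flows from `config$seed` through one generator, so a given
#' config reproduces byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return A list of tibbles: `profiles`, `daily` (valid daily records),
#'   `ess`, `eq5` (valid responses) and `latent` (`person_id`, `L`) for
#'   inspecting recovery.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_persons = 3, n_days = 14, seed = 7))
#' coh$profiles
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "wb_cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_persons
  ids <- sprintf("p%03d", seq_len(n))
  profiles <- tibble::tibble(
    person_id = ids,
    age = sample(25:74, n, replace = TRUE),
    gender = sample(c("male", "female"), n, replace = TRUE)
  )
  L <- clamp(rnorm(n, cfg$latent_mean, cfg$latent_sd), 0.02, 0.98)
  dom <- function(link) clamp(0.5 + link * (L - 0.5), 0, 1)
  l_steps <- dom(cfg$link_steps)
  l_act <- dom(cfg$link_activity)
  l_sleep <- dom(cfg$link_sleep)
  l_hr <- dom(cfg$link_hr)

  step_mu <- 2000 + 13000 * l_steps
  mod_week_min <- 240 * l_act^1.5
  vig_week_min <- 0.25 * mod_week_min
  sleep_dir <- sample(c(-1, 1), n, replace = TRUE)
  sleep_mean_h <- 8 + sleep_dir * 3 * (1 - l_sleep)
  rest_mu <- clamp(78 - 25 * l_hr + rnorm(n, 0, 2), 40, 110)
  hrmax_mu <- clamp(220 - profiles$age + rnorm(n, 0, 4), 120, 215)

  dates <- cfg$start_date + seq_len(cfg$n_days) - 1L
  daily <- purrr::map_dfr(seq_len(n), function(i) {
    nd <- cfg$n_days
    gamma_daily <- function(week_min) {
      if (week_min < 1) return(rep(0, nd))
      rgamma(nd, shape = 2, scale = week_min * 60 / 7 / 2)
    }
    steps <- as.integer(round(
      rnbinom(nd, size = 15, mu = step_mu[i]) * cfg$step_overestimate))
    sleep_s <- round(clamp(rnorm(nd, sleep_mean_h[i], 0.5), 1, 16) * 3600)
    rest <- round(clamp(rnorm(nd, rest_mu[i], 1.5), 35, 120), 1)
    hmax <- round(clamp(hrmax_mu[i] - abs(rnorm(nd, 0, 4)), rest + 10, 235), 1)
    rec <- tibble::tibble(
      person_id = ids[i],
      date = dates,
      walk_steps = steps,
      walk_distance = round(steps * 0.762),
      physicalactivity_moderate_time = round(gamma_daily(mod_week_min[i])),
      physicalactivity_intense_time = round(gamma_daily(vig_week_min[i])),
      sleep_time = sleep_s,
      heartrate_resting = rest,
      heartrate_max = hmax
    )
    keep <- runif(nd) >= cfg$missingness
    rec[keep, ]
  })

  latent_q <- function(sd) clamp(L + rnorm(n, 0, sd), 0, 1)
  response_dates <- function() {
    cfg$start_date + floor(runif(n, 0, cfg$n_days))
  }
  ess <- tibble::tibble(person_id = ids, timestamp = response_dates())
  for (j in 1:15) {
    ess[[paste0("q", j)]] <-
      as.integer(clamp(round(4 * latent_q(cfg$questionnaire_sd)), 0, 4))
  }
  eq5 <- tibble::tibble(person_id = ids, timestamp = response_dates())
  for (j in 1:5) {
    eq5[[paste0("d", j)]] <-
      as.integer(clamp(round(1 + 4 * latent_q(cfg$questionnaire_sd)), 1, 5))
  }
  eq5$hsa <- round(clamp(100 * latent_q(cfg$questionnaire_sd), 0, 100))

  # second filling for a fraction of the cohort, as repeat respondents
  rep_idx <- which(runif(n) < cfg$repeat_fraction)
  if (length(rep_idx) > 0) {
    ess2 <- ess[rep_idx, ]
    ess2$timestamp <- response_dates()[rep_idx]
    for (j in 1:15) {
      ess2[[paste0("q", j)]] <- as.integer(
        clamp(round(4 * latent_q(cfg$questionnaire_sd)[rep_idx]), 0, 4))
    }
    eq52 <- eq5[rep_idx, ]
    eq52$timestamp <- response_dates()[rep_idx]
    for (j in 1:5) {
      eq52[[paste0("d", j)]] <- as.integer(
        clamp(round(1 + 4 * latent_q(cfg$questionnaire_sd)[rep_idx]), 1, 5))
    }
    eq52$hsa <- round(clamp(100 * latent_q(cfg$questionnaire_sd)[rep_idx],
                            0, 100))
    ess <- dplyr::bind_rows(ess, ess2)
    eq5 <- dplyr::bind_rows(eq5, eq52)
  }

  list(profiles = profiles,
       daily = validate_daily_records(daily),
       ess = validate_ess(ess),
       eq5 = validate_eq5(eq5),
       latent = tibble::tibble(person_id = ids, L = L))
}

#' Write a generated cohort to the package's CSV dialects
#'
#' Emits `profiles.csv`, `daily_records.csv`, `responses_ess.csv` and
#' `responses_eq5.csv` into `dir`, in exactly the formats the readers
#' consume.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    profiles = file.path(dir, "profiles.csv"),
    daily = file.path(dir, "daily_records.csv"),
    ess = file.path(dir, "responses_ess.csv"),
    eq5 = file.path(dir, "responses_eq5.csv")
  )
  readr::write_csv(cohort$profiles, paths$profiles, na = "")
  readr::write_csv(cohort$daily, paths$daily, na = "")
  readr::write_csv(cohort$ess, paths$ess, na = "")
  readr::write_csv(cohort$eq5, paths$eq5, na = "")
  invisible(paths)
}

#' Hand-built four-person worked-example cohort
#'
#' A deterministic (not sampled) 4-person, 8-week cohort in which every
#' person sits squarely inside a known scoring band of each domain, together
#' with the hand-specified index table they must score to. Used as the
#' package's golden fixture and in the documentation's worked example.
#'
#' The four people, identical on every one of their 56 days
#' (2019-01-07 to 2019-03-03, ISO weeks 2019-W02..2019-W09):
#' * `p_a`, 30 y male: 13,000 steps, 1,800 s moderate activity, 8 h sleep,
#'   resting 50 / max 200 bpm -> indices 5, 4, 2, 7;
#' * `p_b`, 70 y male: 3,000 steps, 180 s moderate, 10 h sleep,
#'   resting 80 / max 150 bpm -> indices 1, 1, 1, 3;
#' * `p_c`, 30 y female: 8,000 steps, 600 s moderate, 6 h sleep,
#'   resting 60 / max 190 bpm -> indices 3, 3, 1.75, 6;
#' * `p_d`, 50 y male: 10,500 steps, 180 s vigorous, 7.5 h sleep,
#'   resting 60 / max 180 bpm -> indices 4, 2, 2, 6.
#'
#' @return A list with `profiles`, `daily` and `expected_indices` (one row
#'   per person-week: `person_id`, `i_walk`, `i_activity`, `i_sleep`,
#'   `i_cardio`).
#' @export
#' @examples
#' fx <- worked_example_fixture()
#' fx$expected_indices
worked_example_fixture <- function() {
  profiles <- tibble::tibble(
    person_id = c("p_a", "p_b", "p_c", "p_d"),
    age = c(30L, 70L, 30L, 50L),
    gender = c("male", "male", "female", "male")
  )
  spec <- tibble::tibble(
    person_id = profiles$person_id,
    walk_steps = c(13000L, 3000L, 8000L, 10500L),
    physicalactivity_moderate_time = c(1800, 180, 600, 0),
    physicalactivity_intense_time = c(0, 0, 0, 180),
    sleep_time = c(8, 10, 6, 7.5) * 3600,
    heartrate_resting = c(50, 80, 60, 60),
    heartrate_max = c(200, 150, 190, 180)
  )
  dates <- as.Date("2019-01-07") + 0:55  # 8 full ISO weeks
  daily <- tidyr::crossing(spec, date = dates) |>
    dplyr::arrange(.data$person_id, .data$date) |>
    dplyr::relocate("person_id", "date")
  expected <- tibble::tibble(
    person_id = profiles$person_id,
    i_walk = c(5L, 1L, 3L, 4L),
    i_activity = c(4L, 1L, 3L, 2L),
    i_sleep = c(2, 1, 1.75, 2),
    i_cardio = c(7L, 3L, 6L, 6L)
  )
  list(profiles = profiles, daily = validate_daily_records(daily),
       expected_indices = expected)
}
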