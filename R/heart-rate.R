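#' Target heart-rate zone definitions
#'
#' The conventional consumer-device zones as fractions of maximal heart rate:
#' fat burn 50-69%, cardio 70-84%, peak 85-100%. Anything under 50% is
#' `below`. Zone lower bounds are closed, so a rate at exactly 70% of
#' `hr_max` falls in the cardio zone and exactly 85% in the peak zone.
#'
#' @return A tibble with columns `zone`, `lower_frac`, `upper_frac`.
#' @export
#' @examples
#' hr_zones()
hr_zones <- function() {
  tibble::tibble(
    zone = c("below", "fat_burn", "cardio", "peak"),
    lower_frac = c(0, 0.50, 0.70, 0.85),
    upper_frac = c(0.50, 0.70, 0.85, 1.00)
  )
}

#' Classify a heart rate into a target zone
#'
#' @param hr Heart rate(s) in bpm, > 0.
#' @param hr_max Maximal heart rate(s) in bpm, > 0 (recycled).
#' @return A character vector of zone names: `"below"`, `"fat_burn"`,
#'   `"cardio"` or `"peak"`. Rates above `hr_max` still classify as `"peak"`.
#' @export
#' @examples
#' classify_hr_zone(c(90, 150, 180), hr_max = 200)
classify_hr_zone <- function(hr, hr_max) {
  if (any(!is.na(hr_max) & hr_max <= 0)) {
    abort("classify_hr_zone(): hr_max must be > 0")
  }
  if (any(!is.na(hr) & hr <= 0)) {
    abort("classify_hr_zone(): hr must be > 0")
  }
  frac <- hr / hr_max
  out <- dplyr::case_when(
    frac >= 0.85 ~ "peak",
    frac >= 0.70 ~ "cardio",
    frac >= 0.50 ~ "fat_burn",
    TRUE ~ "below"
  )
  out[is.na(frac)] <- NA_character_
  out
}

#' Maximal heart rate for scoring
#'
#' Prefers the device-observed maximum over the scoring window when at least
#' one valid reading exists; otherwise falls back to the crude age formula
#' 220 - age.
#'
#' @param age Age(s) in years (required for the fallback).
#' @param observed_max Device-observed maximal heart rate(s) in bpm over the
#'   window, or `NA` when none was recorded.
#' @return Maximal heart rate(s) in bpm.
#' @export
#' @examples
#' estimate_hr_max(age = 20)                      # 200, from 220 - age
#' estimate_hr_max(age = 40, observed_max = 185)  # 185, observed wins
estimate_hr_max <- function(age, observed_max = NA_real_) {
  n <- max(length(age), length(observed_max))
  age <- rep_len(age, n)
  observed_max <- rep_len(observed_max, n)
  if (any(is.na(age) & is.na(observed_max))) {
    abort("estimate_hr_max(): age is required when no observed maximum exists")
  }
  use_obs <- !is.na(observed_max) & observed_max > 0
  ifelse(use_obs, observed_max, 220 - age)
}
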