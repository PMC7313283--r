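wb_extdata <- function(file) {
  path <- system.file("extdata", file, package = "wearwell")
  if (path == "") abort(paste0("packaged reference file not found: ", file))
  path
}

#' Age-stratified sleep-duration norm table
#'
#' Loads (and validates) the National Sleep Foundation style recommendation
#' table: nine age categories, each with a recommended band, two flanking
#' "considered appropriate" bands, and everything else not recommended. The
#' printed bands are completed by continuity so the three classes partition
#' (0, 24] hours: each appropriate band extends to the adjacent recommended
#' bound, closed on the bound farther from the recommended range. For adults
#' (26-64) this gives recommended \[7, 9\], appropriate \[6, 7) and (9, 10\],
#' not recommended below 6 and above 10 hours.
#'
#' @param path Optional path to an alternative YAML table with the same
#'   structure; defaults to the packaged table.
#' @return A tibble with one row per age category: `category`, `age_min`,
#'   `age_max` (years, lower bound inclusive), `rec_lo`, `rec_hi` (recommended
#'   band, hours, both inclusive), `app_lo`, `app_hi` (outer bounds of the two
#'   appropriate bands, inclusive).
#' @export
#' @examples
#' sleep_norms()
sleep_norms <- function(path = NULL) {
  path <- path %||% wb_extdata("sleep_norms.yaml")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$categories) || length(raw$categories) == 0) {
    abort("sleep norms: no categories defined")
  }
  tab <- purrr::map_dfr(raw$categories, function(cc) {
    for (f in c("name", "age_min", "age_max", "recommended",
                "appropriate_low", "appropriate_high")) {
      if (is.null(cc[[f]])) abort(paste0("sleep norms: missing field ", f))
    }
    tibble::tibble(
      category = cc$name,
      age_min = as.numeric(cc$age_min),
      age_max = as.numeric(cc$age_max),
      rec_lo = cc$recommended[[1]], rec_hi = cc$recommended[[2]],
      app_lo = cc$appropriate_low[[1]],
      app_hi = cc$appropriate_high[[2]]
    )
  })
  tab <- dplyr::arrange(tab, .data$age_min)
  ok <- tab$app_lo <= tab$rec_lo & tab$rec_lo <= tab$rec_hi &
    tab$rec_hi <= tab$app_hi & tab$app_lo > 0 & tab$app_hi <= 24
  if (!all(ok)) {
    abort(paste0("sleep norms: bands out of order for category ",
                 tab$category[which(!ok)[1]]))
  }
  if (any(tab$age_min[-1] != tab$age_max[-nrow(tab)])) {
    abort("sleep norms: age categories must tile the age axis")
  }
  tab
}

#' Cardio-respiratory fitness (VO2max) norm table
#'
#' Loads a gender- and age-stratified categorisation of VO2max into fitness
#' scores 1 (very low) through 7 (elite): six strictly ascending cut-points
#' per (gender, age bracket) cell, interpreted as inclusive lower bounds of
#' scores 2..7. The packaged default
#' (`vo2max_norms_synthetic.yaml`) is a synthetic stand-in table with the
#' shape of published aerobic-fitness norms for ages 6-75; supply `path` to
#' use licensed normative values.
#'
#' @param path Optional path to an alternative YAML table with the same
#'   structure.
#' @return A tibble with columns `gender`, `age_min`, `age_max` and `cut1` ..
#'   `cut6` (mL/(kg*min)).
#' @export
#' @examples
#' vo2max_norms()
vo2max_norms <- function(path = NULL) {
  path <- path %||% wb_extdata("vo2max_norms_synthetic.yaml")
  raw <- yaml::read_yaml(path)
  for (g in c("male", "female")) {
    if (is.null(raw[[g]])) abort(paste0("vo2max norms: missing gender ", g))
  }
  tab <- purrr::map_dfr(c("male", "female"), function(g) {
    purrr::map_dfr(raw[[g]], function(cell) {
      cuts <- as.numeric(cell$cuts)
      if (length(cuts) != 6 || any(diff(cuts) <= 0)) {
        abort("vo2max norms: each cell needs 6 strictly increasing cut-points")
      }
      tibble::tibble(gender = g,
                     age_min = as.numeric(cell$age_min),
                     age_max = as.numeric(cell$age_max),
                     !!!stats::setNames(as.list(cuts), paste0("cut", 1:6)))
    })
  })
  dplyr::arrange(tab, .data$gender, .data$age_min)
}

#' Composite weight factors
#'
#' `default_weights()` returns the default weighting of the four domain
#' indices (walking 0.9, physical activity 1.0, sleep 1.05, cardio fitness
#' 1.05; sum 4). `read_weights()` loads a YAML file with keys
#' `walking,activity,sleep,cardio`, all strictly positive.
#'
#' @param path Path to a YAML weights file.
#' @return A named numeric vector with elements `walking`, `activity`,
#'   `sleep`, `cardio`.
#' @export
#' @examples
#' default_weights()
default_weights <- function() {
  read_weights(wb_extdata("default_weights.yaml"))
}

#' @rdname default_weights
#' @export
read_weights <- function(path) {
  raw <- yaml::read_yaml(path)
  keys <- c("walking", "activity", "sleep", "cardio")
  miss <- setdiff(keys, names(raw))
  if (length(miss) > 0) {
    abort(paste0("weights file lacks key(s): ", paste(miss, collapse = ", ")))
  }
  w <- vapply(raw[keys], as.numeric, numeric(1))
  if (any(!is.finite(w) | w <= 0)) {
    abort("composite weights must all be finite and > 0")
  }
  w
}
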