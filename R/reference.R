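#' Reference counts of the emulated JMDC cohort design
#'
#' The published bookkeeping of the heart-failure onset study on JMDC
#' claims data that this package's simulator emulates: 308,205 people
#' randomly allocated into a 32,547-person analysis cohort (325 four-year
#' events) and a 275,658-person validation cohort, stratified into six
#' groups by the number of matched predictive combinations. These constants
#' parameterise the simulator's calibration and let the stratification
#' arithmetic (per-group incidence, cohort sums, annualized rate) be
#' recomputed by the package's own functions.
#'
#' @return list with `analysis_n`, `analysis_events`, `validation_n`,
#'   `total_n`, `follow_up_years`, and a `groups` data.frame
#'   (`label`, `n`, `events`).
#' @examples
#' ref <- jmdc_reference()
#' sum(ref$groups$n) == ref$validation_n
#' @export
jmdc_reference <- function() {
  list(
    analysis_n = 32547L,
    analysis_events = 325L,
    validation_n = 275658L,
    total_n = 308205L,
    follow_up_years = 4L,
    groups = data.frame(
      label = c("0", "1-50", "51-100", "101-150", "151-200", "201-250"),
      n = c(182468L, 26774L, 46262L, 19722L, 364L, 68L),
      events = c(2695L, 1124L, 1871L, 715L, 43L, 9L),
      stringsAsFactors = FALSE)
  )
}

#' Annualized incidence rate per 1000 person-years
#'
#' Simple exposure approximation `events / (persons * years) * 1000`, the
#' convention used when quoting population HF incidence (e.g. ~2.5/1000
#' person-years for 325 events among 32,547 people over 4 years).
#'
#' @param events number of events.
#' @param persons cohort size.
#' @param years follow-up length in years.
#' @return rate per 1000 person-years.
#' @export
incidence_rate_per_1000py <- function(events, persons, years) {
  stopifnot(events >= 0, persons > 0, years > 0)
  1000 * events / (persons * years)
}
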