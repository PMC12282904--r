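#' Define a screening strategy
#'
#' A strategy is a start age, a screening interval in years, and a stop age
#' (70 throughout the evaluated roster). The null strategy — no systematic
#' screening — has `start_age = NA` and `interval_years = NA`.
#'
#' @param label Strategy name.
#' @param start_age First screened age (or `NA` for no screening).
#' @param interval_years Years between rounds (or `NA` for no screening).
#' @param stop_age Last age at which a round can occur.
#' @return A one-row tibble (`label`, `start_age`, `interval_years`,
#'   `stop_age`).
#' @export
screening_strategy <- function(label, start_age = NA_real_,
                               interval_years = NA_real_, stop_age = 70) {
  if (is.na(start_age) != is.na(interval_years)) {
    abort("start_age and interval_years must both be set or both be NA")
  }
  if (!is.na(start_age) && start_age > stop_age) {
    abort("start_age must not exceed stop_age")
  }
  tibble(label = label, start_age = as.numeric(start_age),
         interval_years = as.numeric(interval_years),
         stop_age = as.numeric(stop_age))
}

#' The evaluated strategy roster
#'
#' The ten comparators: no screening, and annual / biennial / triennial
#' screening starting at ages 30, 40 and 50, all stopping at 70.
#'
#' @return A tibble with 10 rows.
#' @export
strategy_roster <- function() {
  bind_rows(
    screening_strategy("No screening"),
    screening_strategy("Annual screening from the age of 30", 30, 1),
    screening_strategy("Annual screening from the age of 40", 40, 1),
    screening_strategy("Annual screening from the age of 50", 50, 1),
    screening_strategy("Screening every two years from the age of 30", 30, 2),
    screening_strategy("Screening every two years from the age of 40", 40, 2),
    screening_strategy("Screening every two years from the age of 50", 50, 2),
    screening_strategy("Screening every three years from the age of 30", 30, 3),
    screening_strategy("Screening every three years from the age of 40", 40, 3),
    screening_strategy("Screening every three years from the age of 50", 50, 3)
  )
}

#' Does a strategy screen at a given age?
#'
#' TRUE exactly when the strategy screens and the attained age lies on the
#' grid `start, start + interval, ...` within `[start, stop_age]`.
#'
#' @param strategy One-row strategy tibble (see [screening_strategy()]).
#' @param age Attained age(s); vectorized.
#' @return Logical vector.
#' @export
is_screening_cycle <- function(strategy, age) {
  if (is.na(strategy$start_age) || is.na(strategy$interval_years)) {
    return(rep(FALSE, length(age)))
  }
  offs <- age - strategy$start_age
  offs >= 0 & age <= strategy$stop_age & offs %% strategy$interval_years == 0
}

#' Apply one screening round to cohort masses
#'
#' Splits the healthy and the untreated-hypertensive occupancy into
#' screen-outcome sub-populations. Among participating healthy people, a
#' fraction `specificity` test true negative and the rest false positive;
#' among participating untreated hypertensives, a fraction `sensitivity` test
#' true positive and the rest false negative. Every participant incurs the
#' screening-contact cost; every screen-positive (true or false) incurs the
#' confirmatory-workup cost. The confirmatory test is perfectly accurate, so
#' false positives are recognised as healthy; false negatives remain
#' undiagnosed until the next round.
#'
#' @param healthy_mass,untreated_mass Non-negative occupancy masses.
#' @param params An `htn_params` object.
#' @return A tibble with one row per screened state (`group` = `"healthy"`,
#'   `"untreated"`) and columns `true_positive`, `false_negative`,
#'   `false_positive`, `true_negative`, `not_participating`,
#'   `screening_cost`, `confirmatory_cost`.
#' @examples
#' params <- load_parameters(schedules = default_schedule_set(1))
#' apply_screening(1, 0, params)
#' @export
apply_screening <- function(healthy_mass, untreated_mass, params) {
  if (healthy_mass < 0 || untreated_mass < 0) {
    abort("screened masses must be non-negative")
  }
  p <- function(nm) param_value(params, nm)
  part_h <- healthy_mass * p("participation_healthy")
  part_u <- untreated_mass * p("participation_untreated")
  spec <- p("specificity")
  sens <- p("sensitivity")
  c_contact <- p("screening_contact")
  c_confirm <- p("confirmatory_workup")

  healthy <- tibble(
    group = "healthy",
    true_positive = 0, false_negative = 0,
    false_positive = part_h * (1 - spec), true_negative = part_h * spec,
    not_participating = healthy_mass - part_h,
    screening_cost = part_h * c_contact,
    confirmatory_cost = part_h * (1 - spec) * c_confirm
  )
  untreated <- tibble(
    group = "untreated",
    true_positive = part_u * sens, false_negative = part_u * (1 - sens),
    false_positive = 0, true_negative = 0,
    not_participating = untreated_mass - part_u,
    screening_cost = part_u * c_contact,
    confirmatory_cost = part_u * sens * c_confirm
  )
  bind_rows(healthy, untreated)
}
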