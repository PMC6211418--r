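#' Multiplicative score table
#'
#' All parameters of the multiplicative tendency score. Reference
#' categories (young, male, high income, cheap) are pinned at 1.0; the
#' remaining multipliers are the published calibrated values and can be
#' overridden individually (e.g. by the calibration harness or a scenario
#' config).
#'
#' @param mean_frequency mean frequency of sports in the city, events per
#'   year; multiplies the tendency to give the exponential start rate.
#' @param age named multipliers for age groups `young` (18-35), `middle`
#'   (35-55) and `old` (55-85). Boundaries are half-open: 35 belongs to
#'   `middle`, 55 to `old`.
#' @param sex named multipliers for `male` and `female`.
#' @param income named multipliers for `high`, `middle` and `low` income.
#' @param price named multipliers for `cheap` and `expensive` facilities.
#' @param distance_decay named per-10 m exponential distance-decay rates
#'   for `fitness` and `club`; accessibility is `exp(-beta * d / 10)` with
#'   `d` in metres.
#' @param education_effect default tendency multiplier conferred by the
#'   health-education intervention.
#' @return an object of class `sport_scores`
#' @examples
#' sc <- score_table()
#' sc$income[["low"]]
#' @export
score_table <- function(mean_frequency = 153.5,
                        age = c(young = 1, middle = 0.157, old = 0.148),
                        sex = c(male = 1, female = 0.659),
                        income = c(high = 1, middle = 0.471, low = 0.428),
                        price = c(cheap = 1, expensive = 0.85),
                        distance_decay = c(fitness = 0.029, club = 0.027),
                        education_effect = 1.5) {
  st <- list(mean_frequency = mean_frequency, age = age, sex = sex,
             income = income, price = price,
             distance_decay = distance_decay,
             education_effect = education_effect)
  validate_score_table(st)
  structure(st, class = "sport_scores")
}

validate_score_table <- function(st) {
  need <- function(x, nm, where) {
    if (!all(nm %in% names(x)))
      stop("score table ", where, " must have entries ",
           paste(nm, collapse = ", "), call. = FALSE)
    if (any(!is.finite(x)) || any(x <= 0))
      stop("score table ", where, " multipliers must be positive", call. = FALSE)
  }
  need(st$age, c("young", "middle", "old"), "age")
  need(st$sex, c("male", "female"), "sex")
  need(st$income, c("high", "middle", "low"), "income")
  need(st$price, c("cheap", "expensive"), "price")
  need(st$distance_decay, c("fitness", "club"), "distance_decay")
  if (!isTRUE(all.equal(unname(st$age[["young"]]), 1)) ||
      !isTRUE(all.equal(unname(st$sex[["male"]]), 1)) ||
      !isTRUE(all.equal(unname(st$income[["high"]]), 1)) ||
      !isTRUE(all.equal(unname(st$price[["cheap"]]), 1)))
    stop("reference categories (young, male, high, cheap) must equal 1.0",
         call. = FALSE)
  if (!is.finite(st$mean_frequency) || st$mean_frequency <= 0)
    stop("mean_frequency must be positive", call. = FALSE)
  if (st$education_effect < 1)
    stop("education_effect must be >= 1", call. = FALSE)
  invisible(st)
}

#' Age group of an age in years
#'
#' Half-open boundaries: `[18, 35)` young, `[35, 55)` middle, `[55, 85]`
#' old.
#'
#' @param age numeric vector of ages in years
#' @return character vector in `c("young", "middle", "old")`
#' @export
age_group <- function(age) {
  c("young", "middle", "old")[1L + (age >= 35) + (age >= 55)]
}

#' Dynamics parameters of the monthly event loop
#'
#' Annual probabilities govern quitting and frequency changes; they are
#' applied once per simulated year. Demographic turnover uses an
#' age-dependent Gompertz death schedule
#' `p_death(age) = death_a * exp(death_b * age)` (annual probability,
#' capped at 0.5) plus a flat out-migration rate; removed individuals are
#' replaced by new non-participating residents of the same neighbourhood,
#' keeping the population constant.
#'
#' @param quit_prob annual quitting probabilities by category.
#' @param freq_increase_prob annual probability of moving from monthly to
#'   weekly participation.
#' @param freq_decrease_prob annual probability of moving from weekly to
#'   monthly participation.
#' @param multi_sport_adjust_prob probability of a compensating frequency
#'   change when starting an additional sport or quitting one of several.
#' @param weekly_start_fraction probability that a start event begins at
#'   weekly (rather than monthly) frequency.
#' @param death_a,death_b Gompertz coefficients of the annual death
#'   schedule; defaults give roughly 0.2% at 46 and 8% at 85.
#' @param migration_rate annual out-migration probability.
#' @param facility_turnover logical; run the annual one-close/one-open
#'   facility feedback.
#' @param poisson_turnover logical; if `TRUE`, the number of annual
#'   closures and openings per kind is Poisson(1) rather than exactly one
#'   (closures and openings are stated as yearly averages).
#' @param burn_in_years,horizon_years default simulated years before and
#'   after the intervention point.
#' @return an object of class `sport_dynamics`
#' @export
dynamics_params <- function(quit_prob = c(fitness = 0.28, club = 0.12,
                                          self_organized = 0.27),
                            freq_increase_prob = 0.21,
                            freq_decrease_prob = 0.09,
                            multi_sport_adjust_prob = 0.5,
                            weekly_start_fraction = 0.5,
                            death_a = 2.6e-5, death_b = 0.0946,
                            migration_rate = 0.05,
                            facility_turnover = TRUE,
                            poisson_turnover = FALSE,
                            burn_in_years = 50L, horizon_years = 25L) {
  dp <- list(quit_prob = quit_prob,
             freq_increase_prob = freq_increase_prob,
             freq_decrease_prob = freq_decrease_prob,
             multi_sport_adjust_prob = multi_sport_adjust_prob,
             weekly_start_fraction = weekly_start_fraction,
             death_a = death_a, death_b = death_b,
             migration_rate = migration_rate,
             facility_turnover = isTRUE(facility_turnover),
             poisson_turnover = isTRUE(poisson_turnover),
             burn_in_years = as.integer(burn_in_years),
             horizon_years = as.integer(horizon_years))
  validate_dynamics(dp)
  structure(dp, class = "sport_dynamics")
}

validate_dynamics <- function(dp) {
  if (!all(SPORT_CATEGORIES %in% names(dp$quit_prob)))
    stop("quit_prob needs entries fitness, club, self_organized", call. = FALSE)
  probs <- c(dp$quit_prob, dp$freq_increase_prob, dp$freq_decrease_prob,
             dp$multi_sport_adjust_prob, dp$weekly_start_fraction,
             dp$migration_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all dynamics probabilities must lie in [0, 1]", call. = FALSE)
  if (dp$death_a < 0 || dp$death_b < 0)
    stop("death schedule coefficients must be nonnegative", call. = FALSE)
  invisible(dp)
}

#' Structural model options
#'
#' @param social_influence logical; multiply the tendency by the
#'   social-influence score (1 + share of participating neighbours within
#'   `radius` metres).
#' @param si_mode `"any"` counts neighbours participating in any category;
#'   `"category"` counts participation in the category being scored.
#' @param radius social-influence neighbourhood radius in metres.
#' @param categories subset of [SPORT_CATEGORIES] that is simulated.
#' @return an object of class `sport_options`
#' @export
model_options <- function(social_influence = TRUE,
                          si_mode = c("any", "category"),
                          radius = 50,
                          categories = SPORT_CATEGORIES) {
  si_mode <- match.arg(si_mode)
  categories <- match.arg(categories, SPORT_CATEGORIES, several.ok = TRUE)
  structure(list(social_influence = isTRUE(social_influence),
                 si_mode = si_mode, radius = radius,
                 categories = categories,
                 categories_idx = match(categories, SPORT_CATEGORIES)),
            class = "sport_options")
}
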