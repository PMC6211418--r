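# The five intervention scenarios. All are of immediate effect and
# monotone: none ever lowers any individual's tendency.

#' Specify an intervention
#'
#' @param type one of `"health_education"`, `"price"`, `"availability"`,
#'   `"safety"`, `"combined"`.
#' @param start_month month index at which the intervention activates
#'   (defaults to the run's intervention point).
#' @param education_effect tendency multiplier given to sampled
#'   individuals (default 1.5; sweeps use 1.5-3).
#' @param education_reach fraction of current non-participants sampled
#'   (default 0.15; sweeps use up to 0.50).
#' @param availability_n_neighborhoods number of lowest-participation
#'   neighbourhoods that receive one fitness centre and one club facility
#'   (default 5; sweeps use 10-50).
#' @param availability_protection_years years during which the new
#'   facilities cannot close (default 10).
#' @param safety_target `"city_mean"` (unweighted mean over
#'   neighbourhoods), `"fixed_value"` (use `safety_value`) or
#'   `"max_neighborhood"`.
#' @param safety_value target for `safety_target = "fixed_value"`
#'   (default 0.75).
#' @return an object of class `intervention_spec`
#' @export
intervention_spec <- function(type = c("health_education", "price",
                                       "availability", "safety", "combined"),
                              start_month = NULL,
                              education_effect = 1.5,
                              education_reach = 0.15,
                              availability_n_neighborhoods = 5L,
                              availability_protection_years = 10L,
                              safety_target = c("city_mean", "fixed_value",
                                                "max_neighborhood"),
                              safety_value = 0.75) {
  type <- match.arg(type)
  safety_target <- match.arg(safety_target)
  if (education_reach < 0 || education_reach > 1)
    stop("education_reach must lie in [0, 1]")
  if (education_effect < 1) stop("education_effect must be >= 1")
  structure(list(type = type, start_month = start_month,
                 education_effect = education_effect,
                 education_reach = education_reach,
                 availability_n_neighborhoods =
                   as.integer(availability_n_neighborhoods),
                 availability_protection_years =
                   as.integer(availability_protection_years),
                 safety_target = safety_target,
                 safety_value = safety_value),
            class = "intervention_spec")
}

#' Health education: boost the tendency of sampled non-participants
#'
#' A simple random sample of `floor(reach x current non-participants)`
#' individuals (not participating in any category) permanently receives
#' `education_boost = effect`; participants are never sampled.
#'
#' @param state a `sport_state`, modified in place
#' @param spec an [intervention_spec()]
#' @return the state, invisibly
#' @export
apply_health_education <- function(state, spec = intervention_spec("health_education")) {
  nonpart <- which(rowSums(state$stat > 0L) == 0L)
  k <- floor(spec$education_reach * length(nonpart))
  if (k > 0) {
    chosen <- with_stream(state, "interventions",
                          nonpart[sample.int(length(nonpart), k)])
    state$edu[chosen] <- pmax(state$edu[chosen], spec$education_effect)
  }
  invisible(state)
}

#' Price reduction: every expensive facility becomes cheap
#'
#' All open facilities switch to the cheap price level, and facilities
#' opened later open cheap while the intervention is active.
#'
#' @inheritParams apply_health_education
#' @return the state, invisibly
#' @export
apply_price_reduction <- function(state, spec = intervention_spec("price")) {
  state$fcs$cheap[state$fcs$open] <- TRUE
  state$price_lock <- TRUE
  update_best(state)
  invisible(state)
}

#' Availability: new facilities in low-participation neighbourhoods
#'
#' Neighbourhoods are ranked by their residents' current participation
#' fraction (ascending, ties to the lowest id; neighbourhoods without
#' residents are skipped). In each of the bottom `n`, one fitness centre
#' and one club facility open at vacant designated locations — skipped
#' with a warning if the neighbourhood has no vacant location of a kind.
#' New facilities are cheap and protected from closure for the
#' protection horizon (default 10 years).
#'
#' @inheritParams apply_health_education
#' @return the state, invisibly
#' @export
apply_availability <- function(state, spec = intervention_spec("availability")) {
  n_nb <- nrow(state$city$neighborhoods)
  act <- rowSums(state$stat > 0L) > 0L
  tot <- tabulate(state$nbhd, n_nb)
  part <- tabulate(state$nbhd[act], n_nb) / pmax(tot, 1L)
  part[tot == 0L] <- Inf
  ord <- order(part, seq_len(n_nb))
  targets <- ord[seq_len(min(spec$availability_n_neighborhoods,
                             sum(is.finite(part))))]
  until <- state$month + 12L * spec$availability_protection_years
  for (nb in targets) {
    for (k in 1:2) {
      slots <- which(!state$locs$occupied & state$locs$kind == k &
                       state$locs$nbhd == nb)
      if (!length(slots)) {
        warning("availability intervention: no vacant ",
                c("fitness", "club")[k], " location in neighborhood ", nb,
                call. = FALSE)
        log_event(state, "availability_skipped_no_vacancy", k, NA, nb, NA)
        next
      }
      pick <- if (length(slots) == 1L) slots else
        slots[with_stream(state, "interventions",
                          sample.int(length(slots), 1L))]
      open_at(state, pick, k, cheap = TRUE, protected_until = until)
    }
  }
  invisible(state)
}

#' Safety improvement: raise below-target neighbourhood safety
#'
#' The target is the unweighted city mean of neighbourhood safety scores
#' (`"city_mean"`), a fixed value (default 0.75), or the maximum
#' neighbourhood score. Every neighbourhood strictly below the target is
#' raised to it; others are untouched.
#'
#' @inheritParams apply_health_education
#' @return the state, invisibly
#' @export
apply_safety <- function(state, spec = intervention_spec("safety")) {
  target <- switch(spec$safety_target,
                   city_mean = mean(state$safety),
                   fixed_value = spec$safety_value,
                   max_neighborhood = max(state$safety))
  state$safety[state$safety < target] <- target
  invisible(state)
}

#' Combined (multilevel) intervention
#'
#' Applies all four single interventions with the given spec's parameters
#' in fixed order — education, price, availability, safety — at the same
#' month. Identical to the sequential composition of the four.
#'
#' @inheritParams apply_health_education
#' @return the state, invisibly
#' @export
apply_combined <- function(state, spec = intervention_spec("combined")) {
  apply_health_education(state, spec)
  apply_price_reduction(state, spec)
  apply_availability(state, spec)
  apply_safety(state, spec)
  invisible(state)
}

#' Apply an intervention spec to a state
#'
#' @inheritParams apply_health_education
#' @return the state, invisibly
#' @export
apply_intervention <- function(state, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  switch(spec$type,
         health_education = apply_health_education(state, spec),
         price = apply_price_reduction(state, spec),
         availability = apply_availability(state, spec),
         safety = apply_safety(state, spec),
         combined = apply_combined(state, spec))
  invisible(state)
}
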