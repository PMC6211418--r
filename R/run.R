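# Running scenarios: single runs and run ensembles.

#' Simulate a single run
#'
#' Steps the model month by month for `years` simulated years, running
#' the annual update at the end of every year and logging participation
#' metrics monthly. Interventions (if any) activate at the start of the
#' month following `intervention_month` completed months — i.e. after the
#' burn-in when `intervention_month = burn_in_years * 12`.
#'
#' @param city a [generate_city()] result
#' @param years number of simulated years
#' @param seed integer seed for this run
#' @param scores,dyn,opts model parameter objects
#' @param interventions a list of [intervention_spec()] (or `NULL`)
#' @param intervention_month default activation month for specs without
#'   their own `start_month`
#' @param population optional fixed population table (by default drawn
#'   per run from the run seed, so runs differ in population draw and
#'   event history)
#' @param keep_state return the final `sport_state` as attribute `state`
#' @param record_neighborhoods record per-neighbourhood participation
#'   and income inequality at the intervention month and at the end
#' @return a `data.table` in tidy long format: `month`, `metric`,
#'   `value`, with one row per month and metric
#' @export
simulate_run <- function(city, years, seed, scores = score_table(),
                         dyn = dynamics_params(), opts = model_options(),
                         interventions = NULL, intervention_month = NULL,
                         population = NULL, keep_state = FALSE,
                         record_neighborhoods = FALSE) {
  state <- new_state(city, population = population, scores = scores,
                     dyn = dyn, opts = opts, seed = seed)
  months <- as.integer(years * 12)
  log <- matrix(NA_real_, months, length(METRIC_NAMES),
                dimnames = list(NULL, METRIC_NAMES))
  if (!is.null(interventions) && inherits(interventions, "intervention_spec"))
    interventions <- list(interventions)
  starts <- if (is.null(interventions)) integer() else
    vapply(interventions, function(sp)
      as.integer(sp$start_month %||% intervention_month %||% 0L), 0L)
  snap <- list()
  for (m in seq_len(months)) {
    if (length(starts)) {
      due <- which(starts == state$month)
      if (length(due) && record_neighborhoods && is.null(snap$baseline))
        snap$baseline <- neighborhood_metrics(state)
      for (i in due) {
        sp <- interventions[[i]]
        sp$start_month <- state$month
        apply_intervention(state, sp)
      }
    }
    step_month(state)
    if (state$month %% 12L == 0L) annual_update(state)
    log[m, ] <- metric_row(state)
  }
  if (record_neighborhoods) snap$final <- neighborhood_metrics(state)
  out <- data.table::data.table(
    month = rep(seq_len(months), times = ncol(log)),
    metric = rep(colnames(log), each = months),
    value = as.vector(log))
  data.table::setattr(out, "metrics_matrix", log)
  if (record_neighborhoods) data.table::setattr(out, "neighborhoods", snap)
  if (keep_state) data.table::setattr(out, "state", state)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

metric_row <- function(state) {
  act <- state$stat > 0L
  anyp <- act[, 1L] | act[, 2L] | act[, 3L]
  ag <- 1L + (state$age >= 35) + (state$age >= 55)
  grp <- function(g, ng) {
    tot <- tabulate(g, ng)
    s <- tabulate(g[anyp], ng)
    ifelse(tot > 0L, s / tot, NA_real_)
  }
  c(mean(anyp), grp(state$income, 3L), grp(ag, 3L), grp(state$sex, 2L),
    mean(act[, 1L]), mean(act[, 2L]), mean(act[, 3L]))
}

#' Run an ensemble of simulations
#'
#' Executes `n_runs` independent runs (seeds derived from `base_seed` by
#' the documented splitting rule, or supplied explicitly) and collects
#' the monthly metric trajectories. Scenario-vs-counterfactual contrasts
#' should use the same `base_seed` so that runs are paired by common
#' random numbers.
#'
#' @inheritParams simulate_run
#' @param n_runs number of runs
#' @param base_seed integer from which per-run seeds are derived
#' @param seeds optional explicit integer vector of per-run seeds
#' @return an object of class `sport_ensemble`: a list with the metric
#'   array (`months x metrics x runs`), the seeds, and (optionally)
#'   per-run neighbourhood snapshots
#' @export
run_ensemble <- function(city, years, n_runs = 80L, base_seed = 1L,
                         seeds = NULL, scores = score_table(),
                         dyn = dynamics_params(), opts = model_options(),
                         interventions = NULL, intervention_month = NULL,
                         record_neighborhoods = FALSE) {
  if (is.null(seeds))
    seeds <- vapply(seq_len(n_runs), function(i)
      stream_seed(base_seed, 7000L + i), 0L)
  n_runs <- length(seeds)
  months <- as.integer(years * 12)
  arr <- array(NA_real_, c(months, length(METRIC_NAMES), n_runs),
               dimnames = list(NULL, METRIC_NAMES, NULL))
  snaps <- if (record_neighborhoods) vector("list", n_runs) else NULL
  for (i in seq_len(n_runs)) {
    res <- tryCatch(
      simulate_run(city, years, seeds[i], scores = scores, dyn = dyn,
                   opts = opts, interventions = interventions,
                   intervention_month = intervention_month,
                   record_neighborhoods = record_neighborhoods),
      error = function(e) stop("run with seed ", seeds[i], " failed: ",
                               conditionMessage(e), call. = FALSE))
    arr[, , i] <- attr(res, "metrics_matrix")
    if (record_neighborhoods) snaps[[i]] <- attr(res, "neighborhoods")
  }
  structure(list(metrics = arr, metric_names = METRIC_NAMES,
                 months = months, n_runs = n_runs, seeds = seeds,
                 years = years,
                 interventions = interventions,
                 neighborhoods = snaps),
            class = "sport_ensemble")
}

#' @export
print.sport_ensemble <- function(x, ...) {
  cat("<sport_ensemble>", x$n_runs, "runs x", x$months, "months\n")
  fin <- x$metrics[x$months, "overall", ]
  cat(sprintf("  final overall participation: mean %.1f%% (runs %.1f-%.1f%%)\n",
              100 * mean(fin), 100 * min(fin), 100 * max(fin)))
  invisible(x)
}
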