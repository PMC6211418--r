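# Scenario configuration: YAML/JSON schema, validation with key paths,
# and the provenance echo of every resolved default.

SCENARIO_KEYS <- c("city", "scores", "dynamics", "model", "run",
                   "interventions")

schema_error <- function(path, msg) {
  stop(structure(class = c("sportabm_schema_error", "error", "condition"),
                 list(message = paste0("schema error at ", path, ": ", msg),
                      call = NULL)))
}

check_num <- function(x, path, lo = -Inf, hi = Inf) {
  if (is.null(x)) return(invisible(NULL))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    schema_error(path, "must be a single finite number")
  if (x < lo || x > hi)
    schema_error(path, paste0("must lie in [", lo, ", ", hi, "]"))
  invisible(NULL)
}

check_known <- function(lst, known, path) {
  bad <- setdiff(names(lst), known)
  if (length(bad))
    schema_error(paste0(path, ".", bad[1]), "unknown key")
  invisible(NULL)
}

#' Validate a scenario configuration list
#'
#' Checks key names and value ranges of a (nested) scenario list as read
#' from YAML/JSON, reporting the path to the first offending key, then
#' builds the typed parameter objects.
#'
#' @param cfg a named list (parsed YAML/JSON)
#' @return an object of class `sport_scenario`: list with `city_config`,
#'   `scores`, `dyn`, `opts`, `run` (burn_in_years, horizon_years,
#'   n_runs, seed) and `interventions`
#' @export
validate_scenario <- function(cfg) {
  if (!is.list(cfg)) schema_error("(root)", "config must be a mapping")
  check_known(cfg, SCENARIO_KEYS, "(root)")

  city_args <- cfg$city %||% list()
  check_known(city_args, names(formals(city_config)), "city")
  if (!is.null(city_args$income_fractions))
    city_args$income_fractions <- unlist(city_args$income_fractions)
  if (!is.null(city_args$age_range))
    city_args$age_range <- unlist(city_args$age_range)
  ccfg <- tryCatch(do.call(city_config, city_args),
                   error = function(e) schema_error("city", conditionMessage(e)))

  sc_args <- cfg$scores %||% list()
  check_known(sc_args, names(formals(score_table)), "scores")
  for (nm in c("age", "sex", "income", "price", "distance_decay"))
    if (!is.null(sc_args[[nm]])) sc_args[[nm]] <- unlist(sc_args[[nm]])
  scores <- tryCatch(do.call(score_table, sc_args),
                     error = function(e) schema_error("scores",
                                                      conditionMessage(e)))

  dyn_args <- cfg$dynamics %||% list()
  check_known(dyn_args, names(formals(dynamics_params)), "dynamics")
  if (!is.null(dyn_args$quit_prob)) {
    qp <- unlist(dyn_args$quit_prob)
    check_known(as.list(qp), SPORT_CATEGORIES, "dynamics.quit_prob")
    for (nm in names(qp))
      check_num(qp[[nm]], paste0("dynamics.quit_prob.", nm), 0, 1)
    dyn_args$quit_prob <- qp
  }
  for (nm in c("freq_increase_prob", "freq_decrease_prob",
               "multi_sport_adjust_prob", "weekly_start_fraction",
               "migration_rate"))
    check_num(dyn_args[[nm]], paste0("dynamics.", nm), 0, 1)
  dyn <- tryCatch(do.call(dynamics_params, dyn_args),
                  error = function(e) schema_error("dynamics",
                                                   conditionMessage(e)))

  mod_args <- cfg$model %||% list()
  check_known(mod_args, names(formals(model_options)), "model")
  opts <- tryCatch(do.call(model_options, mod_args),
                   error = function(e) schema_error("model",
                                                    conditionMessage(e)))

  run_args <- cfg$run %||% list()
  check_known(run_args, c("burn_in_years", "horizon_years", "n_runs", "seed"),
              "run")
  run <- list(burn_in_years = run_args$burn_in_years %||% dyn$burn_in_years,
              horizon_years = run_args$horizon_years %||% dyn$horizon_years,
              n_runs = run_args$n_runs %||% 80L,
              seed = run_args$seed %||% ccfg$seed)
  check_num(run$burn_in_years, "run.burn_in_years", 0, 1000)
  check_num(run$horizon_years, "run.horizon_years", 0, 1000)
  check_num(run$n_runs, "run.n_runs", 1, 1e6)

  ints <- list()
  if (!is.null(cfg$interventions)) {
    if (!is.list(cfg$interventions))
      schema_error("interventions", "must be a list")
    for (i in seq_along(cfg$interventions)) {
      ia <- cfg$interventions[[i]]
      pth <- paste0("interventions[", i, "]")
      check_known(ia, names(formals(intervention_spec)), pth)
      if (is.null(ia$type)) schema_error(pth, "missing type")
      ints[[i]] <- tryCatch(do.call(intervention_spec, ia),
                            error = function(e)
                              schema_error(pth, conditionMessage(e)))
    }
  }
  structure(list(city_config = ccfg, scores = scores, dyn = dyn,
                 opts = opts, run = run, interventions = ints),
            class = "sport_scenario")
}

#' Read and validate a scenario configuration file
#'
#' @param path a YAML (or JSON) scenario file
#' @return a validated `sport_scenario` (see [validate_scenario()])
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  validate_scenario(cfg %||% list())
}

#' Fully resolved parameter set with provenance labels
#'
#' Every shipped default traces either to a published value or to a
#' labelled assumption/reconstruction of this package; the echo makes
#' that explicit for a run's output directory.
#'
#' @param scenario a `sport_scenario`
#' @return a nested list of `value`/`source` pairs
#' @export
resolved_config <- function(scenario) {
  v <- function(value, source) list(value = value, source = source)
  sc <- scenario$scores; dyn <- scenario$dyn; cc <- scenario$city_config
  list(
    scores = list(
      mean_frequency = v(sc$mean_frequency, "published calibrated value"),
      age = v(sc$age, "published calibrated values"),
      sex = v(sc$sex, "published calibrated values"),
      income = v(sc$income, "published calibrated values"),
      price = v(sc$price, "published estimate (0.85 expensive)"),
      distance_decay = v(sc$distance_decay, "published calibrated values"),
      education_effect = v(sc$education_effect,
                           "published intervention assumption")),
    dynamics = list(
      quit_prob = v(dyn$quit_prob, "published national rates"),
      freq_increase_prob = v(dyn$freq_increase_prob, "published rate"),
      freq_decrease_prob = v(dyn$freq_decrease_prob, "published rate"),
      multi_sport_adjust_prob = v(dyn$multi_sport_adjust_prob,
                                  "stated assumption (0.5)"),
      weekly_start_fraction = v(dyn$weekly_start_fraction,
                                "package assumption"),
      death_schedule = v(c(a = dyn$death_a, b = dyn$death_b),
                         "package assumption (Gompertz-like)"),
      migration_rate = v(dyn$migration_rate, "package assumption")),
    city = list(
      aggregates = v(cc[c("population_size", "n_neighborhoods",
                          "mean_age", "fraction_female")],
                     "published city aggregates"),
      income_fractions = v(cc$income_fractions, "published city aggregates"),
      facilities = v(cc[c("n_fitness_locations", "n_club_locations",
                          "n_fitness_open", "n_club_open",
                          "fraction_expensive_fitness",
                          "fraction_expensive_club")],
                     "published city aggregates"),
      tendency = v(c(mean = cc$tendency_mean, var = cc$tendency_var),
                   "published best-fit Gamma (mean 1, variance 0.5)"),
      safety_cohesion = v(c(cc$safety_mean, cc$cohesion_mean),
                          "package assumption (synthetic stand-in)"),
      sorting_strength = v(cc$sorting_strength,
                           "package assumption (synthetic stand-in)")),
    model = list(
      social_influence = v("1 + share of participating neighbors within 50 m",
                           "package reconstruction"),
      preference_score = v("price x accessibility",
                           "package reconstruction"),
      facility_demand = v("unserved tendency / (1 + local supply)",
                          "package reconstruction")),
    run = lapply(scenario$run, function(x) v(x, "scenario config")))
}
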