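# Shared fixtures: all built in code, no files.

tiny_config <- function(..., seed = 1L) {
  defaults <- list(grid_rows = 40L, grid_cols = 40L, n_neighborhoods = 5L,
                   population_size = 400L, n_fitness_locations = 6L,
                   n_club_locations = 6L, n_fitness_open = 2L,
                   n_club_open = 2L, sorting_strength = 0.1, seed = seed)
  do.call(city_config, utils::modifyList(defaults, list(...)))
}

tiny_city <- function(..., seed = 1L) generate_city(tiny_config(..., seed = seed))

# A one-neighbourhood city sized for a hand-built population.
flat_city <- function(n = 10L, seed = 1L, n_open = 1L, n_loc = 3L) {
  generate_city(city_config(grid_rows = 30L, grid_cols = 30L,
                            n_neighborhoods = 1L, population_size = n,
                            n_fitness_locations = n_loc,
                            n_club_locations = n_loc,
                            n_fitness_open = n_open, n_club_open = n_open,
                            sorting_strength = 0, seed = seed))
}

# Hand-built population table (one neighbourhood, explicit attributes).
make_pop <- function(n, income = "high", sex = "male", age = 30,
                     t0 = 1, row = NULL, col = NULL, grid = 30L) {
  if (is.null(row)) row <- ((seq_len(n) - 1L) %% grid) + 1L
  if (is.null(col)) col <- ((seq_len(n) - 1L) %/% grid) + 1L
  data.table::data.table(
    id = seq_len(n), neighborhood = 1L,
    cell = row + (col - 1L) * grid, row = row, col = col,
    age = rep_len(age, n), sex = rep_len(sex, n),
    income = rep_len(income, n), initial_tendency = rep_len(t0, n),
    education_boost = 1)
}

# Homogeneous single-category state with all scores neutral: the start
# rate is exactly `rate` per year for every agent.
homog_state <- function(n = 2000L, rate = 0.5, quit = 0.2, seed = 7L,
                        grid = 60L) {
  city <- generate_city(city_config(
    grid_rows = grid, grid_cols = grid, n_neighborhoods = 2L,
    population_size = n, n_fitness_locations = 2L, n_club_locations = 2L,
    n_fitness_open = 1L, n_club_open = 1L, tendency_var = 0,
    sorting_strength = 0, seed = seed))
  sc <- score_table(mean_frequency = rate,
                    age = c(young = 1, middle = 1, old = 1),
                    sex = c(male = 1, female = 1),
                    income = c(high = 1, middle = 1, low = 1))
  dyn <- dynamics_params(quit_prob = c(fitness = 0, club = 0,
                                       self_organized = quit),
                         migration_rate = 0, death_a = 0,
                         facility_turnover = FALSE)
  opts <- model_options(social_influence = FALSE,
                        categories = "self_organized")
  st <- new_state(city, scores = sc, dyn = dyn, opts = opts, seed = seed)
  st$safety[] <- 1
  st$cohesion[] <- 1
  st
}

run_months <- function(state, months) {
  for (m in seq_len(months)) {
    step_month(state)
    if (state$month %% 12L == 0L) annual_update(state)
  }
  invisible(state)
}
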