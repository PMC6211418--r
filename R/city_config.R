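#' Configuration of the synthetic city
#'
#' Defaults reproduce the published aggregate description of the study
#' city: 88 neighbourhoods, 173,567 adults aged 18-85 with mean age 46,
#' 49% female, a 41/40/19% low/middle/high income split, 305 fitness and
#' 98 sports-club designated locations, 30 fitness centres and 158 club
#' facilities initially open, and 37%/40% of fitness/club facilities
#' expensive. The real city's registry and GIS inputs are not public, so
#' this generator is an explicit stand-in that matches those aggregates,
#' not a reconstruction of the actual map.
#'
#' Note one inconsistency in the published aggregates: 158 initially open
#' club facilities exceed the 98 designated club locations. Since a
#' location hosts at most one open facility, the generator creates
#' `max(n_locations, n_open)` locations per kind (158 for clubs under the
#' defaults).
#'
#' @param grid_rows,grid_cols grid size in 10 m cells (default 600 x 600,
#'   i.e. 36 km^2).
#' @param cell_size cell edge length in metres (fixed at 10).
#' @param n_neighborhoods number of contiguous neighbourhoods.
#' @param population_size number of adult residents.
#' @param age_range inclusive adult age range in years.
#' @param mean_age city mean age in years.
#' @param fraction_female city share of women.
#' @param income_fractions named fractions `low`, `middle`, `high`; must
#'   sum to 1.
#' @param n_fitness_locations,n_club_locations designated facility
#'   locations per kind.
#' @param n_fitness_open,n_club_open facilities open at simulation start.
#' @param fraction_expensive_fitness,fraction_expensive_club share of
#'   facilities priced "expensive".
#' @param safety_mean,safety_concentration,cohesion_mean,cohesion_concentration
#'   Beta parameters (mean/concentration) of the per-neighbourhood
#'   perceived safety and social cohesion scores on \[0, 1\].
#' @param sorting_strength nonnegative knob for demographic clustering
#'   across neighbourhoods; 0 gives every neighbourhood the city aggregate
#'   mix, larger values Dirichlet-disperse the neighbourhood mixes
#'   (concentration `1 / sorting_strength`) while keeping the
#'   population-weighted aggregates exact.
#' @param tendency_mean,tendency_var mean and variance of the Gamma
#'   distribution of the initial tendency (default mean 1, variance 0.5,
#'   i.e. shape 2 and scale 0.5). `tendency_var = 0` gives everyone the
#'   mean (used by analytic-oracle tests).
#' @param population_scale optional factor in (0, 1\] that shrinks the
#'   population, facility counts and grid area proportionally for
#'   desk-scale experiments; per-capita rate parameters are unaffected and
#'   the number of neighbourhoods is kept, so spatial densities stay
#'   comparable.
#' @param seed integer seed; the city (and its stored per-neighbourhood
#'   resident allocation) is deterministic given the full config.
#' @return an object of class `city_config`
#' @examples
#' cfg <- city_config(population_scale = 0.01)
#' cfg$population_size
#' @export
city_config <- function(grid_rows = 600L, grid_cols = 600L, cell_size = 10,
                        n_neighborhoods = 88L,
                        population_size = 173567L,
                        age_range = c(18, 85), mean_age = 46,
                        fraction_female = 0.49,
                        income_fractions = c(low = 0.41, middle = 0.40,
                                             high = 0.19),
                        n_fitness_locations = 305L, n_club_locations = 98L,
                        n_fitness_open = 30L, n_club_open = 158L,
                        fraction_expensive_fitness = 0.37,
                        fraction_expensive_club = 0.40,
                        safety_mean = 0.65, safety_concentration = 10,
                        cohesion_mean = 0.65, cohesion_concentration = 10,
                        sorting_strength = 0.1,
                        tendency_mean = 1, tendency_var = 0.5,
                        population_scale = 1, seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size = cell_size,
              n_neighborhoods = as.integer(n_neighborhoods),
              population_size = as.integer(population_size),
              age_range = age_range, mean_age = mean_age,
              fraction_female = fraction_female,
              income_fractions = income_fractions,
              n_fitness_locations = as.integer(n_fitness_locations),
              n_club_locations = as.integer(n_club_locations),
              n_fitness_open = as.integer(n_fitness_open),
              n_club_open = as.integer(n_club_open),
              fraction_expensive_fitness = fraction_expensive_fitness,
              fraction_expensive_club = fraction_expensive_club,
              safety_mean = safety_mean,
              safety_concentration = safety_concentration,
              cohesion_mean = cohesion_mean,
              cohesion_concentration = cohesion_concentration,
              sorting_strength = sorting_strength,
              tendency_mean = tendency_mean, tendency_var = tendency_var,
              population_scale = population_scale,
              seed = as.integer(seed))
  if (population_scale <= 0 || population_scale > 1)
    stop("configuration error: population_scale must be in (0, 1]",
         call. = FALSE)
  if (population_scale < 1) {
    s <- population_scale
    cfg$population_size <- max(1L, as.integer(round(cfg$population_size * s)))
    cfg$n_fitness_locations <- max(1L, as.integer(round(cfg$n_fitness_locations * s)))
    cfg$n_club_locations <- max(1L, as.integer(round(cfg$n_club_locations * s)))
    cfg$n_fitness_open <- max(1L, as.integer(round(cfg$n_fitness_open * s)))
    cfg$n_club_open <- max(1L, as.integer(round(cfg$n_club_open * s)))
    cfg$grid_rows <- max(20L, as.integer(round(cfg$grid_rows * sqrt(s))))
    cfg$grid_cols <- max(20L, as.integer(round(cfg$grid_cols * sqrt(s))))
  }
  validate_city_config(cfg)
  structure(cfg, class = "city_config")
}

validate_city_config <- function(cfg) {
  err <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$cell_size != 10) err("cell_size is fixed at 10 m")
  if (cfg$grid_rows < 1 || cfg$grid_cols < 1) err("grid must be nonempty")
  if (cfg$n_neighborhoods < 1) err("need at least one neighborhood")
  if (cfg$n_neighborhoods > cfg$grid_rows * cfg$grid_cols)
    err("n_neighborhoods exceeds the number of grid cells")
  f <- cfg$income_fractions
  if (!all(c("low", "middle", "high") %in% names(f)))
    err("income_fractions needs entries low, middle, high")
  if (abs(sum(f) - 1) > 1e-9) err("income_fractions must sum to 1")
  fr <- c(f, cfg$fraction_female, cfg$fraction_expensive_fitness,
          cfg$fraction_expensive_club)
  if (any(fr < 0) || any(fr > 1)) err("all fractions must lie in [0, 1]")
  if (cfg$mean_age <= cfg$age_range[1] || cfg$mean_age >= cfg$age_range[2])
    err("mean_age must lie strictly inside age_range")
  if (cfg$population_size < 1) err("population_size must be positive")
  if (cfg$n_fitness_open < 0 || cfg$n_club_open < 0)
    err("open facility counts must be nonnegative")
  if (cfg$sorting_strength < 0) err("sorting_strength must be nonnegative")
  if (cfg$tendency_mean <= 0 || cfg$tendency_var < 0)
    err("tendency distribution needs positive mean and nonnegative variance")
  for (nm in c("safety_mean", "cohesion_mean"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1) err(nm, " must lie in (0, 1)")
  invisible(cfg)
}
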