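# Helper: a state with three open fitness centres and hand-set membership
# counts.
three_fitness_state <- function(members = c(5L, 2L, 9L), seed = 2L) {
  city <- generate_city(city_config(
    grid_rows = 40L, grid_cols = 40L, n_neighborhoods = 4L,
    population_size = sum(members) + 20L, n_fitness_locations = 6L,
    n_club_locations = 3L, n_fitness_open = 3L, n_club_open = 1L,
    sorting_strength = 0, seed = seed))
  st <- new_state(city, seed = seed)
  fit_ids <- st$fcs$id[st$fcs$kind == 1L]
  i <- 1L
  for (j in seq_along(members)) {
    take <- seq(i, i + members[j] - 1L)
    st$stat[take, 1L] <- 1L
    st$fac[take, 1L] <- fit_ids[j]
    i <- i + members[j]
  }
  list(state = st, fit_ids = fit_ids)
}

test_that("the facility with the fewest members closes and members re-select", {
  x <- three_fitness_state(c(5L, 2L, 9L))
  st <- x$state
  st$month <- 12L
  victim <- x$fit_ids[2]
  close_weakest(st, "fitness")
  expect_false(st$fcs$open[match(victim, st$fcs$id)])
  # location vacated
  loc <- match(st$fcs$loc_id[match(victim, st$fcs$id)], st$locs$id)
  expect_false(st$locs$occupied[loc])
  # every former member now belongs to exactly one open facility
  open_ids <- st$fcs$id[st$fcs$open & st$fcs$kind == 1L]
  held <- st$fac[st$stat[, 1L] > 0L, 1L]
  expect_true(all(held %in% open_ids))
  expect_identical(sum(st$stat[, 1L] > 0L), 16L)  # closures never delete people
  ev <- facility_events(st)
  expect_identical(ev$event[1], "close")
  expect_identical(ev$facility_id[1], victim)
})

test_that("protected facilities never close; next-fewest goes instead", {
  x <- three_fitness_state(c(5L, 2L, 9L))
  st <- x$state
  st$month <- 12L
  idx2 <- match(x$fit_ids[2], st$fcs$id)
  st$fcs$protected_until[idx2] <- 600L
  close_weakest(st, "fitness")
  expect_true(st$fcs$open[idx2])                         # protected survives
  expect_false(st$fcs$open[match(x$fit_ids[1], st$fcs$id)])  # 5 < 9 closes
})

test_that("with everything protected no closure happens and is logged", {
  x <- three_fitness_state()
  st <- x$state
  st$month <- 12L
  st$fcs$protected_until[] <- 600L
  n_open <- sum(st$fcs$open)
  close_weakest(st, "fitness")
  expect_identical(sum(st$fcs$open), n_open)
  expect_identical(facility_events(st)$event[1], "no_closure_all_protected")
})

test_that("openings go to the highest-demand neighborhood (brute-force oracle)", {
  city <- generate_city(city_config(
    grid_rows = 60L, grid_cols = 60L, n_neighborhoods = 6L,
    population_size = 900L, n_fitness_locations = 12L,
    n_club_locations = 4L, n_fitness_open = 2L, n_club_open = 2L,
    sorting_strength = 0.1, seed = 9L))
  st <- new_state(city, seed = 9L)
  run_months(st, 6L)
  # brute-force demand: unserved base tendency over (1 + local supply)
  tend <- current_tendency(st)  # refreshes state$base and state$si
  base_si <- st$base * st$si
  open_fit <- which(st$fcs$open & st$fcs$kind == 1L)
  loc_nb <- st$locs$nbhd[match(st$fcs$loc_id[open_fit], st$locs$id)]
  dem <- vapply(seq_len(6L), function(nb) {
    res <- which(st$nbhd == nb & st$stat[, 1L] == 0L)
    sum(base_si[res]) / (1 + sum(loc_nb == nb))
  }, 0)
  vac_nb <- unique(st$locs$nbhd[!st$locs$occupied & st$locs$kind == 1L])
  oracle_nb <- vac_nb[which.max(dem[vac_nb])]
  expect_equal(sportabm:::neighborhood_demand(st, 1L), dem)
  n_before <- sum(st$fcs$open & st$fcs$kind == 1L)
  open_best(st, "fitness")
  ev <- facility_events(st)
  opened <- ev[ev$event == "open", ]
  expect_identical(opened$neighborhood_id[nrow(opened)], oracle_nb)
  expect_identical(sum(st$fcs$open & st$fcs$kind == 1L), n_before + 1L)
})

test_that("no vacancy anywhere means no opening", {
  # clubs: all designated locations occupied at start under the defaults
  city <- generate_city(city_config(
    grid_rows = 40L, grid_cols = 40L, n_neighborhoods = 3L,
    population_size = 200L, n_fitness_locations = 3L, n_club_locations = 2L,
    n_fitness_open = 1L, n_club_open = 2L, sorting_strength = 0, seed = 4L))
  st <- new_state(city, seed = 4L)
  n_before <- sum(st$fcs$open & st$fcs$kind == 2L)
  open_best(st, "club")
  expect_identical(sum(st$fcs$open & st$fcs$kind == 2L), n_before)
  expect_identical(facility_events(st)$event[1], "no_opening_no_vacancy")
})

test_that("default turnover keeps per-kind open counts time-invariant", {
  city <- tiny_city(seed = 6L)
  st <- new_state(city, scores = score_table(mean_frequency = 8), seed = 6L)
  counts <- function() c(sum(st$fcs$open & st$fcs$kind == 1L),
                         sum(st$fcs$open & st$fcs$kind == 2L))
  before <- counts()
  for (m in 1:36) {
    step_month(st)
    if (st$month %% 12L == 0L) {
      annual_update(st)
      expect_identical(counts(), before)
    }
  }
})

test_that("with closures suppressed, facilities accumulate until locations run out", {
  city <- tiny_city(seed = 8L)  # 6 fitness locations, 2 open
  st <- new_state(city, seed = 8L)
  st$fcs$protected_until[] <- 10000L  # suppress closures
  n_open <- function() sum(st$fcs$open & st$fcs$kind == 1L)
  expect_identical(n_open(), 2L)
  for (y in 1:6) {
    st$month <- 12L * y
    annual_facility_turnover(st)
    st$fcs$protected_until[] <- 10000L
  }
  expect_identical(n_open(), 6L)  # saturated at the designated locations
})

test_that("Poisson turnover closes about one facility per kind-year", {
  city <- generate_city(city_config(
    grid_rows = 50L, grid_cols = 50L, n_neighborhoods = 4L,
    population_size = 300L, n_fitness_locations = 40L,
    n_club_locations = 40L, n_fitness_open = 15L, n_club_open = 15L,
    sorting_strength = 0, seed = 10L))
  st <- new_state(city, dyn = dynamics_params(poisson_turnover = TRUE),
                  seed = 10L)
  years <- 150L
  for (y in seq_len(years)) {
    st$month <- 12L * y
    annual_facility_turnover(st)
  }
  ev <- facility_events(st)
  rate <- sum(ev$event == "close") / (2 * years)   # per kind-year
  expect_lt(abs(rate - 1), 3 / sqrt(2 * years))
})
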