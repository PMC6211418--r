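education_state <- function(n = 10000L, participating = 0L, seed = 3L) {
  city <- generate_city(city_config(
    grid_rows = 120L, grid_cols = 120L, n_neighborhoods = 4L,
    population_size = n, n_fitness_locations = 8L, n_club_locations = 8L,
    n_fitness_open = 2L, n_club_open = 2L, sorting_strength = 0.1,
    seed = seed))
  st <- new_state(city, seed = seed)
  if (participating > 0L) st$stat[seq_len(participating), 3L] <- 1L
  st
}

test_that("health education boosts exactly floor(reach x non-participants)", {
  st <- education_state(10000L, participating = 0L)
  apply_health_education(st, intervention_spec("health_education",
                                               education_reach = 0.15))
  expect_identical(sum(st$edu == 1.5), 1500L)
  expect_identical(sum(st$edu != 1), 1500L)
})

test_that("education never targets participants and respects degenerate params", {
  st <- education_state(2000L, participating = 500L)
  apply_health_education(st, intervention_spec("health_education",
                                               education_reach = 0.2))
  expect_true(all(st$edu[seq_len(500L)] == 1))     # participants untouched
  expect_identical(sum(st$edu > 1), 300L)  # floor(0.2 * 1500)
  st2 <- education_state(1000L)
  apply_health_education(st2, intervention_spec("health_education",
                                                education_reach = 0))
  expect_true(all(st2$edu == 1))
  st3 <- education_state(1000L)
  tend_before <- current_tendency(st3)
  apply_health_education(st3, intervention_spec("health_education",
                                                education_reach = 0.5,
                                                education_effect = 1))
  expect_equal(current_tendency(st3), tend_before)
})

test_that("price reduction leaves no expensive facility and never lowers tendencies", {
  city <- tiny_city(seed = 12L)
  st <- new_state(city, seed = 12L)
  expect_gt(sum(!st$fcs$cheap[st$fcs$open]), 0L)
  before <- current_tendency(st)
  apply_price_reduction(st)
  expect_identical(sum(!st$fcs$cheap[st$fcs$open]), 0L)
  after <- current_tendency(st)
  ok <- !is.na(before) & !is.na(after)
  expect_true(all(after[ok] >= before[ok] - 1e-12))
  # all-cheap baseline: a second application is a no-op
  snapshot <- list(cheap = st$fcs$cheap, prefb = st$prefb)
  apply_price_reduction(st)
  expect_identical(st$fcs$cheap, snapshot$cheap)
  expect_identical(st$prefb, snapshot$prefb)
})

test_that("availability targets the lowest-participation neighborhoods", {
  city <- generate_city(city_config(
    grid_rows = 80L, grid_cols = 80L, n_neighborhoods = 10L,
    population_size = 2000L, n_fitness_locations = 80L,
    n_club_locations = 80L, n_fitness_open = 3L, n_club_open = 3L,
    sorting_strength = 0.1, seed = 15L))  # seed chosen so every
  # neighborhood has vacant designated locations of both kinds
  st <- new_state(city, scores = score_table(mean_frequency = 6), seed = 15L)
  run_months(st, 24L)
  st_n <- sum(st$fcs$open)
  # brute-force ranking oracle
  act <- rowSums(st$stat > 0L) > 0L
  pf <- vapply(1:10, function(nb) mean(act[st$nbhd == nb]), 0)
  oracle <- order(pf, 1:10)[1:3]
  n_ev_pre <- length(st$events)
  apply_availability(st, intervention_spec("availability",
                                           availability_n_neighborhoods = 3L))
  ev <- facility_events(st)[-seq_len(n_ev_pre), ]
  opened <- ev[ev$event == "open", ]
  expect_identical(nrow(opened), 6L)             # 3 neighborhoods x 2 kinds
  expect_setequal(unique(opened$neighborhood_id), oracle)
  expect_identical(sum(st$fcs$open), st_n + 6L)
  new_rows <- match(opened$facility_id, st$fcs$id)
  expect_true(all(st$fcs$cheap[new_rows]))
  expect_true(all(st$fcs$protected_until[new_rows] == st$month + 120L))
})

test_that("availability with n = 0 and exhausted vacancies degrades gracefully", {
  city <- tiny_city(seed = 2L)
  st <- new_state(city, seed = 2L)
  n_before <- sum(st$fcs$open)
  apply_availability(st, intervention_spec("availability",
                                           availability_n_neighborhoods = 0L))
  expect_identical(sum(st$fcs$open), n_before)
  # occupy everything, then ask for more: warnings, no crash
  for (k in 1:2) {
    vac <- which(!st$locs$occupied & st$locs$kind == k)
    for (v in vac) sportabm:::open_at(st, v, k, TRUE, NA_integer_)
  }
  w <- capture_warnings(
    apply_availability(st, intervention_spec("availability",
                                             availability_n_neighborhoods = 2L)))
  expect_true(all(grepl("no vacant", w)))
  expect_identical(length(w), 4L)  # 2 neighborhoods x 2 kinds, all full
})

test_that("safety raises only below-target neighborhoods", {
  city <- generate_city(city_config(
    grid_rows = 30L, grid_cols = 30L, n_neighborhoods = 3L,
    population_size = 60L, n_fitness_locations = 3L, n_club_locations = 3L,
    n_fitness_open = 1L, n_club_open = 1L, sorting_strength = 0, seed = 5L))
  st <- new_state(city, seed = 5L)
  st$safety <- c(0.4, 0.6, 0.8)
  apply_safety(st, intervention_spec("safety", safety_target = "city_mean"))
  expect_equal(st$safety, c(0.6, 0.6, 0.8))
  # already at or above target: no-op
  apply_safety(st, intervention_spec("safety", safety_target = "city_mean"))
  expect_equal(st$safety, c(2 / 30 + 0.6, 2 / 30 + 0.6, 0.8),
               tolerance = 1e-12)
  st$safety <- c(0.4, 0.6, 0.8)
  apply_safety(st, intervention_spec("safety", safety_target = "fixed_value",
                                     safety_value = 0.75))
  expect_equal(min(st$safety), 0.75)
  st$safety <- c(0.4, 0.6, 0.8)
  apply_safety(st, intervention_spec("safety",
                                     safety_target = "max_neighborhood"))
  expect_equal(st$safety, c(0.8, 0.8, 0.8))
})

test_that("combined equals the sequential composition of the four singles", {
  mk <- function() {
    city <- tiny_city(seed = 31L)
    st <- new_state(city, scores = score_table(mean_frequency = 6),
                    seed = 31L)
    run_months(st, 13L)
    st
  }
  a <- mk(); b <- mk()
  spec <- intervention_spec("combined")
  suppressWarnings(apply_combined(a, spec))
  suppressWarnings({
    apply_health_education(b, spec)
    apply_price_reduction(b, spec)
    apply_availability(b, spec)
    apply_safety(b, spec)
  })
  expect_identical(a$edu, b$edu)
  expect_identical(a$safety, b$safety)
  expect_identical(a$fcs, b$fcs)
  expect_identical(a$locs, b$locs)
  expect_identical(a$prefb, b$prefb)
})

test_that("no intervention ever lowers any individual's tendency", {
  for (type in c("health_education", "price", "availability", "safety",
                 "combined")) {
    city <- tiny_city(seed = 17L)
    st <- new_state(city, scores = score_table(mean_frequency = 6),
                    seed = 17L)
    run_months(st, 12L)
    before <- current_tendency(st)
    suppressWarnings(apply_intervention(st, intervention_spec(type)))
    after <- current_tendency(st)
    ok <- !is.na(before) & !is.na(after)
    expect_true(all(after[ok] >= before[ok] - 1e-12))
    # a facility signal can only appear, never vanish
    expect_true(all(!is.na(after[!is.na(before)])))
  }
})

test_that("a zero-reach education intervention reproduces the counterfactual exactly", {
  city <- tiny_city(seed = 23L)
  base <- simulate_run(city, 3, seed = 40L)
  noop <- simulate_run(city, 3, seed = 40L,
                       interventions = intervention_spec(
                         "health_education", education_reach = 0),
                       intervention_month = 12L)
  expect_identical(attr(base, "metrics_matrix"), attr(noop, "metrics_matrix"))
})
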