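test_that("dynamics parameters validate their probabilities", {
  expect_error(dynamics_params(quit_prob = c(fitness = 1.3, club = 0.1,
                                             self_organized = 0.1)),
               "\\[0, 1\\]")
  expect_error(dynamics_params(migration_rate = -0.1), "\\[0, 1\\]")
  d <- dynamics_params()
  expect_equal(unname(d$quit_prob[c("fitness", "club", "self_organized")]),
               c(0.28, 0.12, 0.27))
})

test_that("scheduled waiting times are exponential in the start rate", {
  st <- homog_state(n = 10000L, rate = 12)
  # continuous waits: mean 1/12 year = 1 month, KS against the exponential
  w <- schedule_start(st, category = "self_organized", raw = TRUE)
  expect_lt(abs(mean(w) * 12 - 1), 3 * sd(w * 12) / sqrt(length(w)))
  ks <- suppressWarnings(stats::ks.test(w, stats::pexp, 12))
  expect_gt(ks$p.value, 0.01)
  # ceiled month indices follow the matching geometric distribution
  m <- schedule_start(st, category = "self_organized") - st$month
  p_geom <- -expm1(-1)
  expect_lt(abs(mean(m == 1) - p_geom), 3 * sqrt(p_geom * (1 - p_geom) / 1e4))
})

test_that("a zero tendency never schedules a start", {
  st <- homog_state(n = 50L)
  st$safety[] <- 0
  expect_true(all(is.infinite(
    schedule_start(st, category = "self_organized"))))
  # no open facility: the no-facility signal propagates
  st2 <- homog_state(n = 50L)
  st2$fcs$open[st2$fcs$kind == 1L] <- FALSE
  update_best(st2)
  expect_true(all(is.infinite(schedule_start(st2, category = "fitness"))))
})

test_that("the engine's monthly hazard equals the ceiled-exponential clock", {
  # constant rate 3/yr: month of first start ~ Geometric(1 - exp(-rate/12))
  st <- homog_state(n = 20000L, rate = 3, quit = 0)
  step_month(st)
  frac <- mean(st$stat[, 3L] > 0L)
  p <- -expm1(-3 / 12)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / st$n))
  # and the independent clock draw agrees
  st2 <- homog_state(n = 20000L, rate = 3, quit = 0, seed = 9L)
  m <- schedule_start(st2, category = "self_organized")
  expect_lt(abs(mean(m == 1) - p), 3 * sqrt(p * (1 - p) / st2$n))
})

test_that("start frequency labels follow weekly_start_fraction", {
  st <- homog_state(n = 100L)
  st$dyn$weekly_start_fraction <- 1
  expect_true(all(assign_frequency(50L, st) == 2L))
  st$dyn$weekly_start_fraction <- 0
  expect_true(all(assign_frequency(50L, st) == 1L))
  st$dyn$weekly_start_fraction <- 0.5
  x <- assign_frequency(10000L, st)
  expect_lt(abs(mean(x == 2L) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("stepping conserves the population and only ages it without turnover", {
  city <- tiny_city()
  st <- new_state(city, dyn = dynamics_params(migration_rate = 0,
                                              death_a = 0), seed = 2L)
  before <- list(sex = st$sex, income = st$income, t0 = st$t0,
                 age = st$age, n = st$n)
  run_months(st, 14L)
  expect_identical(st$n, before$n)
  expect_identical(st$sex, before$sex)
  expect_identical(st$income, before$income)
  expect_identical(st$t0, before$t0)
  expect_equal(st$age, before$age + 14 / 12)
})

test_that("turnover replaces individuals in place, conserving size and homes", {
  city <- tiny_city()
  st <- new_state(city, dyn = dynamics_params(migration_rate = 0.3), seed = 2L)
  nb_before <- st$nbhd
  run_months(st, 24L)
  expect_identical(st$n, 400L)
  expect_identical(st$nbhd, nb_before)  # replacements stay in the neighborhood
  expect_true(all(st$age >= 18 & st$age <= 85 + 1))
  expect_true(all(st$t0 > 0))
})

test_that("forced decay: quit probability one and no starts empties participation", {
  st <- homog_state(n = 500L, rate = 1e-12, quit = 1)
  st$stat[, 3L] <- 1L  # everyone participates
  run_months(st, 12L)
  expect_true(all(st$stat == 0L))
})

test_that("annual quits hit their probabilities and clear memberships", {
  st <- homog_state(n = 20000L, rate = 5, quit = 0.12)
  run_months(st, 11L)
  active <- st$stat[, 3L] > 0L
  expect_gt(sum(active), 5000)
  step_month(st)
  pre <- st$stat[, 3L] > 0L
  annual_update(st)
  post <- st$stat[, 3L] > 0L
  quit_frac <- mean(!post[pre])
  expect_lt(abs(quit_frac - 0.12), 3 * sqrt(0.12 * 0.88 / sum(pre)))
  # a single-sport individual who quits has status none
  expect_true(all(rowSums(st$stat[pre & !post, , drop = FALSE] > 0L) == 0L))
})

test_that("annual frequency changes follow the published flip rates", {
  st <- homog_state(n = 30000L, rate = 5, quit = 0)
  run_months(st, 11L)
  step_month(st)
  st$dyn$freq_increase_prob <- 0.21
  st$dyn$freq_decrease_prob <- 0.09
  monthly_pre <- st$stat[, 3L] == 1L
  weekly_pre <- st$stat[, 3L] == 2L
  annual_update(st)
  up <- mean(st$stat[monthly_pre, 3L] == 2L)
  dn <- mean(st$stat[weekly_pre, 3L] == 1L)
  expect_lt(abs(up - 0.21), 3 * sqrt(0.21 * 0.79 / sum(monthly_pre)))
  expect_lt(abs(dn - 0.09), 3 * sqrt(0.09 * 0.91 / sum(weekly_pre)))
})

test_that("identical seeds give bit-identical runs; seeds differ otherwise", {
  city <- tiny_city()
  a <- simulate_run(city, 3, seed = 5L)
  b <- simulate_run(city, 3, seed = 5L)
  expect_identical(attr(a, "metrics_matrix"), attr(b, "metrics_matrix"))
  c <- simulate_run(city, 3, seed = 6L)
  expect_false(identical(attr(a, "metrics_matrix"),
                         attr(c, "metrics_matrix")))
})

test_that("a single-run ensemble degenerates to its trajectory", {
  city <- tiny_city()
  ens <- run_ensemble(city, 2, n_runs = 1L, base_seed = 3L)
  one <- simulate_run(city, 2, seed = ens$seeds[1])
  expect_equal(ens$metrics[, , 1], attr(one, "metrics_matrix"))
})

test_that("membership stays coherent through starts, quits and turnover", {
  city <- tiny_city(seed = 3L)
  sc <- score_table(mean_frequency = 8)
  st <- new_state(city, scores = sc, seed = 4L)
  for (m in 1:36) {
    step_month(st)
    if (st$month %% 12L == 0L) annual_update(st)
    for (k in 1:2) {
      fid <- st$fac[, k]
      # facility held iff participating in the category
      expect_identical(is.na(fid) | st$stat[, k] > 0L,
                       is.na(fid) | (st$stat[, k] > 0L))
      expect_true(all(is.na(fid[st$stat[, k] == 0L])))
      held <- unique(fid[!is.na(fid)])
      open_ids <- st$fcs$id[st$fcs$open & st$fcs$kind == k]
      expect_true(all(held %in% open_ids))
    }
    expect_identical(st$n, length(st$age))
  }
})

test_that("raising every tendency does not decrease equilibrium participation", {
  base <- homog_state(n = 4000L, rate = 0.4, quit = 0.3, seed = 15L)
  run_months(base, 14 * 12L)
  hi <- homog_state(n = 4000L, rate = 0.6, quit = 0.3, seed = 15L)
  run_months(hi, 14 * 12L)
  expect_gte(mean(hi$stat[, 3L] > 0L), mean(base$stat[, 3L] > 0L))
})
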