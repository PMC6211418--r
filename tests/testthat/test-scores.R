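test_that("score table validates reference categories and positivity", {
  sc <- score_table()
  expect_equal(unname(sc$income[["low"]]), 0.428)
  expect_error(score_table(age = c(young = 2, middle = 0.2, old = 0.2)),
               "reference")
  expect_error(score_table(sex = c(male = 1, female = -1)), "positive")
  expect_error(score_table(mean_frequency = 0), "mean_frequency")
})

test_that("age groups use half-open boundaries", {
  expect_identical(age_group(c(18, 34.99, 35, 54.99, 55, 85)),
                   c("young", "young", "middle", "middle", "old", "old"))
})

test_that("accessibility decays exponentially with distance", {
  expect_equal(accessibility_score(0, 0.029), 1)
  expect_equal(accessibility_score(1000, 0.029), exp(-2.9))
  expect_equal(accessibility_score(1000, 0.027), exp(-2.7))
  d <- seq(0, 5000, by = 100)
  expect_true(all(diff(accessibility_score(d, 0.029)) < 0))
  expect_error(accessibility_score(-1, 0.029), "nonnegative")
  expect_error(accessibility_score(10, 0), "positive")
})

test_that("preference combines price and accessibility", {
  me <- list(row = 5, col = 5)
  expect_equal(preference_score(me, list(row = 5, col = 5, cheap = TRUE)), 1)
  expect_equal(preference_score(me, list(row = 5, col = 5, cheap = FALSE)),
               0.85)
  near <- list(row = 6, col = 5, cheap = TRUE)
  far <- list(row = 20, col = 5, cheap = TRUE)
  expect_gt(preference_score(me, near), preference_score(me, far))
})

test_that("facility selection equals brute-force argmax with lowest-id ties", {
  sc <- score_table()
  me <- list(row = 10, col = 10)
  single <- data.frame(id = 3L, kind = "fitness", row = 1, col = 1,
                       cheap = TRUE, open = TRUE)
  expect_identical(select_facility(me, single, sc, "fitness"), 3L)
  # two identical facilities -> lower id
  twin <- data.frame(id = c(7L, 2L), kind = "fitness", row = 4, col = 4,
                     cheap = FALSE, open = TRUE)
  expect_identical(select_facility(me, twin, sc, "fitness"), 2L)
  # closed and other-kind facilities are never selected
  mixed <- data.frame(id = 1:3, kind = c("fitness", "club", "fitness"),
                      row = c(10, 10, 30), col = c(10, 10, 30),
                      cheap = TRUE, open = c(FALSE, TRUE, TRUE))
  expect_identical(select_facility(me, mixed, sc, "fitness"), 3L)
  expect_identical(select_facility(me, mixed[mixed$kind == "club" &
                                               !mixed$open, ], sc, "club"),
                   NA_integer_)
  # randomized cases against an exhaustive oracle
  set.seed(42)
  for (case in 1:25) {
    nf <- sample(1:10, 1)
    fac <- data.frame(id = sample(100L, nf), kind = "club",
                      row = sample(30, nf, TRUE), col = sample(30, nf, TRUE),
                      cheap = sample(c(TRUE, FALSE), nf, TRUE), open = TRUE)
    ind <- list(row = sample(30, 1), col = sample(30, 1))
    pref <- vapply(seq_len(nf), function(i)
      preference_score(ind, fac[i, ], sc, "club"), 0)
    oracle <- min(fac$id[pref == max(pref)])
    expect_identical(select_facility(ind, fac, sc, "club"), oracle)
  }
})

test_that("social influence is 1 plus the participating-neighbor share", {
  pop <- data.frame(row = c(10, 10, 11, 12, 13),
                    col = c(10, 11, 10, 10, 10),
                    participating = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  si <- social_influence_score(pop)
  expect_equal(si[1], 1.25)  # 4 neighbours, 1 participating
  lone <- data.frame(row = c(1, 200), col = c(1, 200),
                     participating = c(FALSE, TRUE))
  expect_equal(social_influence_score(lone), c(1, 1))  # no one within 50 m
  all_in <- data.frame(row = rep(5, 4), col = 5:8,
                       participating = TRUE)
  expect_equal(social_influence_score(all_in), rep(2, 4))
  none_in <- transform(all_in, participating = FALSE)
  expect_equal(social_influence_score(none_in), rep(1, 4))
})

test_that("the engine stencil agrees with the brute-force social influence", {
  city <- flat_city(n = 300L)
  st <- new_state(city, population = make_pop(300L), seed = 3L)
  set.seed(8)
  st$stat[, 3L] <- sample(c(0L, 1L), 300L, TRUE)
  part <- st$stat[, 3L] > 0L
  fast <- sportabm:::si_fast(st, part)
  brute <- social_influence_score(
    data.frame(row = st$row, col = st$col, participating = part))
  expect_equal(fast, brute)
})

test_that("the tendency is the product of its factor scores", {
  expect_equal(tendency_score(1, 30, "male", "high"), 1)  # reference identity
  expect_equal(tendency_score(1, 45, "female", "low"),
               0.157 * 0.428 * 0.659)
  expect_equal(tendency_score(2, 45, "female", "low"),
               2 * tendency_score(1, 45, "female", "low"))
  # multiplicative separability: scaling one factor scales the output
  base <- tendency_score(1, 60, "female", "middle", safety = 0.5)
  expect_equal(tendency_score(1, 60, "female", "middle", safety = 0.25),
               base / 2)
  # facility categories are additionally damped by price x accessibility
  t_self <- tendency_score(1, 30, "male", "high")
  t_fit <- tendency_score(1, 30, "male", "high", category = "fitness",
                          price_score = 0.85, accessibility = 0.5)
  expect_lte(t_fit, t_self)
  expect_equal(t_fit, 0.85 * 0.5)
})

test_that("state-level tendencies agree with the pure formula and facility choice", {
  city <- tiny_city(seed = 21L)
  st <- new_state(city, opts = model_options(social_influence = FALSE),
                  seed = 13L)
  tend <- current_tendency(st)
  ft <- facilities_table(st)
  sc <- st$scores
  for (i in c(1L, 17L, 101L, 300L)) {
    ind <- list(row = st$row[i], col = st$col[i])
    for (k in 1:2) {
      kind <- c("fitness", "club")[k]
      fid <- select_facility(ind, ft, sc, kind)
      frow <- ft[ft$id == fid, ]
      expected <- tendency_score(
        st$t0[i], st$age[i], c("male", "female")[st$sex[i]],
        c("low", "middle", "high")[st$income[i]], sc, category = kind,
        safety = st$safety[st$nbhd[i]], cohesion = st$cohesion[st$nbhd[i]],
        price_score = ifelse(frow$cheap, 1, 0.85),
        accessibility = accessibility_score(
          10 * sqrt((ind$row - frow$row)^2 + (ind$col - frow$col)^2),
          sc$distance_decay[[kind]]))
      expect_equal(tend[i, k], expected)
    }
    expected_self <- tendency_score(
      st$t0[i], st$age[i], c("male", "female")[st$sex[i]],
      c("low", "middle", "high")[st$income[i]], sc,
      safety = st$safety[st$nbhd[i]], cohesion = st$cohesion[st$nbhd[i]])
    expect_equal(tend[i, 3L], expected_self)
  }
})
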