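# The monthly event loop.
#
# Waiting times to a start are exponential with rate = tendency x mean
# frequency (per year). Because tendencies are refreshed every month
# (environment changes take effect at the next step) and the exponential
# is memoryless, the engine fires starts with the exactly equivalent
# per-month probability 1 - exp(-rate / 12); a constant-rate agent's
# start month then follows the same distribution as the ceiled
# exponential clock drawn by schedule_start().

# Social influence via a disc stencil on the padded grid: per-cell agent
# counts are cumulated along rows so each stencil row-run is a difference
# of two prefix sums.
si_fast <- function(state, participating) {
  n <- state$n
  np <- state$Rp * state$Cp
  cn <- cumsum(tabulate(state$idx, nbins = np))
  cp <- cumsum(tabulate(state$idx[participating], nbins = np))
  idx <- state$idx
  dy <- state$stencil$dy; kx <- state$stencil$kx; Rp <- state$Rp
  nn <- numeric(n); pp <- numeric(n)
  for (j in seq_along(dy)) {
    off <- dy[j] * Rp
    hi <- idx + off + kx[j]
    lo <- idx + off - kx[j] - 1L
    nn <- nn + (cn[hi] - cn[lo])
    pp <- pp + (cp[hi] - cp[lo])
  }
  nn <- nn - 1                    # exclude self from the neighbour count
  pp <- pp - participating        # and from the participating count
  out <- rep.int(1, n)
  pos <- nn > 0
  out[pos] <- 1 + pp[pos] / nn[pos]
  out
}

# demographic base score (everything except social influence and the
# facility price x accessibility factors)
base_score <- function(state) {
  sc <- state$scores
  ag <- 1L + (state$age >= 35) + (state$age >= 55)
  agev <- c(sc$age[["young"]], sc$age[["middle"]], sc$age[["old"]])[ag]
  sexv <- c(sc$sex[["male"]], sc$sex[["female"]])[state$sex]
  incv <- c(sc$income[["low"]], sc$income[["middle"]],
            sc$income[["high"]])[state$income]
  state$t0 * state$edu * agev * sexv * incv *
    state$safety[state$nbhd] * state$cohesion[state$nbhd]
}

#' Current tendency of every individual
#'
#' Recomputes the full multiplicative tendency per category from the
#' current environment: facility-based categories include the price and
#' accessibility score of the currently best facility (`NA` where no
#' facility of the kind is open — the "no facility available" signal).
#'
#' @param state a `sport_state`
#' @return numeric matrix `n x 3` with columns [SPORT_CATEGORIES]
#' @export
current_tendency <- function(state) {
  base <- base_score(state)
  act <- state$stat > 0L
  if (state$opts$social_influence) {
    if (state$opts$si_mode == "any") {
      si <- si_fast(state, act[, 1L] | act[, 2L] | act[, 3L])
      simat <- cbind(si, si, si)
    } else {
      simat <- cbind(si_fast(state, act[, 1L]), si_fast(state, act[, 2L]),
                     si_fast(state, act[, 3L]))
    }
  } else simat <- matrix(1, state$n, 3L)
  state$si <- simat[, 1L]
  state$base <- base
  cbind(base * simat[, 1L] * state$prefb[, 1L],
        base * simat[, 2L] * state$prefb[, 2L],
        base * simat[, 3L])
}

#' Schedule a start time for individuals
#'
#' Draws the literal exponential waiting time `W ~ Exp(tendency x F)` (in
#' years, `F` the city mean frequency of sports per year) and returns the
#' month index at which the start would fire, ceiled to the next whole
#' month. A zero tendency or a missing facility yields `Inf` (no start
#' ever scheduled). The running engine uses the equivalent memoryless
#' monthly hazard instead, so that tendencies refresh each step.
#'
#' @param state a `sport_state`
#' @param ids individual indices (default: everyone)
#' @param category one of [SPORT_CATEGORIES]
#' @param raw if `TRUE`, return the continuous waiting times in years
#'   instead of the ceiled absolute month indices (used by
#'   distributional checks)
#' @return numeric vector of absolute month indices (possibly `Inf`),
#'   or waiting times in years when `raw = TRUE`
#' @export
schedule_start <- function(state, ids = seq_len(state$n),
                           category = "self_organized", raw = FALSE) {
  k <- match(match.arg(category, SPORT_CATEGORIES), SPORT_CATEGORIES)
  rate <- current_tendency(state)[ids, k] * state$scores$mean_frequency
  w <- rep.int(Inf, length(ids))
  ok <- !is.na(rate) & rate > 0
  w[ok] <- with_stream(state, "starts", rexp(sum(ok), rate[ok]))
  if (raw) w else state$month + ceiling(w * 12)
}

#' Draw start-frequency labels
#'
#' At the moment of starting, an individual is categorized into weekly
#' participation with probability `weekly_start_fraction`, else monthly.
#'
#' @param n number of draws
#' @param state a `sport_state` (supplies the probability and RNG stream)
#' @return integer vector: 2 = weekly, 1 = monthly
#' @export
assign_frequency <- function(n, state) {
  u <- with_stream(state, "frequency", runif(n))
  ifelse(u < state$dyn$weekly_start_fraction, 2L, 1L)
}

start_participation <- function(state, ids, k) {
  m <- length(ids)
  if (m == 0L) return(invisible(state))
  had_other <- rowSums(state$stat[ids, , drop = FALSE] > 0L) > 0L
  freq <- assign_frequency(m, state)
  state$stat[cbind(ids, rep.int(k, m))] <- freq
  if (k <= 2L)
    state$fac[cbind(ids, rep.int(k, m))] <- state$facb[cbind(ids, rep.int(k, m))]
  # starting an additional sport may compensate by dropping an existing
  # weekly habit to monthly (reconstruction; probability 0.5)
  adj <- with_stream(state, "frequency", runif(m)) <
    state$dyn$multi_sport_adjust_prob & had_other
  if (any(adj)) {
    done <- !adj
    for (j in setdiff(1:3, k)) {
      sel <- !done & state$stat[cbind(ids, rep.int(j, m))] == 2L
      if (any(sel)) {
        state$stat[cbind(ids[sel], rep.int(j, sum(sel)))] <- 1L
        done <- done | sel
      }
    }
  }
  invisible(state)
}

fire_starts <- function(state) {
  n <- state$n
  tend <- current_tendency(state)
  ftot <- state$scores$mean_frequency
  u <- with_stream(state, "starts", runif(3L * n))
  for (k in state$opts$categories_idx) {
    elig <- state$stat[, k] == 0L
    if (k <= 2L) elig <- elig & !is.na(state$facb[, k])
    p <- -expm1(-tend[, k] * ftot / 12)
    starters <- which(elig & u[(k - 1L) * n + seq_len(n)] < p)
    start_participation(state, starters, k)
  }
  invisible(state)
}

demographic_turnover <- function(state) {
  n <- state$n; dyn <- state$dyn
  cfg <- state$city$config
  nbt <- state$city$neighborhoods
  repl <- with_stream(state, "demography", {
    u <- runif(n)
    pdie <- 1 - (1 - pmin(dyn$death_a * exp(dyn$death_b * state$age), 0.5))^(1 / 12)
    pmig <- 1 - (1 - dyn$migration_rate)^(1 / 12)
    gone <- u < (pdie + pmig - pdie * pmig)
    if (dyn$death_a > 0 || dyn$migration_rate > 0)
      gone <- gone | state$age > cfg$age_range[2]
    ids <- which(gone)
    if (!length(ids)) NULL else {
      nb <- state$nbhd[ids]
      cell <- vapply(nb, function(b) {
        cb <- state$city$cells_by_nbhd[[b]]
        cb[sample.int(length(cb), 1L)]
      }, 0L)
      lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
      mf <- (nbt$mean_age[nb] - lo) / (hi - lo)
      age <- lo + (hi - lo) * rbeta(length(ids), 2, 2 * (1 - mf) / mf)
      sex <- 1L + (runif(length(ids)) < nbt$frac_female[nb])
      u2 <- runif(length(ids))
      income <- 1L + (u2 >= nbt$frac_low[nb]) +
        (u2 >= nbt$frac_low[nb] + nbt$frac_mid[nb])
      t0 <- draw_initial_tendency(length(ids), cfg$tendency_mean,
                                  cfg$tendency_var)
      list(ids = ids, cell = cell, age = age, sex = sex, income = income,
           t0 = t0)
    }
  })
  if (is.null(repl)) return(invisible(state))
  ids <- repl$ids
  state$age[ids] <- repl$age
  state$sex[ids] <- repl$sex
  state$income[ids] <- repl$income
  state$t0[ids] <- repl$t0
  state$edu[ids] <- 1
  state$row[ids] <- (repl$cell - 1L) %% state$city$nrow + 1L
  state$col[ids] <- (repl$cell - 1L) %/% state$city$nrow + 1L
  state$idx[ids] <- (state$row[ids] + state$pad) +
    (state$col[ids] + state$pad - 1L) * state$Rp
  state$stat[ids, ] <- 0L
  state$fac[ids, ] <- NA_integer_
  update_best(state, ids = ids)
  invisible(state)
}

#' Advance the simulation by one month
#'
#' In order: ages advance by 1/12 year; deaths, out-migration and the
#' over-age cap remove individuals, each replaced by a new
#' non-participating resident of the same neighbourhood (population size
#' is conserved); start events fire with the refreshed tendencies.
#' Annual events (quits, frequency changes, facility turnover) run
#' separately via [annual_update()].
#'
#' @param state a `sport_state`, modified in place
#' @return the state, invisibly
#' @export
step_month <- function(state) {
  state$month <- state$month + 1L
  state$age <- state$age + 1 / 12
  demographic_turnover(state)
  fire_starts(state)
  invisible(state)
}

#' Annual update: quits, frequency changes, facility turnover
#'
#' At the end of every simulated year, in fixed order: (1) each
#' participating individual quits each category with the category's
#' annual quitting probability (membership removed; a restart is governed
#' by the same start mechanism as a first start); quitting one of several
#' sports may compensate by upgrading a remaining monthly habit
#' (probability 0.5); (2) survivors change frequency, monthly to weekly
#' with probability 0.21 and weekly to monthly with 0.09; (3) facilities
#' turn over (one closure and one opening per kind, see
#' [annual_facility_turnover()]).
#'
#' @param state a `sport_state` whose month is a positive multiple of 12
#' @return the state, invisibly
#' @export
annual_update <- function(state) {
  if (state$month %% 12L != 0L)
    stop("annual_update requires a month divisible by 12")
  n <- state$n; dyn <- state$dyn
  qv <- c(dyn$quit_prob[["fitness"]], dyn$quit_prob[["club"]],
          dyn$quit_prob[["self_organized"]])
  uq <- with_stream(state, "quits", runif(3L * n))
  for (k in 1:3) {
    quitters <- which(state$stat[, k] > 0L &
                        uq[(k - 1L) * n + seq_len(n)] < qv[k])
    if (!length(quitters)) next
    state$stat[cbind(quitters, rep.int(k, length(quitters)))] <- 0L
    if (k <= 2L)
      state$fac[cbind(quitters, rep.int(k, length(quitters)))] <- NA_integer_
    rem <- state$stat[quitters, , drop = FALSE] > 0L
    has_rem <- rowSums(rem) > 0L
    if (any(has_rem)) {
      adj <- with_stream(state, "frequency", runif(length(quitters))) <
        dyn$multi_sport_adjust_prob & has_rem
      done <- !adj
      for (j in setdiff(1:3, k)) {
        sel <- !done & state$stat[cbind(quitters, rep.int(j, length(quitters)))] == 1L
        if (any(sel)) {
          state$stat[cbind(quitters[sel], rep.int(j, sum(sel)))] <- 2L
          done <- done | sel
        }
      }
    }
  }
  uf <- with_stream(state, "frequency", runif(3L * n))
  for (k in 1:3) {
    col <- state$stat[, k]
    ufk <- uf[(k - 1L) * n + seq_len(n)]
    up <- col == 1L & ufk < dyn$freq_increase_prob
    dn <- col == 2L & ufk < dyn$freq_decrease_prob
    col[up] <- 2L
    col[dn] <- 1L
    state$stat[, k] <- col
  }
  if (dyn$facility_turnover) annual_facility_turnover(state)
  invisible(state)
}
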