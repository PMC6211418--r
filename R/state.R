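# Simulation state: a classed environment holding the population as
# column vectors (fast in the monthly loop), the facility and location
# registers as lists of vectors, named RNG streams, and a metric log.
# Status codes per category: 0 none, 1 monthly, 2 weekly.

SEX_LEVELS <- c("male", "female")
INCOME_LEVELS <- c("low", "middle", "high")
METRIC_NAMES <- c("overall", "inc_low", "inc_mid", "inc_high",
                  "age_young", "age_middle", "age_old",
                  "sex_male", "sex_female",
                  "cat_fitness", "cat_club", "cat_self")

#' Create a simulation state
#'
#' Binds a city, a population (drawn from the city's neighbourhood mixes
#' if not supplied), the score table, the dynamics parameters and the
#' model options into a runnable state at month 0. Nobody participates at
#' creation; best-facility choices are precomputed.
#'
#' @param city a [generate_city()] result
#' @param population optional population table as from
#'   [generate_population()]
#' @param scores a [score_table()]
#' @param dyn a [dynamics_params()]
#' @param opts a [model_options()]
#' @param seed integer seed; fans out to the named RNG streams
#' @return an environment of class `sport_state`
#' @export
new_state <- function(city, population = NULL, scores = score_table(),
                      dyn = dynamics_params(), opts = model_options(),
                      seed = 1L) {
  stopifnot(inherits(city, "sport_city"))
  s <- new.env(parent = emptyenv())
  s$city <- city; s$scores <- scores; s$dyn <- dyn; s$opts <- opts
  s$rng <- rng_streams(seed)
  if (is.null(population))
    population <- generate_population(city, seed = stream_seed(seed, 1L))
  n <- nrow(population)
  s$n <- n
  s$month <- 0L
  s$id <- population$id
  s$nbhd <- as.integer(population$neighborhood)
  s$row <- as.integer(population$row)
  s$col <- as.integer(population$col)
  s$age <- as.numeric(population$age)
  s$sex <- match(population$sex, SEX_LEVELS)
  s$income <- match(population$income, INCOME_LEVELS)
  if (anyNA(s$sex) || anyNA(s$income))
    stop("population sex/income must use levels male/female and low/middle/high")
  s$t0 <- as.numeric(population$initial_tendency)
  s$edu <- as.numeric(population$education_boost)
  s$stat <- matrix(0L, n, 3L)
  s$fac <- matrix(NA_integer_, n, 2L)
  s$safety <- city$neighborhoods$safety
  s$cohesion <- city$neighborhoods$cohesion

  f <- city$facilities
  s$fcs <- list(id = as.integer(f$id), kind = match(f$kind, c("fitness", "club")),
                loc_id = as.integer(f$loc_id), row = as.integer(f$row),
                col = as.integer(f$col), cheap = as.logical(f$cheap),
                open = as.logical(f$open),
                protected_until = as.integer(f$protected_until))
  l <- city$locations
  s$locs <- list(id = as.integer(l$id), kind = match(l$kind, c("fitness", "club")),
                 row = as.integer(l$row), col = as.integer(l$col),
                 occupied = as.logical(l$occupied),
                 nbhd = city$cell2nbhd[l$row + (l$col - 1L) * city$nrow])
  s$frac_expensive <- c(city$config$fraction_expensive_fitness,
                        city$config$fraction_expensive_club)
  s$price_lock <- FALSE

  # padded grid geometry for the social-influence stencil
  pad <- as.integer(ceiling(opts$radius / 10))
  s$pad <- pad
  s$Rp <- city$nrow + 2L * pad
  s$Cp <- city$ncol + 2L * pad
  s$idx <- (s$row + pad) + (s$col + pad - 1L) * s$Rp
  rmax <- floor(opts$radius / 10)
  dys <- (-rmax):rmax
  kx <- floor(sqrt((opts$radius / 10)^2 - dys^2))
  s$stencil <- list(dy = dys, kx = as.integer(kx))
  s$si <- rep.int(1, n)
  s$base <- rep.int(NA_real_, n)

  s$facb <- matrix(NA_integer_, n, 2L)
  s$prefb <- matrix(NA_real_, n, 2L)
  update_best(s)
  s$events <- list()
  class(s) <- c("sport_state", "environment")
  s
}

#' Population table of a state
#'
#' @param state a `sport_state`
#' @return a `data.table` with demographics, current participation status
#'   per category (`none`/`monthly`/`weekly`) and chosen facility ids
#' @export
population_table <- function(state) {
  lv <- c("none", "monthly", "weekly")
  data.table::data.table(
    id = state$id, neighborhood = state$nbhd,
    row = state$row, col = state$col, age = state$age,
    sex = SEX_LEVELS[state$sex], income = INCOME_LEVELS[state$income],
    initial_tendency = state$t0, education_boost = state$edu,
    status_fitness = lv[state$stat[, 1L] + 1L],
    status_club = lv[state$stat[, 2L] + 1L],
    status_self_organized = lv[state$stat[, 3L] + 1L],
    facility_fitness = state$fac[, 1L], facility_club = state$fac[, 2L])
}

#' Facility table of a state
#'
#' @param state a `sport_state`
#' @return a `data.table` of all facilities ever opened, with open flag,
#'   price level, protection horizon and current member count
#' @export
facilities_table <- function(state) {
  mc1 <- members_count(state, 1L); mc2 <- members_count(state, 2L)
  nf <- length(state$fcs$id)
  mc <- integer(nf)
  for (i in seq_len(nf)) {
    m <- if (state$fcs$kind[i] == 1L) mc1 else mc2
    mc[i] <- if (state$fcs$id[i] <= length(m)) m[state$fcs$id[i]] else 0L
  }
  data.table::data.table(
    id = state$fcs$id, kind = c("fitness", "club")[state$fcs$kind],
    loc_id = state$fcs$loc_id, row = state$fcs$row, col = state$fcs$col,
    cheap = state$fcs$cheap, open = state$fcs$open,
    protected_until = state$fcs$protected_until, members = mc)
}

#' @export
print.sport_state <- function(x, ...) {
  cat("<sport_state> month", x$month, "-", x$n, "individuals,",
      sum(x$fcs$open), "open facilities\n")
  act <- x$stat > 0L
  cat(sprintf("  participation: %.1f%% (fitness %.1f%%, club %.1f%%, self %.1f%%)\n",
              100 * mean(act[, 1L] | act[, 2L] | act[, 3L]),
              100 * mean(act[, 1L]), 100 * mean(act[, 2L]),
              100 * mean(act[, 3L])))
  invisible(x)
}

# members of facility id per kind column (facility ids index tabulate bins)
members_count <- function(state, kind) {
  fid <- state$fac[, kind]
  fid <- fid[!is.na(fid)]
  nb <- if (length(state$fcs$id)) max(state$fcs$id) else 0L
  tabulate(fid, nbins = nb)
}

# Recompute each agent's best open facility and preference score for the
# given kinds (optionally only for a subset of agents). Facilities are
# scanned in increasing id order with strict improvement, so ties resolve
# to the lowest id.
update_best <- function(state, kinds = 1:2, ids = NULL) {
  ar <- if (is.null(ids)) state$row else state$row[ids]
  ac <- if (is.null(ids)) state$col else state$col[ids]
  m <- length(ar)
  pr_cheap <- state$scores$price[["cheap"]]
  pr_exp <- state$scores$price[["expensive"]]
  for (k in kinds) {
    beta <- state$scores$distance_decay[[k]]
    sel <- which(state$fcs$open & state$fcs$kind == k)
    sel <- sel[order(state$fcs$id[sel])]
    if (!length(sel)) {
      best <- rep.int(NA_real_, m); bid <- rep.int(NA_integer_, m)
    } else {
      best <- rep.int(-Inf, m); bid <- rep.int(NA_integer_, m)
      for (j in sel) {
        price <- if (state$fcs$cheap[j]) pr_cheap else pr_exp
        pref <- price * exp(-beta * sqrt((ar - state$fcs$row[j])^2 +
                                         (ac - state$fcs$col[j])^2))
        upd <- pref > best
        best[upd] <- pref[upd]
        bid[upd] <- state$fcs$id[j]
      }
    }
    if (is.null(ids)) {
      state$facb[, k] <- bid; state$prefb[, k] <- best
    } else {
      state$facb[ids, k] <- bid; state$prefb[ids, k] <- best
    }
  }
  invisible(state)
}

log_event <- function(state, event, kind, fac_id, nbhd, members) {
  state$events[[length(state$events) + 1L]] <- data.table::data.table(
    year = state$month %/% 12L, month = state$month, event = event,
    kind = c("fitness", "club")[kind],
    facility_id = as.integer(fac_id), neighborhood_id = as.integer(nbhd),
    members_at_event = as.integer(members))
  invisible(state)
}

#' Facility event log
#'
#' @param state a `sport_state`
#' @return a `data.table` of open/close events (year, month, event, kind,
#'   facility id, neighbourhood, members at the event)
#' @export
facility_events <- function(state) {
  if (!length(state$events))
    return(data.table::data.table(year = integer(), month = integer(),
                                  event = character(), kind = character(),
                                  facility_id = integer(),
                                  neighborhood_id = integer(),
                                  members_at_event = integer()))
  data.table::rbindlist(state$events)
}
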