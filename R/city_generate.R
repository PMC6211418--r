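# Synthetic city generation.
#
# The grid is partitioned into contiguous neighbourhoods by a seeded
# Voronoi tessellation (every cell joins its nearest seed cell; Euclidean
# Voronoi regions on a lattice are contiguous). Facility locations are
# scattered uniformly over cells, i.e. across neighbourhoods in proportion
# to area. Per-neighbourhood demographic mixes are Dirichlet-perturbed
# copies of the city aggregate whose population-weighted means are then
# restored exactly by iterative proportional fitting.

rdirichlet_rows <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Iterative proportional fitting: rescale the columns of a row-stochastic
# matrix until the weighted column means hit `target`, renormalising rows
# between passes. Rows with zero weight follow the scaling but do not
# constrain it.
ipf_match <- function(mat, w, target, tol = 1e-12, max_iter = 200L) {
  if (sum(w) == 0) return(mat)
  for (i in seq_len(max_iter)) {
    colw <- colSums(mat * w) / sum(w)
    if (max(abs(colw - target)) < tol) break
    mat <- mat * rep(target / colw, each = nrow(mat))
    mat <- mat / rowSums(mat)
  }
  mat
}

#' Generate a synthetic city
#'
#' Builds the gridded city described by a [city_config()]: a contiguous
#' neighbourhood partition with safety/cohesion scores, per-neighbourhood
#' demographic mixes whose population-weighted aggregates equal the
#' configured city aggregates, designated facility locations, and the
#' initially open facilities with their price levels. Deterministic given
#' the config (including its seed).
#'
#' @param config a [city_config()]
#' @return an object of class `sport_city`: a list with the grid size,
#'   the cell-to-neighbourhood map, a `neighborhoods` table, a
#'   `locations` table and a `facilities` table.
#' @examples
#' city <- generate_city(city_config(population_scale = 0.005, seed = 7))
#' nrow(city$neighborhoods)
#' @export
generate_city <- function(config = city_config()) {
  validate_city_config(config)
  with_seed(config$seed, generate_city_impl(config))
}

generate_city_impl <- function(cfg) {
  R <- cfg$grid_rows; C <- cfg$grid_cols
  ncell <- R * C
  nb <- cfg$n_neighborhoods

  # --- Voronoi partition over random seed cells -------------------------
  seed_cells <- sample.int(ncell, nb)
  sr <- (seed_cells - 1L) %% R + 1L
  sc <- (seed_cells - 1L) %/% R + 1L
  rr <- rep.int(seq_len(R), C)
  cc <- rep(seq_len(C), each = R)
  best_d <- rep.int(Inf, ncell)
  cell2nbhd <- integer(ncell)
  for (i in seq_len(nb)) {
    d <- (rr - sr[i])^2 + (cc - sc[i])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    cell2nbhd[upd] <- i
  }
  cells_by_nbhd <- split(seq_len(ncell), cell2nbhd)
  n_cells <- lengths(cells_by_nbhd)

  # --- residents allocated to neighbourhoods in proportion to area ------
  n_res <- as.integer(rmultinom(1L, cfg$population_size, prob = n_cells))

  # --- neighbourhood environment scores ---------------------------------
  bdraw <- function(m, k) rbeta(nb, m * k, (1 - m) * k)
  safety <- bdraw(cfg$safety_mean, cfg$safety_concentration)
  cohesion <- bdraw(cfg$cohesion_mean, cfg$cohesion_concentration)

  # --- demographic mixes -------------------------------------------------
  fr <- cfg$income_fractions[c("low", "middle", "high")]
  s <- cfg$sorting_strength
  if (s > 0) {
    inc <- rdirichlet_rows(nb, as.numeric(fr) / s)
    inc <- ipf_match(inc, n_res, as.numeric(fr))
    fem2 <- rdirichlet_rows(nb, c(cfg$fraction_female, 1 - cfg$fraction_female) * 2 / s)
    fem2 <- ipf_match(fem2, n_res, c(cfg$fraction_female, 1 - cfg$fraction_female))
    fem <- fem2[, 1L]
    mage <- cfg$mean_age + rnorm(nb, 0, 40 * s)
    if (sum(n_res) > 0)
      mage <- mage + (cfg$mean_age - sum(mage * n_res) / sum(n_res))
    mage <- pmin(pmax(mage, cfg$age_range[1] + 7), cfg$age_range[2] - 15)
  } else {
    inc <- matrix(rep(as.numeric(fr), each = nb), nrow = nb)
    fem <- rep.int(cfg$fraction_female, nb)
    mage <- rep.int(cfg$mean_age, nb)
  }

  neighborhoods <- data.table::data.table(
    id = seq_len(nb), n_cells = as.integer(n_cells), n_residents = n_res,
    safety = safety, cohesion = cohesion,
    frac_low = inc[, 1L], frac_mid = inc[, 2L], frac_high = inc[, 3L],
    frac_female = fem, mean_age = mage)

  # --- designated facility locations ------------------------------------
  nf_loc <- max(cfg$n_fitness_locations, cfg$n_fitness_open)
  nc_loc <- max(cfg$n_club_locations, cfg$n_club_open)
  loc_cells <- sample.int(ncell, nf_loc + nc_loc)
  kind <- rep(c("fitness", "club"), c(nf_loc, nc_loc))
  locations <- data.table::data.table(
    id = seq_along(loc_cells), kind = kind,
    row = (loc_cells - 1L) %% R + 1L,
    col = (loc_cells - 1L) %/% R + 1L,
    occupied = FALSE)

  # --- initially open facilities ----------------------------------------
  open_loc <- c(sample(which(kind == "fitness"), cfg$n_fitness_open),
                sample(which(kind == "club"), cfg$n_club_open))
  locations$occupied[open_loc] <- TRUE
  fkind <- locations$kind[open_loc]
  cheap <- logical(length(open_loc))
  for (k in c("fitness", "club")) {
    ik <- which(fkind == k)
    fe <- if (k == "fitness") cfg$fraction_expensive_fitness else cfg$fraction_expensive_club
    n_exp <- round(length(ik) * fe)
    expensive <- if (n_exp > 0) sample(ik, n_exp) else integer()
    cheap[ik] <- TRUE
    cheap[expensive] <- FALSE
  }
  facilities <- data.table::data.table(
    id = seq_along(open_loc), kind = fkind, loc_id = locations$id[open_loc],
    row = locations$row[open_loc], col = locations$col[open_loc],
    cheap = cheap, open = TRUE, protected_until = NA_integer_)

  structure(list(config = cfg, nrow = R, ncol = C,
                 cell2nbhd = cell2nbhd, cells_by_nbhd = cells_by_nbhd,
                 neighborhoods = neighborhoods, locations = locations,
                 facilities = facilities),
            class = "sport_city")
}

#' @export
print.sport_city <- function(x, ...) {
  cat("<sport_city>", x$nrow, "x", x$ncol, "cells (10 m),",
      nrow(x$neighborhoods), "neighborhoods\n")
  cat("  residents:", sum(x$neighborhoods$n_residents),
      " locations:", nrow(x$locations),
      " open facilities:", sum(x$facilities$open), "\n")
  invisible(x)
}

#' Generate the resident population of a city
#'
#' Draws exactly the configured number of individuals. Each individual is
#' placed on a uniformly chosen cell of its neighbourhood and receives
#' age, sex and income from the neighbourhood's demographic mix, plus an
#' initial tendency drawn from the configured Gamma distribution (mean 1,
#' variance 0.5 by default). Nobody participates in sport at creation.
#'
#' @param city a [generate_city()] result
#' @param n optional population size override; by default the city's
#'   stored per-neighbourhood allocation is used.
#' @param seed optional seed; defaults to a child of the city seed.
#' @return a `data.table` with one row per individual: `id`,
#'   `neighborhood`, `cell`, `row`, `col`, `age`, `sex`, `income`,
#'   `initial_tendency`, `education_boost`.
#' @export
generate_population <- function(city, n = NULL, seed = NULL) {
  if (!inherits(city, "sport_city")) stop("city must be a sport_city")
  if (is.null(seed)) seed <- stream_seed(city$config$seed, 541L)
  if (!is.null(n) && n <= 0)
    stop("population of 0 requested: population size must be positive")
  with_seed(seed, generate_population_impl(city, n))
}

generate_population_impl <- function(city, n = NULL) {
  cfg <- city$config
  nbt <- city$neighborhoods
  counts <- nbt$n_residents
  if (!is.null(n))
    counts <- as.integer(rmultinom(1L, as.integer(n), prob = pmax(counts, 1e-9)))
  total <- sum(counts)
  if (total <= 0) stop("population of 0 requested: nothing to generate")
  nbv <- rep.int(nbt$id, counts)

  # home cell: uniform over the neighbourhood's cells
  cells <- unlist(lapply(seq_len(nrow(nbt)), function(i) {
    if (counts[i] == 0L) return(integer())
    cb <- city$cells_by_nbhd[[i]]
    cb[sample.int(length(cb), counts[i], replace = TRUE)]
  }), use.names = FALSE)

  # age: Beta(2, b) scaled to the adult range, b set by the neighbourhood
  # mean age
  lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
  m <- rep.int(nbt$mean_age, counts)
  mf <- (m - lo) / (hi - lo)
  b <- 2 * (1 - mf) / mf
  age <- lo + (hi - lo) * rbeta(total, 2, b)

  sex <- ifelse(runif(total) < rep.int(nbt$frac_female, counts),
                "female", "male")
  u <- runif(total)
  flo <- rep.int(nbt$frac_low, counts)
  fmid <- rep.int(nbt$frac_mid, counts)
  income <- ifelse(u < flo, "low", ifelse(u < flo + fmid, "middle", "high"))

  t0 <- draw_initial_tendency(total, cfg$tendency_mean, cfg$tendency_var)

  data.table::data.table(
    id = seq_len(total), neighborhood = nbv, cell = cells,
    row = (cells - 1L) %% city$nrow + 1L,
    col = (cells - 1L) %/% city$nrow + 1L,
    age = age, sex = sex, income = income,
    initial_tendency = t0, education_boost = 1)
}

#' Draw initial tendencies
#'
#' Gamma with the given mean and variance (shape `mean^2/var`, scale
#' `var/mean`); a zero variance returns the mean for every individual.
#'
#' @param n number of draws
#' @param mean,var Gamma mean and variance
#' @return numeric vector of positive tendencies
#' @export
draw_initial_tendency <- function(n, mean = 1, var = 0.5) {
  if (var == 0) return(rep.int(mean, n))
  rgamma(n, shape = mean^2 / var, scale = var / mean)
}
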