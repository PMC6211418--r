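# The multiplicative tendency score and its components.

#' Accessibility score of a facility at a given distance
#'
#' Exponential distance decay `exp(-beta * d / 10)`: `beta` is the decay
#' per 10 m (one grid cell), `d` the Euclidean distance between cell
#' centres in metres. At 1 km with `beta = 0.029` this gives
#' `exp(-2.9) ~ 0.055`.
#'
#' @param distance distance in metres, nonnegative
#' @param beta per-10 m decay rate, positive
#' @return multiplier in (0, 1]
#' @examples
#' accessibility_score(0, 0.029)      # 1
#' accessibility_score(1000, 0.029)   # exp(-2.9)
#' @export
accessibility_score <- function(distance, beta) {
  if (any(distance < 0)) stop("distance must be nonnegative")
  if (any(beta <= 0)) stop("beta must be positive")
  exp(-beta * distance / 10)
}

#' Preference score of a facility for an individual
#'
#' Product of the facility's price score (1 for cheap, 0.85 for
#' expensive) and its accessibility from the individual's home cell.
#' Individuals rank all open facilities of a kind by this score and join
#' the best one.
#'
#' @param individual a list or one-row data.frame with `row` and `col`
#'   (home cell, 1-based grid coordinates)
#' @param facility a list or one-row data.frame with `row`, `col` and
#'   `cheap` (logical)
#' @param scores a [score_table()]
#' @param kind `"fitness"` or `"club"`, selects the distance-decay rate
#' @return the preference score
#' @export
preference_score <- function(individual, facility, scores = score_table(),
                             kind = c("fitness", "club")) {
  kind <- match.arg(kind)
  d <- 10 * sqrt((individual$row - facility$row)^2 +
                 (individual$col - facility$col)^2)
  price <- ifelse(facility$cheap, scores$price[["cheap"]],
                  scores$price[["expensive"]])
  price * accessibility_score(d, scores$distance_decay[[kind]])
}

#' Select the best facility of a kind for an individual
#'
#' Argmax of [preference_score()] over the open facilities of the kind;
#' ties are broken deterministically towards the lowest facility id. If no
#' facility of the kind is open the "no facility available" signal
#' `NA_integer_` is returned: the individual cannot start that category
#' this attempt.
#'
#' @param individual as in [preference_score()]
#' @param facilities data.frame of facilities (`id`, `kind`, `row`,
#'   `col`, `cheap`, `open`)
#' @param scores a [score_table()]
#' @param kind `"fitness"` or `"club"`
#' @return the selected facility id, or `NA_integer_`
#' @export
select_facility <- function(individual, facilities, scores = score_table(),
                            kind = c("fitness", "club")) {
  kind <- match.arg(kind)
  f <- as.data.frame(facilities)   # avoid data.table scoping of `kind`
  f <- f[f$open & f$kind == kind, , drop = FALSE]
  if (nrow(f) == 0) return(NA_integer_)
  f <- f[order(f$id), , drop = FALSE]
  pref <- preference_score(individual, f, scores, kind)
  f$id[which.max(pref)]  # which.max takes the first (lowest id) on ties
}

#' Social influence score
#'
#' `1 + p`, where `p` is the proportion of an individual's direct
#' neighbours (everyone living within `radius` metres, excluding the
#' individual) that participates in sport. Individuals without neighbours
#' get the neutral score 1. This reference implementation is a brute-force
#' pairwise computation intended for modest populations; the simulation
#' engine uses an equivalent gridded stencil.
#'
#' @param population data.frame with `row`, `col` (home cells) and a
#'   logical `participating` column
#' @param radius neighbourhood radius in metres
#' @return numeric vector of multipliers in \[1, 2\]
#' @export
social_influence_score <- function(population, radius = 50) {
  n <- nrow(population)
  out <- numeric(n)
  r2 <- (radius / 10)^2
  for (i in seq_len(n)) {
    d2 <- (population$row - population$row[i])^2 +
          (population$col - population$col[i])^2
    nb <- which(d2 <= r2)
    nb <- nb[nb != i]
    out[i] <- if (length(nb) == 0) 1 else 1 + mean(population$participating[nb])
  }
  out
}

#' Tendency to start sports
#'
#' The model's core score: the initial tendency multiplied by the age
#' group, sex, income, safety, cohesion, social-influence and (for
#' facility-based categories) price and accessibility scores, plus any
#' health-education boost. Self-organized sport is not influenced by
#' price or accessibility. All arguments are vectorised.
#'
#' @param t0 initial tendency (positive)
#' @param age age in years
#' @param sex `"male"` or `"female"`
#' @param income `"low"`, `"middle"` or `"high"`
#' @param scores a [score_table()]
#' @param category one of [SPORT_CATEGORIES]
#' @param safety,cohesion neighbourhood scores in \[0, 1\]
#' @param social_influence multiplier from [social_influence_score()]
#' @param education health-education boost (1 when not targeted)
#' @param price_score,accessibility facility factors for the selected
#'   facility; ignored for `self_organized`. `NA` encodes the
#'   "no facility available" signal and propagates.
#' @return numeric vector of tendencies
#' @examples
#' # middle-aged low-income woman, self-organized, neutral environment:
#' tendency_score(1, 45, "female", "low")  # 0.157 * 0.428 * 0.659
#' @export
tendency_score <- function(t0, age, sex, income, scores = score_table(),
                           category = "self_organized",
                           safety = 1, cohesion = 1, social_influence = 1,
                           education = 1, price_score = 1, accessibility = 1) {
  stopifnot(all(t0 > 0))
  category <- match.arg(category, SPORT_CATEGORIES)
  base <- t0 * education *
    unname(scores$age[age_group(age)]) *
    unname(scores$sex[sex]) *
    unname(scores$income[income]) *
    safety * cohesion * social_influence
  if (category == "self_organized") base else base * price_score * accessibility
}
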