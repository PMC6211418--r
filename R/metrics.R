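# Outcome metrics, ensemble summaries and file outputs.

#' Participation fraction of a (filtered) group
#'
#' Fraction of the filtered individuals whose status differs from `none`
#' in any of the filtered categories (both monthly and weekly count as
#' participating). An empty filter group yields `NA` (missing), not 0.
#'
#' @param state a `sport_state`
#' @param income,sex,age_group,neighborhood,category optional filters;
#'   each may be a vector of admissible values
#' @return a fraction in \[0, 1\], or `NA_real_`
#' @export
participation <- function(state, income = NULL, sex = NULL,
                          age_group = NULL, neighborhood = NULL,
                          category = NULL) {
  keep <- rep.int(TRUE, state$n)
  if (!is.null(income))
    keep <- keep & state$income %in% match(income, INCOME_LEVELS)
  if (!is.null(sex)) keep <- keep & state$sex %in% match(sex, SEX_LEVELS)
  if (!is.null(age_group)) {
    ag <- 1L + (state$age >= 35) + (state$age >= 55)
    keep <- keep & ag %in% match(age_group, c("young", "middle", "old"))
  }
  if (!is.null(neighborhood)) keep <- keep & state$nbhd %in% neighborhood
  cats <- if (is.null(category)) 1:3 else
    match(match.arg(category, SPORT_CATEGORIES, several.ok = TRUE),
          SPORT_CATEGORIES)
  if (!any(keep)) return(NA_real_)
  act <- state$stat[keep, cats, drop = FALSE] > 0L
  mean(rowSums(act) > 0L)
}

#' Absolute income inequality in sports participation
#'
#' Participation of the high-income group minus that of the low-income
#' group, in percentage points. With `by_neighborhood = TRUE`, the same
#' difference is computed per neighbourhood (missing where a
#' neighbourhood lacks one of the groups).
#'
#' @param state a `sport_state`
#' @param by_neighborhood logical
#' @return a single value in percentage points, or a `data.table` with
#'   one row per neighbourhood
#' @export
absolute_inequality <- function(state, by_neighborhood = FALSE) {
  if (!by_neighborhood) {
    hi <- participation(state, income = "high")
    lo <- participation(state, income = "low")
    return(100 * (hi - lo))
  }
  nbs <- state$city$neighborhoods$id
  res <- data.table::data.table(
    neighborhood_id = nbs,
    participation = vapply(nbs, function(b)
      participation(state, neighborhood = b), 0),
    part_high = vapply(nbs, function(b)
      participation(state, income = "high", neighborhood = b), 0),
    part_low = vapply(nbs, function(b)
      participation(state, income = "low", neighborhood = b), 0))
  res$inequality <- 100 * (res$part_high - res$part_low)
  res
}

neighborhood_metrics <- function(state) {
  res <- absolute_inequality(state, by_neighborhood = TRUE)
  res$month <- state$month
  res
}

#' Summarize a run ensemble
#'
#' Per metric and month: the ensemble mean and a 95% uncertainty range
#' formed by discarding the `ceiling(0.025 n)` highest and lowest run
#' values from each tail — with the canonical 80 runs that discards the
#' two highest and two lowest, so the interval spans the 3rd smallest to
#' the 3rd largest value. For fewer than 5 runs the interval is omitted
#' (`NA`) with a warning; the mean is always reported.
#'
#' @param ensemble a [run_ensemble()] result
#' @param drop_per_tail optional explicit number of runs discarded per
#'   tail (defaults to `ceiling(0.025 * n_runs)`)
#' @return a `data.table`: `month`, `metric`, `mean`, `lo`, `hi`
#' @export
summarize_ensemble <- function(ensemble, drop_per_tail = NULL) {
  stopifnot(inherits(ensemble, "sport_ensemble"))
  arr <- ensemble$metrics
  n <- dim(arr)[3]
  if (is.null(drop_per_tail)) drop_per_tail <- ceiling(0.025 * n)
  has_interval <- n >= 5L
  if (!has_interval)
    warning("fewer than 5 runs: uncertainty interval omitted", call. = FALSE)
  k <- drop_per_tail
  mn <- apply(arr, c(1, 2), mean)
  if (has_interval) {
    srt <- apply(arr, c(1, 2), function(v) {
      s <- sort(v)
      c(s[k + 1L], s[length(s) - k])
    })
    lo <- srt[1L, , ]; hi <- srt[2L, , ]
  } else {
    lo <- hi <- matrix(NA_real_, nrow(mn), ncol(mn))
  }
  months <- dim(arr)[1]
  data.table::data.table(
    month = rep(seq_len(months), times = ncol(mn)),
    metric = rep(colnames(arr), each = months),
    mean = as.vector(mn), lo = as.vector(lo), hi = as.vector(hi))
}

#' Contrast a scenario ensemble against its counterfactual
#'
#' Pairs runs by position (use a common `base_seed` so runs share random
#' numbers) and returns per month and metric the mean difference
#' scenario minus counterfactual along with its drop-per-tail interval
#' over the paired differences.
#'
#' @param scenario,counterfactual [run_ensemble()] results of equal shape
#' @return a `data.table`: `month`, `metric`, `delta`, `lo`, `hi`
#' @export
contrast_ensembles <- function(scenario, counterfactual) {
  stopifnot(identical(dim(scenario$metrics), dim(counterfactual$metrics)))
  diff <- scenario
  diff$metrics <- scenario$metrics - counterfactual$metrics
  out <- summarize_ensemble(diff)
  data.table::setnames(out, "mean", "delta")
  out
}

#' Export ensemble outputs to files
#'
#' Writes a tidy per-run trajectory CSV (`run`, `month`, `scenario`,
#' `metric`, `value`), a summary CSV (from [summarize_ensemble()]), and —
#' when the ensemble recorded neighbourhood snapshots — a GeoJSON of
#' per-neighbourhood participation and income inequality (ensemble means
#' at the intervention month and at the end). All outputs are
#' reproducible from the CSVs alone.
#'
#' @param ensemble a [run_ensemble()] result
#' @param city the city the ensemble was run on
#' @param dir output directory (created if needed)
#' @param scenario scenario label written into the CSVs
#' @return named character vector of the files written
#' @export
export_outputs <- function(ensemble, city, dir, scenario = "scenario") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- ensemble$metrics
  months <- dim(arr)[1]; nmet <- dim(arr)[2]; nrun <- dim(arr)[3]
  traj <- data.table::data.table(
    run = rep(seq_len(nrun), each = months * nmet),
    month = rep(rep(seq_len(months), times = nmet), times = nrun),
    scenario = scenario,
    metric = rep(rep(colnames(arr), each = months), times = nrun),
    value = as.vector(arr))
  f_traj <- file.path(dir, "trajectories.csv")
  data.table::fwrite(traj, f_traj)
  f_sum <- file.path(dir, "summary.csv")
  data.table::fwrite(summarize_ensemble(ensemble), f_sum)
  files <- c(trajectories = f_traj, summary = f_sum)
  if (!is.null(ensemble$neighborhoods) &&
      length(ensemble$neighborhoods) && !is.null(ensemble$neighborhoods[[1]])) {
    snap_mean <- function(which) {
      mats <- lapply(ensemble$neighborhoods, function(s) s[[which]])
      base <- mats[[1]]
      for (col in c("participation", "part_high", "part_low", "inequality")) {
        base[[col]] <- rowMeans(sapply(mats, function(m) m[[col]]))
      }
      base
    }
    b <- snap_mean("baseline"); fn <- snap_mean("final")
    feats <- lapply(seq_len(nrow(b)), function(i) {
      nb <- b$neighborhood_id[i]
      runs <- cell_runs(city$cells_by_nbhd[[nb]], city$nrow)
      polys <- lapply(seq_len(nrow(runs)), function(kk)
        rect_ring(runs$col[kk], runs$r1[kk], runs$r2[kk],
                  city$config$cell_size))
      list(type = "Feature",
           properties = list(neighborhood_id = nb,
                             participation_baseline = b$participation[i],
                             inequality_baseline = b$inequality[i],
                             participation_final = fn$participation[i],
                             inequality_final = fn$inequality[i]),
           geometry = list(type = "MultiPolygon", coordinates = polys))
    })
    f_geo <- file.path(dir, "neighborhoods.geojson")
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         f_geo, auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, neighborhoods = f_geo)
  }
  files
}
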