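# City files: a GeoJSON FeatureCollection (planar coordinates in metres)
# holding neighbourhood MultiPolygons, designated-location Points and open
# facilities, plus a CSV attribute table per neighbourhood. Geometry is
# exact: each neighbourhood polygon is the union of per-column rectangles
# of grid-cell runs, so loading reconstructs the cell partition
# bit-exactly. No geospatial package is involved; files are plain JSON.

cell_runs <- function(cells, R) {
  cells <- sort(cells)
  colv <- (cells - 1L) %/% R
  brk <- which(diff(cells) != 1L | diff(colv) != 0L)
  starts <- cells[c(1L, brk + 1L)]
  ends <- cells[c(brk, length(cells))]
  data.frame(col = (starts - 1L) %/% R + 1L,
             r1 = (starts - 1L) %% R + 1L,
             r2 = (ends - 1L) %% R + 1L)
}

rect_ring <- function(col, r1, r2, cell_size = 10) {
  x0 <- (col - 1) * cell_size; x1 <- col * cell_size
  y0 <- (r1 - 1) * cell_size; y1 <- r2 * cell_size
  list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
}

#' Save a city to GeoJSON + CSV
#'
#' Writes `path` (a GeoJSON FeatureCollection with the full resolved
#' config, neighbourhood geometries and attributes, facility locations and
#' open facilities) and a sibling CSV attribute table
#' (`<path without extension>.csv`) with one row per neighbourhood.
#' `load_city(save_city(city, path))` reproduces every field.
#'
#' @param city a `sport_city`
#' @param path output GeoJSON path
#' @return `path`, invisibly
#' @export
save_city <- function(city, path) {
  stopifnot(inherits(city, "sport_city"))
  nbt <- city$neighborhoods
  feats <- vector("list", nrow(nbt) + nrow(city$locations) + nrow(city$facilities))
  j <- 0L
  for (i in seq_len(nrow(nbt))) {
    runs <- cell_runs(city$cells_by_nbhd[[i]], city$nrow)
    polys <- lapply(seq_len(nrow(runs)), function(k)
      rect_ring(runs$col[k], runs$r1[k], runs$r2[k], city$config$cell_size))
    j <- j + 1L
    feats[[j]] <- list(type = "Feature",
      properties = c(list(feature = "neighborhood"),
                     as.list(nbt[i])),
      geometry = list(type = "MultiPolygon", coordinates = polys))
  }
  cs <- city$config$cell_size
  for (i in seq_len(nrow(city$locations))) {
    l <- city$locations[i]
    j <- j + 1L
    feats[[j]] <- list(type = "Feature",
      properties = list(feature = "location", id = l$id, kind = l$kind,
                        row = l$row, col = l$col, occupied = l$occupied),
      geometry = list(type = "Point",
                      coordinates = c((l$col - 0.5) * cs, (l$row - 0.5) * cs)))
  }
  for (i in seq_len(nrow(city$facilities))) {
    f <- city$facilities[i]
    j <- j + 1L
    feats[[j]] <- list(type = "Feature",
      properties = list(feature = "facility", id = f$id, kind = f$kind,
                        loc_id = f$loc_id, row = f$row, col = f$col,
                        cheap = f$cheap, open = f$open,
                        protected_until = f$protected_until),
      geometry = list(type = "Point",
                      coordinates = c((f$col - 0.5) * cs, (f$row - 0.5) * cs)))
  }
  cfg_out <- unclass(city$config)
  cfg_out$income_fractions <- as.list(cfg_out$income_fractions)
  doc <- list(type = "FeatureCollection",
              properties = list(generator = "sportabm",
                                grid_rows = city$nrow, grid_cols = city$ncol,
                                config = cfg_out),
              features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  write.csv(nbt[, c("id", "n_residents", "safety", "cohesion", "frac_low",
                    "frac_mid", "frac_high", "frac_female", "mean_age")],
            sub("\\.[^.]+$", ".csv", path), row.names = FALSE)
  invisible(path)
}

num1 <- function(x, what, rec) {
  if (is.null(x) || length(x) != 1 || !is.numeric(unlist(x)))
    stop("parse error in ", rec, ": missing or non-numeric field '", what, "'",
         call. = FALSE)
  unlist(x)
}

restore_config <- function(lst) {
  lst$income_fractions <- unlist(lst$income_fractions)
  lst$age_range <- unlist(lst$age_range)
  for (nm in c("grid_rows", "grid_cols", "n_neighborhoods", "population_size",
               "n_fitness_locations", "n_club_locations", "n_fitness_open",
               "n_club_open", "seed"))
    lst[[nm]] <- as.integer(lst[[nm]])
  cfg <- structure(lst, class = "city_config")
  validate_city_config(cfg)
  cfg
}

#' Load a city saved by [save_city()]
#'
#' @param path a GeoJSON path written by [save_city()]
#' @return a `sport_city`
#' @export
load_city <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("parse error in ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  if (!identical(doc$type, "FeatureCollection") || is.null(doc$features))
    stop("parse error in ", path, ": not a FeatureCollection", call. = FALSE)
  cfg <- restore_config(doc$properties$config)
  R <- as.integer(num1(doc$properties$grid_rows, "grid_rows", "header"))
  C <- as.integer(num1(doc$properties$grid_cols, "grid_cols", "header"))
  cs <- cfg$cell_size

  nb_rows <- list(); loc_rows <- list(); fac_rows <- list()
  cells_by_nbhd <- list()
  for (i in seq_along(doc$features)) {
    ft <- doc$features[[i]]
    rec <- paste0("feature ", i)
    pr <- ft$properties
    if (is.null(pr$feature))
      stop("parse error in ", rec, ": missing 'feature' property", call. = FALSE)
    if (pr$feature == "neighborhood") {
      id <- as.integer(num1(pr$id, "id", rec))
      cells <- integer()
      for (poly in ft$geometry$coordinates) {
        ring <- poly[[1]]
        xs <- vapply(ring, function(p) unlist(p)[1], 0)
        ys <- vapply(ring, function(p) unlist(p)[2], 0)
        col <- as.integer(round(min(xs) / cs)) + 1L
        r1 <- as.integer(round(min(ys) / cs)) + 1L
        r2 <- as.integer(round(max(ys) / cs))
        if (col < 1L || col > C || r1 < 1L || r2 > R || r2 < r1)
          stop("parse error in ", rec, ": rectangle outside grid", call. = FALSE)
        cells <- c(cells, r1:r2 + (col - 1L) * R)
      }
      cells_by_nbhd[[id]] <- sort(cells)
      nb_rows[[length(nb_rows) + 1L]] <- data.table::data.table(
        id = id, n_cells = as.integer(num1(pr$n_cells, "n_cells", rec)),
        n_residents = as.integer(num1(pr$n_residents, "n_residents", rec)),
        safety = num1(pr$safety, "safety", rec),
        cohesion = num1(pr$cohesion, "cohesion", rec),
        frac_low = num1(pr$frac_low, "frac_low", rec),
        frac_mid = num1(pr$frac_mid, "frac_mid", rec),
        frac_high = num1(pr$frac_high, "frac_high", rec),
        frac_female = num1(pr$frac_female, "frac_female", rec),
        mean_age = num1(pr$mean_age, "mean_age", rec))
    } else if (pr$feature == "location") {
      loc_rows[[length(loc_rows) + 1L]] <- data.table::data.table(
        id = as.integer(num1(pr$id, "id", rec)), kind = as.character(pr$kind),
        row = as.integer(num1(pr$row, "row", rec)),
        col = as.integer(num1(pr$col, "col", rec)),
        occupied = isTRUE(pr$occupied))
    } else if (pr$feature == "facility") {
      fac_rows[[length(fac_rows) + 1L]] <- data.table::data.table(
        id = as.integer(num1(pr$id, "id", rec)), kind = as.character(pr$kind),
        loc_id = as.integer(num1(pr$loc_id, "loc_id", rec)),
        row = as.integer(num1(pr$row, "row", rec)),
        col = as.integer(num1(pr$col, "col", rec)),
        cheap = isTRUE(pr$cheap), open = isTRUE(pr$open),
        protected_until = if (is.null(pr$protected_until))
          NA_integer_ else as.integer(pr$protected_until))
    } else stop("parse error in ", rec, ": unknown feature type '",
                pr$feature, "'", call. = FALSE)
  }
  if (!length(nb_rows))
    stop("parse error in ", path, ": no neighborhood features", call. = FALSE)
  nbt <- data.table::rbindlist(nb_rows)
  data.table::setkey(nbt, NULL)
  nbt <- nbt[order(nbt$id)]
  cells_by_nbhd <- cells_by_nbhd[nbt$id]
  cell2nbhd <- integer(R * C)
  for (i in seq_along(cells_by_nbhd)) cell2nbhd[cells_by_nbhd[[i]]] <- nbt$id[i]
  if (any(cell2nbhd == 0L))
    stop("parse error in ", path, ": neighborhood polygons do not cover the grid",
         call. = FALSE)
  locations <- data.table::rbindlist(loc_rows)
  locations <- locations[order(locations$id)]
  facilities <- if (length(fac_rows)) {
    f <- data.table::rbindlist(fac_rows); f[order(f$id)]
  } else data.table::data.table(id = integer(), kind = character(),
                                loc_id = integer(), row = integer(),
                                col = integer(), cheap = logical(),
                                open = logical(), protected_until = integer())
  names(cells_by_nbhd) <- as.character(nbt$id)
  structure(list(config = cfg, nrow = R, ncol = C, cell2nbhd = cell2nbhd,
                 cells_by_nbhd = cells_by_nbhd, neighborhoods = nbt,
                 locations = locations, facilities = facilities),
            class = "sport_city")
}
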