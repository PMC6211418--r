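# Environment feedback: annual closure of the weakest facility and
# opening of a new facility where demand is highest.
#
# The demand definition is a documented reconstruction (the original's
# exact formula is not published): a neighbourhood's demand for a kind is
# the summed facility-independent tendency of its residents who do not
# yet participate in that kind's category, divided by (1 + open
# facilities of the kind in the neighbourhood) — demand rises with
# unserved propensity and falls with local supply.

kind_index <- function(kind) {
  if (is.character(kind)) match(match.arg(kind, c("fitness", "club")),
                                c("fitness", "club"))
  else as.integer(kind)
}

#' Close the open facility with the fewest members
#'
#' Among unprotected open facilities of the kind, the one with the fewest
#' members closes (ties to the lowest id); its location becomes vacant,
#' and its members immediately re-select the best remaining facility of
#' the kind (keeping their participation), or hold no facility if none
#' remains. If every facility of the kind is protected, no closure
#' happens that year (logged).
#'
#' @param state a `sport_state`, modified in place
#' @param kind `"fitness"` or `"club"`
#' @return the state, invisibly
#' @export
close_weakest <- function(state, kind) {
  k <- kind_index(kind)
  f <- state$fcs
  open_k <- which(f$open & f$kind == k)
  unprot <- open_k[is.na(f$protected_until[open_k]) |
                     f$protected_until[open_k] < state$month]
  if (!length(unprot)) {
    log_event(state, "no_closure_all_protected", k, NA, NA, NA)
    return(invisible(state))
  }
  mc <- members_count(state, k)
  cnt <- mc[f$id[unprot]]
  victim <- unprot[order(cnt, f$id[unprot])][1L]
  vid <- f$id[victim]
  loc <- match(f$loc_id[victim], state$locs$id)
  nb <- state$locs$nbhd[loc]
  log_event(state, "close", k, vid, nb, cnt[order(cnt, f$id[unprot])][1L])
  state$fcs$open[victim] <- FALSE
  state$locs$occupied[loc] <- FALSE
  members <- which(!is.na(state$fac[, k]) & state$fac[, k] == vid)
  update_best(state, kinds = k)
  if (length(members))
    state$fac[cbind(members, rep.int(k, length(members)))] <-
      state$facb[cbind(members, rep.int(k, length(members)))]
  invisible(state)
}

neighborhood_demand <- function(state, k) {
  nb_n <- nrow(state$city$neighborhoods)
  pending <- state$stat[, k] == 0L
  base <- state$base
  if (anyNA(base)) base <- base_score(state)
  si <- state$si
  w <- (base * si)[pending]
  dem <- numeric(nb_n)
  agg <- rowsum(w, state$nbhd[pending])
  dem[as.integer(rownames(agg))] <- agg[, 1L]
  open_k <- state$fcs$open & state$fcs$kind == k
  fnb <- state$locs$nbhd[match(state$fcs$loc_id[open_k], state$locs$id)]
  supply <- tabulate(fnb, nbins = nb_n)
  dem / (1 + supply)
}

#' Open a facility in the neighbourhood with the highest demand
#'
#' Demand per neighbourhood is defined above; among neighbourhoods with
#' at least one vacant designated location of the kind, the one with the
#' highest demand (ties to the lowest neighbourhood id) receives a new
#' facility at a uniformly chosen vacant location. Its price level is
#' drawn with the configured expensive fraction (or fixed cheap while a
#' price intervention is active). With no vacant location anywhere the
#' opening is skipped (logged).
#'
#' @inheritParams close_weakest
#' @return the state, invisibly
#' @export
open_best <- function(state, kind) {
  k <- kind_index(kind)
  vac <- which(!state$locs$occupied & state$locs$kind == k)
  if (!length(vac)) {
    log_event(state, "no_opening_no_vacancy", k, NA, NA, NA)
    return(invisible(state))
  }
  dem <- neighborhood_demand(state, k)
  cand <- sort(unique(state$locs$nbhd[vac]))
  best_nb <- cand[which.max(dem[cand])]   # first max -> lowest id on ties
  slots <- vac[state$locs$nbhd[vac] == best_nb]
  pick <- if (length(slots) == 1L) slots else
    slots[with_stream(state, "facilities", sample.int(length(slots), 1L))]
  cheap <- state$price_lock ||
    (with_stream(state, "facilities", runif(1L)) >= state$frac_expensive[k])
  open_at(state, pick, k, cheap = cheap, protected_until = NA_integer_)
  invisible(state)
}

# register a new facility at location index `loc` (row index into locs)
open_at <- function(state, loc, k, cheap, protected_until) {
  nid <- if (length(state$fcs$id)) max(state$fcs$id) + 1L else 1L
  state$locs$occupied[loc] <- TRUE
  state$fcs$id <- c(state$fcs$id, nid)
  state$fcs$kind <- c(state$fcs$kind, k)
  state$fcs$loc_id <- c(state$fcs$loc_id, state$locs$id[loc])
  state$fcs$row <- c(state$fcs$row, state$locs$row[loc])
  state$fcs$col <- c(state$fcs$col, state$locs$col[loc])
  state$fcs$cheap <- c(state$fcs$cheap, cheap)
  state$fcs$open <- c(state$fcs$open, TRUE)
  state$fcs$protected_until <- c(state$fcs$protected_until,
                                 as.integer(protected_until))
  log_event(state, "open", k, nid, state$locs$nbhd[loc], 0L)
  update_best(state, kinds = k)
  nid
}

#' Annual facility turnover
#'
#' For each kind (fitness first, then club): the weakest facility closes
#' and a new one opens where demand is highest. By default exactly one
#' closure and one opening per kind per year, so open counts are
#' time-invariant; with `poisson_turnover` the yearly event counts are
#' Poisson(1) draws (closures and openings are yearly averages).
#'
#' @param state a `sport_state`, modified in place
#' @return the state, invisibly
#' @export
annual_facility_turnover <- function(state) {
  for (k in 1:2) {
    nc <- no <- 1L
    if (state$dyn$poisson_turnover) {
      nc <- with_stream(state, "facilities", rpois(1L, 1))
      no <- with_stream(state, "facilities", rpois(1L, 1))
    }
    for (i in seq_len(nc)) close_weakest(state, k)
    for (i in seq_len(no)) open_best(state, k)
  }
  invisible(state)
}
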