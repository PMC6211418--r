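# Named independent RNG streams.
#
# Base R keeps a single global generator, so independent streams are
# implemented by saving and restoring `.Random.seed` around every draw.
# Each stream's seed is derived from the scenario seed by a fixed
# linear-congruential splitting rule, so a single integer seed in a config
# reproducibly fans out to all processes.  Keeping e.g. demography on its
# own stream means that adding an intervention does not perturb who dies
# or migrates, which is the variance-reduction backbone of the
# scenario-vs-counterfactual contrasts.

STREAM_NAMES <- c("population", "demography", "starts", "quits",
                  "frequency", "facilities", "interventions")

#' Derive a child seed from a base seed
#'
#' Documented splitting rule: `(seed * 48271 + k * 104729) mod (2^31 - 1)`,
#' mapped away from 0. Deterministic and platform independent.
#'
#' @param seed integer base seed
#' @param k integer stream / run index
#' @return a positive integer seed below 2^31
#' @export
stream_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647) * 48271 + as.double(k) * 104729
  out <- as.integer(s %% 2147483647)
  if (out == 0L) 1L else out
}

rng_streams <- function(seed, names = STREAM_NAMES) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  out <- vector("list", length(names))
  names(out) <- names
  for (i in seq_along(names)) {
    set.seed(stream_seed(seed, i))
    out[[i]] <- get(".Random.seed", envir = globalenv())
  }
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  out
}

# Evaluate `expr` with the named stream active; the global RNG state of the
# caller is untouched.
with_stream <- function(state, name, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", state$rng[[name]], envir = globalenv())
  res <- expr
  state$rng[[name]] <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}

# Run `expr` under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  res <- expr
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}
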