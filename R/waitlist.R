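# Dynamic waiting list: stratified initialization from a candidate pool,
# Poisson arrivals, Poisson departures removing the highest exit-risk
# candidates, and day-by-day advancement with per-day RNG substreams.
#
# A waitlist state keeps the full candidate table once and tracks the
# active set and the unlisted reservoir as row-index vectors; the event
# log is accumulated as parallel vectors and materialized on demand.

#' Construct a waitlist state
#'
#' @param candidates full candidate table (active members plus reservoir).
#' @param clock starting date.
#' @return a `kap_waitlist` list with fields `candidates`, `active`
#'   (row indices), `pool` (row indices), `clock`, and an internal event
#'   accumulator; see [event_log()].
#' @keywords internal
new_waitlist <- function(candidates, clock) {
  structure(list(
    candidates = candidates,
    active = integer(0),
    pool = seq_len(nrow(candidates)),
    departed = integer(0),
    clock = as.Date(clock),
    ev_date = list(), ev_id = list(), ev_event = list()
  ), class = "kap_waitlist")
}

log_events <- function(state, date, ids, event) {
  if (length(ids) == 0) return(state)
  n <- length(state$ev_date) + 1L
  state$ev_date[[n]] <- rep(as.Date(date), length(ids))
  state$ev_id[[n]] <- ids
  state$ev_event[[n]] <- rep(event, length(ids))
  state
}

#' Event log of a waitlist state
#'
#' Append-only record of every `init`, `arrival`, `departure` and
#' `transplant` event, with non-decreasing dates. The conservation
#' invariant `|active| = inits + arrivals - departures - transplants` is
#' checkable from this log at any time (see [check_conservation()]).
#'
#' @param state a `kap_waitlist`.
#' @return data.frame with columns `date`, `id`, `event`.
#' @export
event_log <- function(state) {
  data.frame(
    date = as.Date(unlist(lapply(state$ev_date, as.integer)) %||% integer(0),
                   origin = "1970-01-01"),
    id = unlist(state$ev_id) %||% character(0),
    event = unlist(state$ev_event) %||% character(0),
    stringsAsFactors = FALSE
  )
}

#' @rdname event_log
#' @export
check_conservation <- function(state) {
  ev <- table(factor(unlist(state$ev_event),
                     levels = c("init", "arrival", "departure", "transplant")))
  expected <- ev[["init"]] + ev[["arrival"]] - ev[["departure"]] -
    ev[["transplant"]]
  kap_assert(length(state$active) == expected,
             "conservation violated: |active| = %d but log implies %d",
             length(state$active), expected, class = "kap_invariant_error")
  kap_assert(!anyDuplicated(state$active),
             "candidate appears twice in active set",
             class = "kap_invariant_error")
  invisible(TRUE)
}

# Stratified sampling weights: for each pool member, the product over the
# four stratification variables (age band, blood group, state, PRA band)
# of target frequency / pool frequency, so realized stratum frequencies
# approximate the targets. Targets default to the pool's own marginals
# (weights 1). Positive target mass on an empty stratum is renormalized
# over the non-empty strata with a warning.
strata_weights <- function(candidates, strata_targets) {
  w <- rep(1, nrow(candidates))
  vars <- list(
    age_band = as.character(age_band(candidates$age)),
    blood_group = candidates$blood_group,
    state = candidates$state,
    pra_band = as.character(pra_band(candidates$pra))
  )
  for (v in names(vars)) {
    target <- strata_targets[[v]]
    if (is.null(target)) next
    target <- unlist(target)
    kap_assert(all(target >= 0) && abs(sum(target) - 1) < 1e-6,
               "strata_targets$%s must be frequencies summing to 1", v,
               class = "kap_validation_error")
    pool_freq <- prop.table(table(vars[[v]]))
    empty <- setdiff(names(target)[target > 0], names(pool_freq))
    if (length(empty) > 0) {
      warning(sprintf(
        "strata_targets$%s: no pool members in stratum(s) %s; mass renormalized",
        v, paste(empty, collapse = ", ")))
      target <- target[setdiff(names(target), empty)]
      target <- target / sum(target)
    }
    ratio <- target[vars[[v]]] / pool_freq[vars[[v]]]
    ratio[is.na(ratio)] <- 0
    w <- w * as.numeric(ratio)
  }
  w
}

#' Initialize the waiting list by stratified sampling
#'
#' Samples `n0` (default 300) initial candidates from the pool without
#' replacement, with stratum weights chosen so the realized distribution
#' over age band, blood group, state and PRA band approximates
#' `strata_targets`; the rest of the pool is retained as the reservoir
#' feeding future arrivals.
#'
#' @param pool candidate table with at least `n0` rows.
#' @param config a `kap_config` (dynamics block: `n0`; optional
#'   `strata_targets` passed separately).
#' @param start_date the simulation clock at initialization; defaults to
#'   the latest listing date among selected members so every initial
#'   member is already listed.
#' @param seed integer seed.
#' @param strata_targets optional named list of target frequency vectors
#'   for `age_band`, `blood_group`, `state`, `pra_band`.
#' @return a `kap_waitlist`.
#' @export
initialize_waitlist <- function(pool, config = parse_config(),
                                start_date = NULL, seed = config$seed,
                                strata_targets = list()) {
  n0 <- config$dynamics$n0
  kap_assert(nrow(pool) >= n0,
             "pool has %d candidates but n0 = %d", nrow(pool), n0,
             class = "kap_size_error")
  w <- strata_weights(pool, strata_targets)
  sel <- with_local_seed(derive_seed(seed, "init"), {
    if (n0 == 0) integer(0)
    else sample(seq_len(nrow(pool)), n0, replace = FALSE, prob = w)
  })
  if (is.null(start_date)) {
    start_date <- if (n0 > 0) max(pool$listing_date[sel]) else Sys.Date()
  }
  start_date <- as.Date(start_date)
  # Initial members represent a list accumulated before the start: any
  # listing date after start_date is reflected across it, so time already
  # waited is positive and uniformly spread without extra random draws.
  late <- sel[pool$listing_date[sel] > start_date]
  pool$listing_date[late] <- start_date -
    as.numeric(pool$listing_date[late] - start_date)
  ds <- pool$dialysis_start_date[late]
  pool$dialysis_start_date[late] <- pmin(ds, pool$listing_date[late])
  state <- new_waitlist(pool, start_date)
  state$active <- sort(sel)
  state$pool <- setdiff(seq_len(nrow(pool)), sel)
  state$weights <- w
  state$strata_targets <- strata_targets
  log_events(state, start_date, pool$id[state$active], "init")
}

#' Advance the waiting list by one day of arrivals
#'
#' Draws `Poisson(k_in(day) * lambda_in)` arrivals and moves that many
#' candidates from the reservoir to the active list using the same
#' stratified weights as initialization; movers get `day` as their listing
#' date. If the reservoir runs short, as many as available are admitted
#' with a warning. Each day uses an RNG substream derived from the master
#' seed and the date, so advancing in two calls equals advancing in one.
#'
#' @param state a `kap_waitlist`.
#' @param day the calendar day being simulated.
#' @param config a `kap_config`.
#' @param seed master seed (default `config$seed`).
#' @return the updated `kap_waitlist`.
#' @export
step_arrivals <- function(state, day, config, seed = config$seed) {
  day <- as.Date(day)
  lam <- rate_multiplier(config$dynamics$k_in, day) * config$dynamics$lambda_in
  with_local_seed(derive_seed(seed, "arrivals", day), {
    n <- stats::rpois(1, lam)
    if (n == 0) return(state)
    if (n > length(state$pool)) {
      if (!isTRUE(state$pool_warned)) {  # warn once per exhaustion episode
        warning(sprintf("candidate pool exhausted on %s: admitting %d of %d",
                        day, length(state$pool), n))
        state$pool_warned <- TRUE
      }
      n <- length(state$pool)
      if (n == 0) return(state)
    } else if (isTRUE(state$pool_warned)) {
      state$pool_warned <- FALSE
    }
    w <- state$weights[state$pool]
    take <- if (length(state$pool) == 1) state$pool
            else state$pool[sample.int(length(state$pool), n, prob = w)]
    state$candidates$listing_date[take] <- day
    state$active <- c(state$active, take)
    state$pool <- setdiff(state$pool, take)
    log_events(state, day, state$candidates$id[take], "arrival")
  })
}

#' Advance the waiting list by one day of departures
#'
#' Draws `Poisson(k_out(day) * lambda_out)` departures, scores every
#' active candidate with the exit-risk scorer, and removes the
#' highest-scoring ones (ties: earlier listing date first, then id
#' order) -- modelling exit without transplant. If the draw exceeds the
#' active size, all active candidates are removed with a warning.
#'
#' @inheritParams step_arrivals
#' @param scorer an exit-risk scorer, see [default_exit_scorer()].
#' @return the updated `kap_waitlist`.
#' @export
step_departures <- function(state, day, config, scorer = NULL,
                            seed = config$seed) {
  day <- as.Date(day)
  if (is.null(scorer)) scorer <- default_exit_scorer(config)
  lam <- rate_multiplier(config$dynamics$k_out, day) * config$dynamics$lambda_out
  with_local_seed(derive_seed(seed, "departures", day), {
    n <- stats::rpois(1, lam)
    if (n == 0) return(state)
    if (n > length(state$active)) {
      warning(sprintf("departure draw %d exceeds active list (%d) on %s",
                      n, length(state$active), day))
      n <- length(state$active)
      if (n == 0) return(state)
    }
    act <- state$candidates[state$active, , drop = FALSE]
    score <- scorer(act, day)
    ord <- order(-score, act$listing_date, act$id)
    out <- state$active[ord[seq_len(n)]]
    state$active <- setdiff(state$active, out)
    state$departed <- c(state$departed, out)
    log_events(state, day, state$candidates$id[out], "departure")
  })
}

# Optional daily re-entry of departed candidates (default probability 0):
# departures model interim-list stand-downs, which may end.
step_reentries <- function(state, day, config, seed = config$seed) {
  p <- config$dynamics$reentry_prob
  if (p <= 0 || length(state$departed) == 0) return(state)
  with_local_seed(derive_seed(seed, "reentry", as.Date(day)), {
    back <- state$departed[stats::runif(length(state$departed)) < p]
    if (length(back) == 0) return(state)
    state$departed <- setdiff(state$departed, back)
    state$active <- c(state$active, back)
    log_events(state, day, state$candidates$id[back], "arrival")
  })
}

#' Advance the waiting list to a target date
#'
#' Applies [step_arrivals()] then [step_departures()] (and re-entries when
#' configured) for every day after the current clock up to and including
#' `target_date`. Because every day draws from its own substream, two
#' consecutive advances produce exactly the same state and event log as
#' one combined advance.
#'
#' @inheritParams step_departures
#' @param target_date date `>=` the current clock.
#' @return the updated `kap_waitlist` with `clock = target_date`.
#' @export
advance_to <- function(state, target_date, config, scorer = NULL,
                       seed = config$seed) {
  target_date <- as.Date(target_date)
  kap_assert(target_date >= state$clock,
             "target_date %s precedes clock %s", target_date, state$clock,
             class = "kap_temporal_error")
  if (is.null(scorer)) scorer <- default_exit_scorer(config)
  day <- state$clock
  while (day < target_date) {
    day <- day + 1
    state <- step_arrivals(state, day, config, seed)
    state <- step_departures(state, day, config, scorer, seed)
    state <- step_reentries(state, day, config, seed)
  }
  state$clock <- target_date
  state
}

#' Remove a transplanted candidate from the active list
#'
#' @param state a `kap_waitlist`.
#' @param idx row index (into `state$candidates`) of the recipient.
#' @param day transplant date.
#' @return the updated `kap_waitlist`.
#' @export
record_transplant <- function(state, idx, day) {
  kap_assert(idx %in% state$active, "recipient not on the active list",
             class = "kap_invariant_error")
  state$active <- setdiff(state$active, idx)
  log_events(state, day, state$candidates$id[idx], "transplant")
}

#' Logistic-linear exit-without-transplant scorer
#'
#' The rank-and-remove departure step needs a relative exit-risk score for
#' every active candidate. The default scorer is a logistic transform of a
#' linear predictor over eleven recipient features: age, sex, the five
#' comorbidity flags (lung disease, smoking, diabetes, cardiovascular
#' disease, cancer), PRA, blood group O, a metropolitan-state indicator
#' (NSW/VIC/QLD) and years on dialysis at the scoring date. Coefficients
#' live in the config, so a scorer fitted on real data (e.g. a random
#' survival forest) can be plugged in behind the same contract:
#' `function(candidates, date) -> numeric`, deterministic and finite.
#'
#' @param config a `kap_config`, or a named coefficient list with an
#'   optional `intercept`.
#' @return a scorer function `(candidates, date) -> numeric in (0, 1)`.
#' @export
default_exit_scorer <- function(config = parse_config()) {
  spec <- if (inherits(config, "kap_config")) config$exit_scorer else config
  coef <- unlist(spec$coefficients)
  intercept <- spec$intercept %||% 0
  needed <- c("age", "sex_m", "lung_disease", "smoking", "diabetes",
              "cardiovascular_disease", "cancer", "pra", "blood_group_o",
              "state_metro", "years_on_dialysis")
  miss <- setdiff(needed, names(coef))
  kap_assert(length(miss) == 0, "exit scorer missing coefficient(s): %s",
             paste(miss, collapse = ", "), class = "kap_config_error")
  function(candidates, date) {
    date <- as.Date(date)
    yrs <- years_on_dialysis(candidates, date)
    x <- cbind(
      age = candidates$age,
      sex_m = as.numeric(candidates$sex == "M"),
      lung_disease = as.numeric(candidates$lung_disease),
      smoking = as.numeric(candidates$smoking),
      diabetes = as.numeric(candidates$diabetes),
      cardiovascular_disease = as.numeric(candidates$cardiovascular_disease),
      cancer = as.numeric(candidates$cancer),
      pra = candidates$pra,
      blood_group_o = as.numeric(candidates$blood_group == "O"),
      state_metro = as.numeric(candidates$state %in% c("NSW", "VIC", "QLD")),
      years_on_dialysis = yrs
    )
    eta <- intercept + as.numeric(x[, needed, drop = FALSE] %*% coef[needed])
    stats::plogis(eta)
  }
}

#' Years on dialysis at a given date
#'
#' Zero for candidates not on dialysis; otherwise days since dialysis
#' start divided by 365.25, floored at 0.
#'
#' @param candidates candidate table.
#' @param date evaluation date.
#' @return numeric vector.
#' @export
years_on_dialysis <- function(candidates, date) {
  yrs <- as.numeric(as.Date(date) - candidates$dialysis_start_date) / 365.25
  yrs[is.na(yrs)] <- 0
  pmax(0, yrs)
}
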