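# Simulation engine: donor stream sampling, the per-donor allocation loop
# (eligibility -> ABO rounds -> scoring -> decision model), and parallel
# replication with reproducible per-replicate substreams.

#' Sample the donor stream
#'
#' Draws `n` donors (default 800) uniformly without replacement from the
#' donor pool and sorts them chronologically by donation date; each is
#' then offered sequentially to the simulated waiting list. Sampling
#' switches to with-replacement (with a warning) only when `n` exceeds the
#' pool.
#'
#' @param donors donor table.
#' @param n stream size.
#' @param seed integer seed.
#' @return a donor data.frame of `n` rows, dates non-decreasing.
#' @export
sample_donor_stream <- function(donors, n, seed = 1L) {
  kap_assert(nrow(donors) > 0, "empty donor pool", class = "kap_size_error")
  with_local_seed(derive_seed(seed, "donor_stream"), {
    if (n > nrow(donors)) {
      warning(sprintf("donor stream size %d exceeds pool %d: sampling with replacement",
                      n, nrow(donors)))
      idx <- sample.int(nrow(donors), n, replace = TRUE)
    } else {
      idx <- sample.int(nrow(donors), n, replace = FALSE)
    }
    out <- donors[idx, , drop = FALSE]
    out <- out[order(out$donation_date, out$id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

empty_match_records <- function() {
  data.frame(
    donor_id = character(0), recipient_id = character(0),
    tier = character(0), abo_round = character(0),
    consideration = integer(0), score = numeric(0),
    waiting_time = numeric(0), transplant_date = as.Date(character(0)),
    centre = character(0),
    recipient_age = numeric(0), recipient_blood_group = character(0),
    recipient_state = character(0), recipient_pra = numeric(0),
    recipient_epts_pct = numeric(0), donor_kdpi_pct = numeric(0),
    stringsAsFactors = FALSE
  )
}

# Split "X;Y" HLA columns once into per-allele vectors for vectorized
# mismatch counting against each donor.
split_hla <- function(tbl) {
  out <- list()
  for (loc in c("a", "b", "dr")) {
    parts <- strsplit(tbl[[paste0("hla_", loc)]], ";", fixed = TRUE)
    out[[paste0(loc, "1")]] <- vapply(parts, `[`, "", 1)
    out[[paste0(loc, "2")]] <- vapply(parts, `[`, "", 2)
  }
  out
}

mismatch_vec <- function(d1, d2, r1, r2) {
  (d1 != r1 & d1 != r2) + (d2 != r1 & d2 != r2)
}

#' Run one full allocation simulation
#'
#' Sequentially offers each donor in the stream to the simulated waiting
#' list. Per donor: (process III only) advance the waiting list to the
#' donation date; apply the configured eligibility filter (none, CORisk or
#' IRisk on EPTS/KDPI percentiles); compute allocation scores; run the
#' national-state-national rounds (national ABO-strict, state ABO-strict
#' in the balance-adjusted centre, national ABO-compatible) with the
#' configured decision model (`sdm0` or `sdm1`); on a match, remove the
#' recipient, log the transplant and update the state ledger; otherwise
#' record a discard. The whole run is deterministic given the master seed.
#'
#' KDPI percentiles are computed against the full donor pool's KDRI and
#' EPTS percentiles against the full candidate pool's raw EPTS (dialysis
#' years evaluated at listing).
#'
#' @param config a `kap_config`.
#' @param candidates candidate pool table.
#' @param donors donor pool table.
#' @param scorer optional exit-risk scorer (default from config).
#' @return list with `records` (MatchRecord data.frame, one row per
#'   donor), `waitlist` (final `kap_waitlist`), `events` (event log
#'   data.frame) and `ledger` (state ledger).
#' @export
run_simulation <- function(config = parse_config(), candidates, donors,
                           scorer = NULL) {
  config <- validate_config(config)
  validate_cohort(candidates, "candidate")
  validate_cohort(donors, "donor")
  seed <- config$seed
  if (is.null(scorer)) scorer <- default_exit_scorer(config)

  stream <- sample_donor_stream(donors, config$donor_sample_size,
                                derive_seed(seed, "stream"))
  state <- initialize_waitlist(candidates, config,
                               start_date = min(stream$donation_date) - 1,
                               seed = seed)

  # reference pools for the percentile conversions
  kdpi_ref <- sort(donors$kdri)
  epts_at_listing <- raw_epts(candidates$age, candidates$prior_kidney_transplant,
                              years_on_dialysis_at_listing(candidates))
  epts_ref <- sort(epts_at_listing)

  cand_hla <- split_hla(candidates)
  stream_hla <- split_hla(stream)
  stream_kdpi <- percentile_score(stream$kdri, kdpi_ref)

  ledger <- new_state_ledger()
  rows <- vector("list", nrow(stream))

  for (d in seq_len(nrow(stream))) {
    donor <- stream[d, , drop = FALSE]
    dday <- donor$donation_date
    if (config$dynamics$enabled && dday > state$clock) {
      state <- advance_to(state, dday, config, scorer, seed)
    }
    res <- offer_donor(state, donor, d, stream_hla, stream_kdpi[d],
                       cand_hla, epts_ref, ledger, config, seed)
    if (!is.na(res$idx)) {
      year <- as.integer(format(dday, "%Y"))
      ledger <- ledger_add(ledger, geodesic_center(donor$state), year,
                           donors = 1L)
      ledger <- ledger_add(ledger,
                           geodesic_center(state$candidates$state[res$idx]),
                           year, transplants = 1L)
      state <- record_transplant(state, res$idx, dday)
    }
    rows[[d]] <- res$record
  }

  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  check_conservation(state)
  list(records = records, waitlist = state, events = event_log(state),
       ledger = ledger)
}

years_on_dialysis_at_listing <- function(candidates) {
  yrs <- as.numeric(candidates$listing_date - candidates$dialysis_start_date) /
    365.25
  yrs[is.na(yrs)] <- 0
  pmax(0, yrs)
}

# One donor's allocation: eligibility, rounds, decision model.
offer_donor <- function(state, donor, donor_pos, stream_hla, kdpi_pct,
                        cand_hla, epts_ref, ledger, config, seed) {
  discard <- function() list(idx = NA_integer_, record = data.frame(
    donor_id = donor$id, recipient_id = NA_character_, tier = NA_character_,
    abo_round = NA_character_, consideration = NA_integer_,
    score = NA_real_, waiting_time = NA_real_,
    transplant_date = donor$donation_date, centre = NA_character_,
    recipient_age = NA_real_, recipient_blood_group = NA_character_,
    recipient_state = NA_character_, recipient_pra = NA_real_,
    recipient_epts_pct = NA_real_, donor_kdpi_pct = kdpi_pct,
    stringsAsFactors = FALSE))

  act <- state$active
  if (length(act) == 0) return(discard())
  cand <- state$candidates[act, , drop = FALSE]
  dday <- donor$donation_date

  mm <- weighted_hla_mismatch(
    mismatch_vec(stream_hla$dr1[donor_pos], stream_hla$dr2[donor_pos],
                 cand_hla$dr1[act], cand_hla$dr2[act]),
    mismatch_vec(stream_hla$a1[donor_pos], stream_hla$a2[donor_pos],
                 cand_hla$a1[act], cand_hla$a2[act]),
    mismatch_vec(stream_hla$b1[donor_pos], stream_hla$b2[donor_pos],
                 cand_hla$b1[act], cand_hla$b2[act]))
  # donors predating a listing are still offered; waiting is floored at 0
  days <- pmax(0, as.numeric(dday - cand$listing_date))
  score <- surrogate_score(mm, cand$pra, days, config)

  epts_now <- raw_epts(cand$age, cand$prior_kidney_transplant,
                       years_on_dialysis(cand, dday))
  epts_pct <- percentile_score(epts_now, epts_ref)

  eligible <- switch(config$eligibility$mode,
    default = rep(TRUE, nrow(cand)),
    corisk = corisk_eligible(epts_pct, kdpi_pct, config$eligibility$c),
    irisk = irisk_eligible(epts_pct, kdpi_pct, config$eligibility$s))

  flags <- consideration_flags(cand, donor, epts_pct, kdpi_pct, config)
  p <- acceptance_probability(cand$pra, mm, config$acceptance$z)
  tier <- route_tier(score, config)
  centre_of <- geodesic_center(cand$state)
  target_centre <- state_balance_target(ledger, donor, config$state_balance)

  rounds <- list(
    list(name = "national", abo = "strict",
         pool = tier == "national" &
           abo_compatible(donor$blood_group, cand$blood_group, "strict")),
    list(name = "state", abo = "strict",
         pool = tier == "state" & centre_of == target_centre &
           abo_compatible(donor$blood_group, cand$blood_group, "strict")),
    list(name = "national", abo = "compatible",
         pool = tier == "national" &
           abo_compatible(donor$blood_group, cand$blood_group, "compatible"))
  )

  dseed <- derive_seed(seed, "donor", donor$id)
  for (rd in rounds) {
    keep <- which(eligible & rd$pool)
    if (length(keep) == 0) next
    offers <- data.frame(id = cand$id[keep], score = score[keep],
                         days_waited = days[keep], p = p[keep],
                         flags[keep, , drop = FALSE],
                         stringsAsFactors = FALSE)
    sel <- if (config$decision_model == "sdm0") {
      sdm0_select(offers)
    } else {
      # per-donor substream, one branch per round
      sdm1_select(offers, seed = derive_seed(dseed, rd$name, rd$abo))
    }
    if (!is.na(sel$index)) {
      j <- keep[sel$index]
      anchor <- if (config$waiting_time_from == "dialysis" &&
                    !is.na(cand$dialysis_start_date[j])) {
        cand$dialysis_start_date[j]
      } else cand$listing_date[j]
      wt <- max(0, as.numeric(dday - anchor))
      rec <- data.frame(
        donor_id = donor$id, recipient_id = cand$id[j], tier = rd$name,
        abo_round = rd$abo, consideration = sel$consideration,
        score = score[j], waiting_time = wt, transplant_date = dday,
        centre = if (rd$name == "state") target_centre else centre_of[j],
        recipient_age = cand$age[j],
        recipient_blood_group = cand$blood_group[j],
        recipient_state = cand$state[j], recipient_pra = cand$pra[j],
        recipient_epts_pct = epts_pct[j], donor_kdpi_pct = kdpi_pct,
        stringsAsFactors = FALSE)
      return(list(idx = act[j], record = rec))
    }
  }
  discard()
}

#' Run replicated simulations, optionally in parallel
#'
#' Replicate `r` runs with a seed derived from `(master seed, r)`, so the
#' result list is identical element-for-element whatever the worker count
#' or scheduling order.
#'
#' @param config a `kap_config`.
#' @param candidates,donors pool tables.
#' @param n_reps number of replicates (default `config$replications`).
#' @param workers parallel workers (default `config$workers`); forked via
#'   \code{parallel::mclapply} where available.
#' @return list of [run_simulation()] outputs, indexed by replicate.
#' @export
replicate_simulation <- function(config = parse_config(), candidates, donors,
                                 n_reps = config$replications,
                                 workers = config$workers) {
  kap_assert(n_reps >= 1 && workers >= 1, "n_reps and workers must be >= 1",
             class = "kap_validation_error")
  one <- function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "replicate", r)
    run_simulation(cfg, candidates, donors)
  }
  if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n_reps), one, mc.cores = workers)
  } else {
    lapply(seq_len(n_reps), one)
  }
}

#' Write match records to CSV
#'
#' @param records MatchRecord data.frame from [run_simulation()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_match_records <- function(records, path) {
  out <- records
  out$transplant_date <- format(out$transplant_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_match_records
#' @export
read_match_records <- function(path) {
  kap_assert(file.exists(path), "records file not found: %s", path,
             class = "kap_io_error")
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  out$transplant_date <- as.Date(out$transplant_date)
  out
}
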