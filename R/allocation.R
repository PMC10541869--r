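# Allocation rules: ABO compatibility, the raw EPTS equation, percentile
# (KDPI / EPTS-percent) conversion, a surrogate two-tier allocation score,
# national/state routing, geodesic centres, CORisk/IRisk eligibility
# filters and the state-balance mechanism.

#' ABO blood-group compatibility
#'
#' `strict` mode requires identical groups (used in the first
#' national-state allocation round); `compatible` mode follows the standard
#' transfusion-style rule used in the final national round: O donates to
#' all, A to A/AB, B to B/AB, AB to AB only.
#'
#' @param donor_bg,recipient_bg blood groups in `{O, A, B, AB}`; vectors
#'   are recycled.
#' @param mode `"strict"` or `"compatible"`.
#' @return logical vector.
#' @export
abo_compatible <- function(donor_bg, recipient_bg,
                           mode = c("strict", "compatible")) {
  mode <- match.arg(mode)
  kap_assert(all(donor_bg %in% BLOOD_GROUPS) &&
               all(recipient_bg %in% BLOOD_GROUPS),
             "unknown blood group", class = "kap_validation_error")
  if (mode == "strict") return(donor_bg == recipient_bg)
  donor_bg == "O" |
    (donor_bg == "A" & recipient_bg %in% c("A", "AB")) |
    (donor_bg == "B" & recipient_bg %in% c("B", "AB")) |
    (donor_bg == "AB" & recipient_bg == "AB")
}

#' Raw EPTS score
#'
#' Estimated Post-Transplant Survival linear predictor (lower = better
#' expected survival):
#' \deqn{0.049\,a\,I(a > 25) + 0.493\,I(\mathrm{prior}) +
#'       0.287\ln(y + 1) + 0.598\,I(y = 0)}
#' with `a` the recipient age in years and `y` years on dialysis. The age
#' indicator is strictly greater than 25; the log is natural.
#'
#' @param age recipient age in years (>= 0).
#' @param prior_transplant logical, any prior solid-organ kidney transplant.
#' @param years_on_dialysis non-negative, dialysis vintage in years.
#' @return numeric raw EPTS; vectorized.
#' @export
raw_epts <- function(age, prior_transplant, years_on_dialysis) {
  kap_assert(all(age >= 0) && all(years_on_dialysis >= 0),
             "age and years_on_dialysis must be >= 0",
             class = "kap_validation_error")
  0.049 * age * (age > 25) +
    0.493 * as.numeric(prior_transplant) +
    0.287 * log(years_on_dialysis + 1) +
    0.598 * (years_on_dialysis == 0)
}

#' Midrank percentile of a value within a reference sample
#'
#' Converts a raw score to its percentile against a reference population
#' using midranks: `100 * (#\{below\} + #\{equal\}/2) / n`. This is the
#' conversion used for KDRI to KDPI (donor quality percentile) and raw
#' EPTS to EPTS-percent (candidate standing percentile), with the
#' simulation's own pools as the default reference.
#'
#' @param value numeric vector of values to convert.
#' @param reference non-empty numeric reference sample.
#' @return percentages in `[0, 100]`, same length as `value`.
#' @export
percentile_score <- function(value, reference) {
  kap_assert(length(reference) > 0, "empty reference sample",
             class = "kap_validation_error")
  sr <- sort(reference)
  n <- length(sr)
  le <- findInterval(value, sr)                    # count <= value
  lt <- findInterval(value, sr, left.open = TRUE)  # count <  value
  100 * (lt + 0.5 * (le - lt)) / n
}

#' Donor-to-recipient HLA mismatch count at one locus
#'
#' Number of donor alleles (with multiplicity, max 2) absent from the
#' recipient's two alleles at the locus. Inputs are the semicolon-joined
#' two-allele labels used by the cohort tables.
#'
#' @param donor_hla single `"X;Y"` label pair for the donor.
#' @param recipient_hla character vector of `"X;Y"` pairs.
#' @return integer vector in `{0, 1, 2}`.
#' @export
hla_mismatch_locus <- function(donor_hla, recipient_hla) {
  d <- strsplit(donor_hla, ";", fixed = TRUE)[[1]]
  kap_assert(length(d) == 2, "donor HLA must hold two alleles",
             class = "kap_validation_error")
  rc <- strsplit(recipient_hla, ";", fixed = TRUE)
  r1 <- vapply(rc, `[`, "", 1)
  r2 <- vapply(rc, `[`, "", 2)
  as.integer((d[1] != r1 & d[1] != r2) + (d[2] != r1 & d[2] != r2))
}

#' Weighted HLA mismatch
#'
#' The acceptance model weights DR mismatches double:
#' `HLA = 2 * DR + A + B`, range 0-8.
#'
#' @param dr,a,b per-locus mismatch counts in `{0, 1, 2}`.
#' @return integer vector in `[0, 8]`.
#' @export
weighted_hla_mismatch <- function(dr, a, b) {
  kap_assert(all(c(dr, a, b) %in% 0:2),
             "mismatch counts must be in {0, 1, 2}",
             class = "kap_validation_error")
  as.integer(2 * dr + a + b)
}

#' Surrogate allocation score
#'
#' The national and five state scoring tables are defined by TSANZ
#' guidelines and are not re-implemented here; the package ships a
#' documented surrogate behind the same interface so the real formulas can
#' be plugged in. The surrogate is
#' `score = level * level_base + min(days_waited, level_base - 1)`, with
#' match level in `{0..6}`:
#' level 6 is reserved for zero weighted HLA mismatch or (weighted
#' mismatch <= 2 and PRA >= 80); otherwise
#' `level = floor((8 - mismatch)/2) + I(PRA >= 50)`, capped at 5.
#' With the default `level_base = 1e7` and `national_threshold = 5.4e7`,
#' only level-6 candidates route nationally, and the score is strictly
#' increasing in waiting time within a level.
#'
#' @param hla_weighted weighted HLA mismatch in `[0, 8]`.
#' @param pra PRA percentage in `[0, 100]`.
#' @param days_waited non-negative days since listing.
#' @param config a `kap_config` (only `scoring$level_base` is used).
#' @return numeric score vector.
#' @export
surrogate_score <- function(hla_weighted, pra, days_waited,
                            config = parse_config()) {
  base <- config$scoring$level_base
  level <- pmin(5, floor((8 - hla_weighted) / 2) + (pra >= 50))
  level[hla_weighted == 0 | (hla_weighted <= 2 & pra >= 80)] <- 6
  level * base + pmin(days_waited, base - 1)
}

#' Allocation score for one candidate-donor pair
#'
#' Computes per-locus mismatches, the weighted HLA mismatch, waiting days
#' from listing, and the configured scoring function (surrogate by
#' default). Raises a temporal error when the candidate is not yet listed.
#'
#' @param candidate one-row candidate data.frame.
#' @param donor one-row donor data.frame.
#' @param today the donation date.
#' @param config a `kap_config`.
#' @return numeric score.
#' @export
allocation_score <- function(candidate, donor, today, config = parse_config()) {
  today <- as.Date(today)
  kap_assert(candidate$listing_date <= today,
             "candidate %s listed after %s", candidate$id, today,
             class = "kap_temporal_error")
  mm <- weighted_hla_mismatch(
    hla_mismatch_locus(donor$hla_dr, candidate$hla_dr),
    hla_mismatch_locus(donor$hla_a, candidate$hla_a),
    hla_mismatch_locus(donor$hla_b, candidate$hla_b))
  days <- as.numeric(today - candidate$listing_date)
  surrogate_score(mm, candidate$pra, days, config)
}

#' Route a score to the national or state tier
#'
#' Scores strictly greater than the national threshold (default
#' 54,000,000) are allocated interstate under the national system; all
#' others fall to the state-based system.
#'
#' @param score numeric score vector (>= 0).
#' @param config a `kap_config`.
#' @return character vector, `"national"` or `"state"`.
#' @export
route_tier <- function(score, config = parse_config()) {
  ifelse(score > config$scoring$national_threshold, "national", "state")
}

#' Geodesic allocation centre for a state
#'
#' ACT, TAS and NT have no allocation centre of their own and are served
#' by NSW, VIC and SA respectively; the five centres are NSW/ACT, VIC/TAS,
#' WA, SA/NT and QLD.
#'
#' @param state character vector of state codes.
#' @return character vector of centre labels.
#' @export
geodesic_center <- function(state) {
  kap_assert(all(state %in% STATES), "unknown state code",
             class = "kap_validation_error")
  map <- c(NSW = "NSW/ACT", ACT = "NSW/ACT", VIC = "VIC/TAS",
           TAS = "VIC/TAS", WA = "WA", SA = "SA/NT", NT = "SA/NT",
           QLD = "QLD")
  unname(map[state])
}

#' CORisk / IRisk longevity-matching eligibility
#'
#' Risk-based filters pairing the candidate's EPTS percentile with the
#' donor's KDPI percentile. CORisk with cut-off `c`: eligible iff both
#' percentiles are `<= c` or both are `>= c` (boundaries inclusive), so
#' good kidneys go to candidates with good expected survival and vice
#' versa. IRisk with bandwidth `s`: eligible iff the EPTS percentile lies
#' within `[KDPI - s, KDPI + s]` (inclusive).
#'
#' @param epts_pct,kdpi_pct percentiles in `[0, 100]`; vectors recycled.
#' @param c,s cut-off / bandwidth in `[0, 100]`.
#' @return logical vector.
#' @export
corisk_eligible <- function(epts_pct, kdpi_pct, c) {
  (epts_pct <= c & kdpi_pct <= c) | (epts_pct >= c & kdpi_pct >= c)
}

#' @rdname corisk_eligible
#' @export
irisk_eligible <- function(epts_pct, kdpi_pct, s) {
  epts_pct >= kdpi_pct - s & epts_pct <= kdpi_pct + s
}

#' State ledger: per-centre yearly donors and transplants
#'
#' Tracks, per allocation centre and calendar year, the number of donors
#' contributed and transplants received; the state-balance mechanism keeps
#' each centre's yearly donors-to-transplants ratio close to one. Counts
#' are updated once per allocated donor and once per transplant.
#'
#' @return `new_state_ledger`: an empty ledger data.frame with columns
#'   `centre`, `year`, `donors`, `transplants`.
#' @export
new_state_ledger <- function() {
  data.frame(centre = character(0), year = integer(0),
             donors = integer(0), transplants = integer(0),
             stringsAsFactors = FALSE)
}

#' @rdname new_state_ledger
#' @param ledger a state ledger.
#' @param centre centre label.
#' @param year calendar year.
#' @param donors,transplants increments.
#' @export
ledger_add <- function(ledger, centre, year, donors = 0L, transplants = 0L) {
  i <- which(ledger$centre == centre & ledger$year == year)
  if (length(i) == 0) {
    ledger <- rbind(ledger, data.frame(centre = centre, year = as.integer(year),
                                       donors = 0L, transplants = 0L,
                                       stringsAsFactors = FALSE))
    i <- nrow(ledger)
  }
  ledger$donors[i] <- ledger$donors[i] + donors
  ledger$transplants[i] <- ledger$transplants[i] + transplants
  ledger
}

ledger_ratio <- function(ledger, centre, year) {
  i <- which(ledger$centre == centre & ledger$year == year)
  if (length(i) == 0) return(1)  # zero donors, zero transplants: balanced
  d <- ledger$donors[i]
  t <- ledger$transplants[i]
  if (t == 0) { if (d == 0) 1 else Inf } else d / t
}

#' Target allocation centre under the state-balance mechanism
#'
#' When enabled and the donor's own centre has contributed more donors
#' than it received transplants this calendar year (ratio > 1), the kidney
#' is redirected to the centre with the smallest yearly
#' donors-to-transplants ratio (a centre in deficit, ratio < 1, is thereby
#' preferred); ties break alphabetically. Otherwise, and always when
#' disabled, the donor's own geodesic centre is used.
#'
#' @param ledger a state ledger.
#' @param donor one-row donor data.frame.
#' @param enabled logical flag.
#' @return a centre label.
#' @export
state_balance_target <- function(ledger, donor, enabled = FALSE) {
  own <- geodesic_center(donor$state)
  if (!isTRUE(enabled)) return(own)
  year <- as.integer(format(as.Date(donor$donation_date), "%Y"))
  if (ledger_ratio(ledger, own, year) <= 1) return(own)
  ratios <- vapply(CENTRES, function(ct) ledger_ratio(ledger, ct, year),
                   numeric(1))
  # CENTRES is alphabetical, so which.min's first match breaks ties
  names(ratios)[which.min(ratios)]
}

#' @rdname new_state_ledger
#' @param path file path for the CSV export (columns centre, year, donors,
#'   transplants, ratio).
#' @export
write_state_ledger <- function(ledger, path) {
  out <- ledger
  out$ratio <- ifelse(out$transplants == 0,
                      ifelse(out$donors == 0, 1, Inf),
                      out$donors / out$transplants)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
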