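# Shared decision-making: the offer-acceptance probability model and the
# two recipient-selection rules (sdm0 = maximum score; sdm1 = nested
# consideration tree with Bernoulli acceptance).

#' Offer-acceptance probability
#'
#' `p = (1 - PRA/100) * (1 - HLA/z)` where HLA is the weighted mismatch
#' and `z` (default 50) tunes the emphasis on HLA mismatch relative to
#' sensitization. The HLA factor is clamped at 0 when the weighted
#' mismatch reaches `z`, so the result is always a probability; a highly
#' sensitized, highly mismatched candidate is unlikely to accept.
#'
#' @param pra PRA percentage in `[0, 100]`.
#' @param hla_weighted weighted HLA mismatch (>= 0).
#' @param z positive scaling divisor.
#' @return probabilities in `[0, 1]`; vectorized.
#' @export
acceptance_probability <- function(pra, hla_weighted, z = 50) {
  kap_assert(all(pra >= 0 & pra <= 100) && all(hla_weighted >= 0) && z > 0,
             "pra in [0,100], hla_weighted >= 0, z > 0 required",
             class = "kap_validation_error")
  (1 - pra / 100) * pmax(0, 1 - hla_weighted / z)
}

#' Consideration flags for the nested decision tree
#'
#' Four consideration variables, evaluated in fixed order:
#' \enumerate{
#'   \item pediatric: candidate under 18 and donor within 30 years of age;
#'   \item quality gap between donor and recipient: applicable when the
#'     candidate's EPTS percentile is at least the donor's KDPI percentile
#'     minus the configured slack (i.e. the kidney is at least as good as
#'     the candidate's standing); with `alpha2_scale = "raw"` the gap is
#'     raw EPTS minus KDRI instead;
#'   \item AB-to-AB: both candidate and donor blood group AB;
#'   \item same state: no interstate transport needed.
#' }
#'
#' @param candidates candidate data.frame (any number of rows).
#' @param donor one-row donor data.frame.
#' @param epts_pct candidate EPTS percentiles (or raw EPTS when
#'   `alpha2_scale = "raw"`).
#' @param kdpi_pct donor KDPI percentile (or raw KDRI).
#' @param config a `kap_config` (acceptance block).
#' @return data.frame of logicals `alpha1..alpha4`, one row per candidate.
#' @export
consideration_flags <- function(candidates, donor, epts_pct, kdpi_pct,
                                config = parse_config()) {
  thr <- config$acceptance$alpha2_threshold
  gap_ok <- if (config$acceptance$alpha2_scale == "percentile") {
    epts_pct / 100 >= kdpi_pct / 100 - thr
  } else {
    epts_pct - kdpi_pct >= -thr
  }
  data.frame(
    alpha1 = candidates$age < 18 & abs(candidates$age - donor$age) < 30,
    alpha2 = gap_ok,
    alpha3 = candidates$blood_group == "AB" & donor$blood_group == "AB",
    alpha4 = candidates$state == donor$state
  )
}

#' Select a recipient by maximum allocation score (sdm0)
#'
#' Returns the row index of the highest-scoring offer; ties break by
#' longer waiting time, then id order. No acceptance randomness.
#'
#' @param offers data.frame with columns `score`, `days_waited`, `id`.
#' @return list with `index` (row index or `NA`) and `consideration`
#'   (always `NA` for sdm0).
#' @export
sdm0_select <- function(offers) {
  if (nrow(offers) == 0) return(list(index = NA_integer_,
                                     consideration = NA_integer_))
  ord <- order(-offers$score, -offers$days_waited, offers$id)
  list(index = ord[1], consideration = NA_integer_)
}

#' Select a recipient by the nested consideration tree (sdm1)
#'
#' Offers are walked in descending score order. For each candidate the
#' acceptance probability `p` is computed once; then the four
#' considerations are tried in order 1 to 4, and each *applicable*
#' consideration draws one Bernoulli(`p`) acceptance. The first success
#' returns that candidate together with the index of the consideration
#' that fired; when all applicable considerations of a candidate fail, the
#' next candidate is tried; when every candidate is exhausted the kidney
#' goes unallocated. Non-applicable considerations consume no randomness,
#' so draw counts are reproducible.
#'
#' @param offers data.frame with columns `id`, `score`, `days_waited`,
#'   `p` (acceptance probability) and logical `alpha1..alpha4`.
#' @param seed integer seed for the per-donor decision substream.
#' @param draws optional numeric vector of forced uniform draws in
#'   `[0, 1]`, consumed in order (for deterministic traces); acceptance is
#'   `draw < p`.
#' @return list with `index` (row index into `offers`, or `NA`) and
#'   `consideration` (1-4, or `NA`).
#' @export
sdm1_select <- function(offers, seed = 1L, draws = NULL) {
  empty <- list(index = NA_integer_, consideration = NA_integer_)
  if (nrow(offers) == 0) return(empty)
  ord <- order(-offers$score, -offers$days_waited, offers$id)
  k <- 0L
  next_draw <- function() {
    k <<- k + 1L
    if (!is.null(draws)) {
      kap_assert(k <= length(draws), "forced draw sequence exhausted",
                 class = "kap_validation_error")
      draws[k]
    } else {
      stats::runif(1)
    }
  }
  walk <- function() {
    for (j in ord) {
      p <- offers$p[j]
      for (i in 1:4) {
        if (isTRUE(offers[[paste0("alpha", i)]][j])) {
          if (next_draw() < p) {
            return(list(index = j, consideration = i))
          }
        }
      }
    }
    empty
  }
  if (is.null(draws)) with_local_seed(seed, walk()) else walk()
}
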