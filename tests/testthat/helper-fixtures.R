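# Shared fixtures: small pools and configs built in code at test time.

fixture_marginals <- function() cohort_marginals()

# Moderate pools reused across engine/cli tests (built once per run).
small_candidates <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_candidates(2500, fixture_marginals(),
                                                  seed = 42)
    val
  }
})

# Donation window kept to two years so dynamic runs cannot exhaust the
# small candidate pool.
small_donors <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_donors(600, fixture_marginals(),
                                              seed = 42,
                                              start_date = "2010-01-01",
                                              end_date = "2011-12-31")
    val
  }
})

# Config scaled down for fast engine tests.
small_config <- function(...) {
  parse_config(overrides = modifyList(list(
    donor_sample_size = 120,
    dynamics = list(n0 = 150),
    seed = 11
  ), list(...)))
}

# A donor/candidate pair set where acceptance is certain: PRA 0 and
# identical HLA alleles everywhere (weighted mismatch 0 -> p = 1), same
# state so alpha4 always applies.
saturated_pools <- function(n_cand = 60, n_don = 10) {
  cand <- generate_candidates(n_cand, fixture_marginals(), seed = 5)
  don <- generate_donors(n_don, fixture_marginals(), seed = 5)
  cand$pra <- 0
  cand$hla_a <- "A1;A2"; cand$hla_b <- "B7;B8"; cand$hla_dr <- "DR1;DR4"
  don$hla_a <- "A1;A2"; don$hla_b <- "B7;B8"; don$hla_dr <- "DR1;DR4"
  cand$state <- "NSW"; don$state <- "NSW"
  cand$blood_group <- "O"; don$blood_group <- "O"
  list(candidates = cand, donors = don)
}

# One-row candidate/donor builders for unit tests.
toy_candidate <- function(id = "C1", age = 40, sex = "M", blood_group = "O",
                          state = "NSW", pra = 0, hla_a = "A1;A2",
                          hla_b = "B7;B8", hla_dr = "DR1;DR4",
                          listing_date = as.Date("2010-01-01"),
                          dialysis_start_date = as.Date(NA),
                          prior_kidney_transplant = FALSE) {
  data.frame(id = id, age = age, sex = sex, blood_group = blood_group,
             state = state, pra = pra, hla_a = hla_a, hla_b = hla_b,
             hla_dr = hla_dr, listing_date = listing_date,
             dialysis_start_date = dialysis_start_date,
             prior_kidney_transplant = prior_kidney_transplant,
             lung_disease = FALSE, smoking = FALSE, diabetes = FALSE,
             cardiovascular_disease = FALSE, cancer = FALSE,
             stringsAsFactors = FALSE)
}

toy_donor <- function(id = "D1", age = 45, blood_group = "O", state = "NSW",
                      kdri = 1, donation_date = as.Date("2012-01-01"),
                      hla_a = "A1;A2", hla_b = "B7;B8", hla_dr = "DR1;DR4") {
  data.frame(id = id, age = age, blood_group = blood_group, state = state,
             kdri = kdri, donation_date = donation_date, hla_a = hla_a,
             hla_b = hla_b, hla_dr = hla_dr, stringsAsFactors = FALSE)
}

# Total-variation distance between a realized categorical sample and a
# target frequency vector.
tv_distance <- function(x, target) {
  freq <- prop.table(table(factor(x, levels = names(target))))
  sum(abs(as.numeric(freq) - as.numeric(target))) / 2
}
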