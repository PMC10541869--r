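# Allocation rules: ABO matrix, raw EPTS, percentiles, surrogate score,
# tier routing, geodesic centres, CORisk/IRisk, state balance.

test_that("ABO compatible-mode matrix has exactly the 9 expected true cells", {
  grid <- expand.grid(donor = c("O", "A", "B", "AB"),
                      recipient = c("O", "A", "B", "AB"),
                      stringsAsFactors = FALSE)
  grid$ok <- abo_compatible(grid$donor, grid$recipient, "compatible")
  expect_equal(sum(grid$ok), 9)
  expected <- list(c("O", "O"), c("O", "A"), c("O", "B"), c("O", "AB"),
                   c("A", "A"), c("A", "AB"), c("B", "B"), c("B", "AB"),
                   c("AB", "AB"))
  for (pair in expected) {
    expect_true(abo_compatible(pair[1], pair[2], "compatible"),
                label = paste(pair, collapse = "->"))
  }
  expect_false(abo_compatible("A", "O", "compatible"))
  expect_false(abo_compatible("O", "A", "strict"))
  expect_true(abo_compatible("A", "A", "strict"))
  # strict implies compatible
  strict <- abo_compatible(grid$donor, grid$recipient, "strict")
  expect_true(all(!strict | grid$ok))
  expect_error(abo_compatible("X", "O", "strict"),
               class = "kap_validation_error")
})

test_that("raw EPTS reproduces its printed structure", {
  expect_equal(raw_epts(20, FALSE, 0), 0.598)
  expect_equal(raw_epts(25, FALSE, 0), 0.598)  # age indicator strict at 25
  expect_equal(raw_epts(30, TRUE, 0), 2.561)   # 0.049*30 + 0.493 + 0.598
  expect_equal(raw_epts(50, FALSE, exp(1) - 1), 0.049 * 50 + 0.287)
  # monotone in age and prior-transplant flag
  ages <- seq(0, 90, by = 5)
  expect_true(all(diff(raw_epts(ages, FALSE, 2)) >= 0))
  expect_true(all(raw_epts(ages, TRUE, 2) > raw_epts(ages, FALSE, 2)))
  # jump at zero dialysis years from the 0.598 indicator
  expect_gt(raw_epts(40, FALSE, 0), raw_epts(40, FALSE, 1e-9))
  expect_error(raw_epts(-1, FALSE, 0), class = "kap_validation_error")
})

test_that("midrank percentile matches its closed form", {
  ref <- c(5, 1, 3, 2, 4)
  expect_equal(percentile_score(1, ref), 100 * 0.5 / 5)  # unique minimum
  expect_equal(percentile_score(101, 1:100), 100)
  expect_equal(percentile_score(7, rep(7, 13)), 50)
  # monotone non-decreasing in value
  v <- sort(runif(50))
  expect_true(all(diff(percentile_score(v, runif(30))) >= 0))
  expect_error(percentile_score(1, numeric(0)),
               class = "kap_validation_error")
})

test_that("HLA mismatch counts donor alleles absent from the recipient", {
  expect_equal(hla_mismatch_locus("A1;A2", c("A1;A2", "A1;A3", "A3;A4")),
               c(0L, 1L, 2L))
  expect_equal(hla_mismatch_locus("A1;A1", "A2;A3"), 2L)  # multiplicity
  expect_equal(hla_mismatch_locus("A1;A1", "A1;A3"), 0L)
  expect_equal(weighted_hla_mismatch(2, 2, 2), 8L)
  expect_equal(weighted_hla_mismatch(1, 0, 0), 2L)
  expect_equal(weighted_hla_mismatch(0, 0, 0), 0L)
  expect_error(weighted_hla_mismatch(3, 0, 0), class = "kap_validation_error")
})

test_that("surrogate score is monotone in waiting time and routes zero-mismatch nationally", {
  cfg <- parse_config()
  expect_gt(surrogate_score(4, 10, 200, cfg), surrogate_score(4, 10, 100, cfg))
  expect_equal(surrogate_score(8, 0, 0, cfg), 0)
  # zero mismatch -> level 6 -> 6e7 > 5.4e7 threshold
  s <- surrogate_score(0, 0, 1, cfg)
  expect_gt(s, cfg$scoring$national_threshold)
  expect_equal(route_tier(s, cfg), "national")
  # highly sensitized with low mismatch also reaches the national tier
  expect_equal(route_tier(surrogate_score(2, 85, 0, cfg), cfg), "national")
})

test_that("allocation_score raises a temporal error for future listings", {
  cand <- toy_candidate(listing_date = as.Date("2015-01-01"))
  don <- toy_donor(donation_date = as.Date("2012-01-01"))
  expect_error(allocation_score(cand, don, don$donation_date),
               class = "kap_temporal_error")
  # listed earlier: deterministic arithmetic
  cand$listing_date <- as.Date("2011-01-01")
  expect_equal(allocation_score(cand, don, don$donation_date),
               surrogate_score(0, 0, 365, parse_config()))
})

test_that("tier routing switches strictly at the national threshold", {
  cfg <- parse_config()
  expect_equal(route_tier(54000001, cfg), "national")
  expect_equal(route_tier(54000000, cfg), "state")
  expect_equal(route_tier(0, cfg), "state")
})

test_that("geodesic centres absorb ACT, TAS and NT", {
  expect_equal(geodesic_center(c("ACT", "TAS", "NT")),
               c("NSW/ACT", "VIC/TAS", "SA/NT"))
  expect_equal(geodesic_center(c("NSW", "VIC", "SA", "WA", "QLD")),
               c("NSW/ACT", "VIC/TAS", "SA/NT", "WA", "QLD"))
  expect_error(geodesic_center("NZ"), class = "kap_validation_error")
})

test_that("CORisk pairs like with like, boundaries inclusive", {
  expect_false(corisk_eligible(20, 50, c = 40))  # good EPTS, poor kidney
  expect_true(corisk_eligible(30, 30, c = 40))
  expect_true(corisk_eligible(40, 40, c = 40))   # boundary, both branches
  expect_true(corisk_eligible(60, 80, c = 40))
  expect_false(corisk_eligible(50, 20, c = 40))
  # degenerate cut-offs accept every pair
  g <- expand.grid(e = seq(0, 100, 10), k = seq(0, 100, 10))
  expect_true(all(corisk_eligible(g$e, g$k, c = 0)))
  expect_true(all(corisk_eligible(g$e, g$k, c = 100)))
})

test_that("IRisk accepts within the symmetric KDPI band, inclusive", {
  expect_true(irisk_eligible(30, 50, s = 20))   # lower boundary
  expect_false(irisk_eligible(29, 50, s = 20))
  expect_true(irisk_eligible(70, 50, s = 20))   # upper boundary
  expect_false(irisk_eligible(71, 50, s = 20))
  expect_true(all(irisk_eligible(seq(0, 100, 5), 42, s = 100)))
  expect_true(irisk_eligible(33, 33, s = 0))    # zero-width containment
})

test_that("state balance redirects from surplus centres to the deficit centre", {
  don <- toy_donor(state = "NSW",
                   donation_date = as.Date("2014-06-01"))
  led <- new_state_ledger()
  # disabled -> own centre regardless of ledger
  expect_equal(state_balance_target(led, don, enabled = FALSE), "NSW/ACT")
  # empty ledger (all ratios 1) -> own centre
  expect_equal(state_balance_target(led, don, enabled = TRUE), "NSW/ACT")
  # donor centre ratio 5/3, another centre 2/4 -> redirect there
  led <- ledger_add(led, "NSW/ACT", 2014, donors = 5L, transplants = 3L)
  led <- ledger_add(led, "QLD", 2014, donors = 2L, transplants = 4L)
  expect_equal(state_balance_target(led, don, enabled = TRUE), "QLD")
  # a different calendar year resets nothing within-year: 2015 is balanced
  don15 <- toy_donor(state = "NSW", donation_date = as.Date("2015-02-01"))
  expect_equal(state_balance_target(led, don15, enabled = TRUE), "NSW/ACT")
})
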