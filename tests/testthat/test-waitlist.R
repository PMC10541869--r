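# Waiting-list dynamics: stratified initialization, Poisson arrivals and
# departures, exit-risk ranking, composition and conservation.

test_that("initialization draws exactly n0 candidates and honours degenerate targets", {
  pool <- generate_candidates(3000, fixture_marginals(), seed = 21)
  cfg <- parse_config()
  st <- initialize_waitlist(pool, cfg, seed = 1)
  expect_equal(length(st$active), 300)
  expect_equal(length(st$active) + length(st$pool), nrow(pool))
  expect_equal(sum(event_log(st)$event == "init"), 300)

  # all target mass on one blood group -> everyone sampled from it
  cfg2 <- small_config()
  st2 <- initialize_waitlist(pool, cfg2, seed = 1,
                             strata_targets = list(blood_group = c(
                               O = 1, A = 0, B = 0, AB = 0)))
  expect_true(all(pool$blood_group[st2$active] == "O"))
})

test_that("stratified initialization pulls realized frequencies toward the target", {
  pool <- generate_candidates(10000, fixture_marginals(), seed = 22)
  cfg <- parse_config()
  target <- c(O = 0.25, A = 0.25, B = 0.25, AB = 0.25)
  st <- initialize_waitlist(pool, cfg, seed = 3,
                            strata_targets = list(blood_group = target))
  realized <- pool$blood_group[st$active]
  expect_lt(tv_distance(realized, target), 0.1)
  # and much closer to uniform than the heavily skewed pool itself
  expect_gt(tv_distance(pool$blood_group, target),
            tv_distance(realized, target))
})

test_that("an empty target stratum renormalizes with a warning", {
  pool <- generate_candidates(500, fixture_marginals(), seed = 23)
  pool <- pool[pool$blood_group != "AB", ]
  cfg <- small_config()
  expect_warning(
    st <- initialize_waitlist(pool, cfg, seed = 1,
                              strata_targets = list(blood_group = c(
                                O = 0.4, A = 0.3, B = 0.2, AB = 0.1))),
    "renormalized")
  expect_equal(length(st$active), cfg$dynamics$n0)
})

test_that("a pool smaller than n0 is a size error", {
  pool <- generate_candidates(100, fixture_marginals(), seed = 2)
  expect_error(initialize_waitlist(pool, parse_config(), seed = 1),
               class = "kap_size_error")
})

test_that("zero rates yield identity dynamics; clock still advances", {
  pool <- generate_candidates(400, fixture_marginals(), seed = 31)
  cfg <- small_config(dynamics = list(n0 = 100, lambda_in = 0,
                                      lambda_out = 0))
  st <- initialize_waitlist(pool, cfg, start_date = as.Date("2010-01-01"),
                            seed = 1)
  st2 <- advance_to(st, as.Date("2010-01-31"), cfg)
  expect_identical(st2$active, st$active)
  expect_equal(st2$clock, as.Date("2010-01-31"))
  expect_identical(advance_to(st, st$clock, cfg)$active, st$active)
  expect_error(advance_to(st2, as.Date("2010-01-01"), cfg),
               class = "kap_temporal_error")
})

test_that("arrival and departure rates recover their configured values", {
  # MLE of a Poisson rate is the sample mean; over 2000 days it must land
  # within 3 standard errors of the configured rate
  pool <- generate_candidates(3500, fixture_marginals(), seed = 32)
  cfg <- small_config(dynamics = list(n0 = 300, lambda_in = 0.7,
                                      lambda_out = 0.4))
  st <- initialize_waitlist(pool, cfg, start_date = as.Date("2008-01-01"),
                            seed = 8)
  days <- 2000
  st <- advance_to(st, as.Date("2008-01-01") + days, cfg)
  ev <- event_log(st)
  arr <- sum(ev$event == "arrival") / days
  dep <- sum(ev$event == "departure") / days
  expect_lt(abs(arr - 0.7), 3 * sqrt(0.7 / days))
  expect_lt(abs(dep - 0.4), 3 * sqrt(0.4 / days))
  check_conservation(st)
})

test_that("yearly rate multipliers scale arrivals in their year only", {
  pool <- generate_candidates(4000, fixture_marginals(), seed = 33)
  cfg <- small_config(dynamics = list(
    n0 = 50, lambda_in = 0.7, lambda_out = 0,
    k_in = list(list(year = 2011, multiplier = 2))))
  st <- initialize_waitlist(pool, cfg, start_date = as.Date("2009-12-31"),
                            seed = 4)
  st <- advance_to(st, as.Date("2011-12-31"), cfg)
  ev <- event_log(st)
  yr <- format(ev$date[ev$event == "arrival"], "%Y")
  r2010 <- sum(yr == "2010") / 365
  r2011 <- sum(yr == "2011") / 365
  # ratio test: 2011 runs at twice the 2010 rate
  expect_gt(r2011 / r2010, 1.5)
  expect_lt(abs(r2010 - 0.7), 4 * sqrt(0.7 / 365))
  expect_lt(abs(r2011 - 1.4), 4 * sqrt(1.4 / 365))
})

test_that("departures remove exactly the top-n candidates by exit risk", {
  # forced draw: brute-force full-sort oracle on a list of 100
  pool <- generate_candidates(100, fixture_marginals(), seed = 34)
  cfg <- small_config(dynamics = list(n0 = 100, lambda_out = 50))
  st <- initialize_waitlist(pool, cfg, start_date = as.Date("2010-01-01"),
                            seed = 1)
  scorer <- default_exit_scorer(cfg)
  day <- as.Date("2010-01-02")
  st2 <- step_departures(st, day, cfg, scorer)
  ev <- event_log(st2)
  gone <- ev$id[ev$event == "departure"]
  n_out <- length(gone)
  expect_gt(n_out, 20)  # Poisson(50) fires well above 20

  act <- st$candidates[st$active, ]
  sc <- scorer(act, day)
  oracle <- act$id[order(-sc, act$listing_date, act$id)][seq_len(n_out)]
  expect_setequal(gone, oracle)
})

test_that("departure draws exceeding the active list empty it with a warning", {
  pool <- generate_candidates(60, fixture_marginals(), seed = 35)
  cfg <- small_config(dynamics = list(n0 = 5, lambda_out = 40))
  st <- initialize_waitlist(pool, cfg, start_date = as.Date("2010-01-01"),
                            seed = 1)
  expect_warning(st2 <- step_departures(st, as.Date("2010-01-02"), cfg),
                 "exceeds")
  expect_length(st2$active, 0)
})

test_that("advancing in two steps equals one combined advance exactly", {
  pool <- generate_candidates(2000, fixture_marginals(), seed = 36)
  cfg <- small_config(dynamics = list(n0 = 200))
  st0 <- initialize_waitlist(pool, cfg, start_date = as.Date("2010-01-01"),
                             seed = 6)
  one <- advance_to(st0, as.Date("2010-07-01"), cfg)
  two <- advance_to(advance_to(st0, as.Date("2010-04-01"), cfg),
                    as.Date("2010-07-01"), cfg)
  expect_identical(event_log(one), event_log(two))
  expect_identical(one$active, two$active)

  # and the whole trajectory is seed-reproducible
  again <- advance_to(st0, as.Date("2010-07-01"), cfg)
  expect_identical(event_log(one), event_log(again))
  expect_true(all(diff(as.integer(event_log(one)$date)) >= 0))
})

test_that("the logistic exit scorer honours its contract", {
  cfg <- parse_config()
  cand <- generate_candidates(50, fixture_marginals(), seed = 37)
  # all-zero coefficients with zero intercept -> logistic(0) = 0.5 for all
  zero <- cfg$exit_scorer
  zero$intercept <- 0
  zero$coefficients <- lapply(zero$coefficients, function(x) 0)
  expect_equal(default_exit_scorer(zero)(cand, Sys.Date()),
               rep(0.5, nrow(cand)))

  # finite at extreme ages
  ext <- rbind(toy_candidate(age = 0), toy_candidate(id = "C2", age = 90))
  expect_true(all(is.finite(default_exit_scorer(cfg)(ext, Sys.Date()))))

  # doubling the age coefficient never demotes an older candidate's rank
  young <- toy_candidate(id = "Cy", age = 30)
  old <- toy_candidate(id = "Co", age = 70)
  both <- rbind(young, old)
  s1 <- default_exit_scorer(cfg)(both, Sys.Date())
  doubled <- cfg$exit_scorer
  doubled$coefficients$age <- 2 * doubled$coefficients$age
  s2 <- default_exit_scorer(doubled)(both, Sys.Date())
  expect_gte(s2[2] - s2[1], s1[2] - s1[1])

  # missing coefficient is a configuration error
  broken <- cfg$exit_scorer
  broken$coefficients$age <- NULL
  expect_error(default_exit_scorer(broken), class = "kap_config_error")
})
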