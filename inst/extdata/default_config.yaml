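# Default run configuration. Single source of truth for the simulator's
# tunables; parse_config() layers a user file and then explicit overrides
# on top of these values and validates the result.

seed: 1
process: "III"          # I: max-score, static list; II: sdm1, static list;
                        # III: sdm1 + dynamic waiting list
decision_model: "sdm1"  # forced by process: I -> sdm0, II/III -> sdm1
donor_sample_size: 800
state_balance: false
replications: 1
workers: 1
waiting_time_from: "listing"   # or "dialysis" (KRT anchor)

dynamics:
  n0: 300               # initial waiting-list size
  lambda_in: 0.7        # daily arrival rate (Poisson)
  lambda_out: 0.4       # daily departure rate (Poisson)
  k_in: []              # piecewise-constant yearly multipliers,
                        # e.g. [{year: 2010, multiplier: 2}]
  k_out: []
  reentry_prob: 0.0     # daily re-listing probability for departed candidates

scoring:
  national_threshold: 54000000   # scores above this are allocated nationally
  level_base: 10000000           # score units per match level

eligibility:
  mode: "default"       # default | corisk | irisk
  c: 40                 # CORisk cut-off, percent
  s: 20                 # IRisk bandwidth, percent

acceptance:
  z: 50                 # HLA scaling divisor in p = (1-PRA/100)(1-HLA/z)
  alpha2_threshold: 0   # quality-gap slack, on the percentile/100 scale
  alpha2_scale: "percentile"     # or "raw" (raw EPTS minus KDRI)

# Logistic-linear exit-without-transplant scorer: eleven recipient
# features; higher score = removed earlier when departures fire.
exit_scorer:
  intercept: -3.0
  coefficients:
    age: 0.020
    sex_m: 0.10
    lung_disease: 0.50
    smoking: 0.30
    diabetes: 0.40
    cardiovascular_disease: 0.50
    cancer: 0.70
    pra: 0.005
    blood_group_o: 0.00
    state_metro: -0.10
    years_on_dialysis: 0.08
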