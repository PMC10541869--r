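---
title: "Simulating the deceased-donor kidney allocation process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the deceased-donor kidney allocation process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kapsim)
```

## The model

Deceased-donor kidneys are scarce, and allocation policy decides who
receives them. `kapsim` simulates the whole allocation pipeline as a
discrete-event process with three coupled phases, so that a proposed rule
change can be evaluated in silico before it touches patients.

**Phase A - the dynamic waiting list.** The active candidate set $W_t$
starts from $n_0 = 300$ members drawn from a candidate pool by stratified
sampling over four clinically load-bearing variables (age band, blood
group, state of residence, PRA sensitization band), with weights
`target frequency / pool frequency` so the realized list matches a target
composition. Each simulated day then draws arrivals
$\sim \mathrm{Poisson}(k_{in}(t)\,\lambda_{in})$ and departures
$\sim \mathrm{Poisson}(k_{out}(t)\,\lambda_{out})$, with defaults
$\lambda_{in} = 0.7$ and $\lambda_{out} = 0.4$ per day and
piecewise-constant yearly multipliers $k(t)$ for secular trends. Arrivals
are drawn from the reservoir with the same stratified weights; departures
remove the candidates with the *highest exit-without-transplant risk*, as
ranked by a pluggable scorer. The default scorer is a logistic-linear
model over eleven recipient features (age, sex, five comorbidity flags,
PRA, blood group O, a metropolitan-state indicator, years on dialysis)
with coefficients in the packaged config; any
`function(candidates, date) -> numeric` can replace it, e.g. a random
survival forest fitted where training data exist. Departure is permanent
by default; a daily re-entry probability (default 0) exposes the
alternative reading in which departures are temporary stand-downs.

**Phase B - the allocation rule.** Each donor is offered through a
two-tier national/state system: candidates whose allocation score
strictly exceeds 54,000,000 compete nationally, the rest within the
donor's geodesic allocation centre (ACT, TAS and NT are served by
NSW, VIC and SA). The true national and five state scoring tables are
guideline-defined and deliberately *not* re-implemented; the package ships
a documented surrogate,
$\mathrm{score} = \ell \cdot 10^7 + \min(\text{days waited}, 10^7 - 1)$,
where the match level $\ell \in \{0,\dots,6\}$ is a function of the
weighted HLA mismatch and PRA, with level 6 reserved for zero-mismatch or
(mismatch $\le 2$ and PRA $\ge 80$) offers. The surrogate preserves the
routing semantics of the threshold and strict monotonicity in waiting
time within a level, and sits behind a pluggable interface so the real
tables can be supplied. Offers proceed through national-state-national
rounds: national and state under ABO-identical matching, then a final
national round under ABO-compatible matching (O donates to all, A to
A/AB, B to B/AB, AB to AB). An optional state-balance mechanism redirects
state-tier kidneys from centres whose yearly donors-to-transplants ratio
exceeds one toward the centre with the smallest ratio.

Two hypothetical longevity-matching filters restrict eligibility before
scoring, both on percentile scales: the donor's KDPI (midrank percentile
of KDRI in the donor pool) and the candidate's EPTS percentile (midrank
percentile of raw EPTS in the candidate pool, with
$\text{raw EPTS} = 0.049\,a\,I(a>25) + 0.493\,I(\text{prior Tx}) +
0.287\ln(y+1) + 0.598\,I(y=0)$ for age $a$ and dialysis years $y$).
CORisk with cut-off $c$ pairs both-below-$c$ with both-above-$c$
(inclusive boundaries, since both sides are stated as "or less"/"or
more"); IRisk with bandwidth $s$ requires the EPTS percentile to lie in
$[\mathrm{KDPI}-s, \mathrm{KDPI}+s]$.

**Phase C - shared decision-making.** Clinician-patient acceptance is
stochastic. `sdm0` simply takes the top-scoring candidate. `sdm1` walks
the eligible candidates in descending score order through a nested
consideration tree: pediatric bonus ($\alpha_1$: age under 18 and donor
within 30 years), quality gap ($\alpha_2$), AB-to-AB preference
($\alpha_3$), same-state convenience ($\alpha_4$). Each *applicable*
consideration draws one Bernoulli acceptance with
$p = (1 - \mathrm{PRA}/100)(1 - \mathrm{HLA}/z)$, where
$\mathrm{HLA} = 2\,\mathrm{DR} + \mathrm{A} + \mathrm{B}$ weights DR
mismatches double and $z = 50$ by default; the first success seals the
match and records which consideration fired. The HLA factor is clamped at
zero once the weighted mismatch reaches $z$, keeping $p$ a probability.

## Design choices where the design was open

* **$\alpha_2$ scales.** Written as raw EPTS minus KDRI, the quality gap
  mixes a linear-predictor scale with a relative-risk scale. The default
  evaluates both sides as percentiles and treats $\alpha_2$ as applicable
  when the candidate's EPTS percentile is at least the donor's KDPI
  percentile minus a slack (default 0) - the kidney is at least as good
  as the candidate's standing. The raw-difference form remains available
  (`acceptance$alpha2_scale: raw`).
* **Rejected candidates try all four considerations** before the next
  candidate is offered; one Bernoulli draw per applicable consideration,
  in fixed order 1-4, non-applicable branches consuming no randomness.
* **Round 3 stays within the national tier** (score above threshold),
  consistent with tier-labelled match records; whether the second
  national round widens the candidate set is not determinable from the
  rule's published description.
* **Donor HLA.** Mismatch counts need donor typing, so the donor schema
  carries two alleles per locus; a donor-to-recipient mismatch at a locus
  is the number of donor alleles (with multiplicity) absent from the
  recipient's pair.
* **Initial waiting times.** Initial list members whose generated listing
  date falls after the simulation start have it reflected across the
  start date, giving a standing list accumulated over past years without
  extra random draws.
* **Eleven exit-scorer features.** Only seven are canonical (age, sex,
  lung disease, smoking, diabetes, cardiovascular disease, cancer); PRA,
  blood group, state and years on dialysis complete the set and are
  configurable, not canonical.

## Reproducibility and numerical choices

Every source of randomness derives a substream seed from the master seed
and a structural key (calendar day, donor id, replicate index) via a
Lehmer-style integer mix modulo $2^{31}-1$. Consequences, all tested:
advancing the list in two calls equals one combined advance *exactly*;
per-donor decisions are independent of donor processing order; and
`replicate_simulation()` returns identical results whatever the worker
count. Ties are always broken deterministically: departures by earlier
listing date then id, selection by longer waiting time then id,
state-balance redirection alphabetically.

Percentile conversions use midranks, `100 (\#below + \#equal/2)/n`, so a
value equal to a constant reference sits at 50. Kurtosis is Pearson
(non-excess) $m_4/m_2^2$. Degenerate inputs fail loudly: empty reference
pools, zero-variance samples for kurtosis, non-positive medians for
log-ratios, inverted date ranges.

## The synthetic cohort generator

Registry extracts are access-restricted, so testing runs on synthetic
tables with the same schema. The generator draws every field
independently from configurable marginals (packaged defaults: blood
groups O/A/B/AB at 0.49/0.38/0.10/0.03, Australian-state frequencies by
population share, PRA with a 55% point mass at zero, log-normal KDRI with
$\mu = 0, \sigma = 0.3$, realistic broad-antigen HLA pools). What it does
*not* emulate: correlation among comorbidities and between age and
comorbidity, HLA linkage disequilibrium, secular trends in listing
practice, or the joint donor-candidate geography of a real registry.
Passing tests therefore demonstrate that the *mechanisms* (queueing
rates, ranking, routing, filters, acceptance calibration) are correct,
not that simulated outputs match any particular registry's allocations -
that comparison is exactly what the ACCA suite is for when real records
are available.

## Validating against observed allocations (ACCA)

`acca_compare()` contrasts two MatchRecord sets on the national:state
split (difference and Hellinger distance), recipient waiting time
(Kolmogorov-Smirnov statistic, kurtosis difference, median
$|\log(\text{actual}/\text{simulated})|$), per-centre percentages
(Hellinger), and stratified median-log-ratio tables by state, age band,
EPTS quintile, PRA band and blood group. The aggregate dissimilarity is
the unweighted mean of the components after normalization (bounded
metrics pass through; unbounded ones are squashed by $1 - e^{-x}$); the
aggregation is isolated in `dissimilarity_score()` so another blend can
be swapped in.

## Problem sizes and worked example

The packaged defaults ($n_0 = 300$ initial candidates, 800-donor stream,
$\lambda_{in} = 0.7$, $\lambda_{out} = 0.4$) run in seconds; the test
suite exercises rate recovery over 10,000 simulated days and acceptance
calibration over 10,000 seeded offers, and scales engine tests down to
120-donor streams on 2,500-candidate pools - sizes chosen to give tight
stochastic bounds (4 CLT standard errors) while keeping a full check run
short.

```{r example, eval = FALSE}
m <- cohort_marginals()
candidates <- generate_candidates(8000, m, seed = 1)
donors <- generate_donors(2000, m, seed = 1)

cfg <- parse_config()            # process III: dynamic list + sdm1
res <- run_simulation(cfg, candidates, donors)
national_state_ratio(res$records)

cfg_corisk <- parse_config(overrides = list(
  eligibility = list(mode = "corisk", c = 40)))
res_corisk <- run_simulation(cfg_corisk, candidates, donors)
acca_compare(res$records, res_corisk$records)
```

## Known limitations

Multi-organ offers, re-offers of declined kidneys beyond the ABO rounds,
competing-risks modelling of death versus other exits, and
registry-faithful scoring tables are out of scope. The surrogate score's
national share depends on the HLA pool richness of the synthetic cohort
and should not be read as an estimate of any real system's
national:state split.
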