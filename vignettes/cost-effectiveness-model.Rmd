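---
title: "A Markov cohort cost-effectiveness model for third-line HER2+ metastatic breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-effectiveness model for third-line HER2+ metastatic breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcmarkov)
```

## The decision problem

For HER2-positive metastatic breast cancer that has progressed on two prior
HER2-targeted lines, two oral third-line regimens compete: neratinib plus
capecitabine (N+C) and lapatinib plus capecitabine (L+C). `mbcmarkov`
implements a payer-perspective cost-utility comparison of the two over a
five-year horizon, as a cohort-level Markov model with four health states:

* **SD** — stable disease, the chemotherapeutic period (on treatment);
* **RE** — remission (response, off intensive treatment);
* **PD** — progressive/relapsed disease;
* **DE** — death, absorbing.

The cycle length is 21 days, matching the chemotherapy cycle; the horizon
holds `floor(5 × 365.25 / 21) = 86` cycles (≈ 4.95 years), chosen so the
stated horizon is never exceeded. Costs and QALYs are discounted at 3% per
year and compared at a willingness-to-pay (WTP) threshold of $36,000/QALY —
three times the 2022 Chinese per-capita GDP of $12,000 — with the
GDP-tier decision rule of the Chinese pharmacoeconomic guidelines: an ICER
below one GDP is *cost-effective*,
between one and three GDPs *acceptable*, above three *not worthwhile*.

## From survival medians to transition probabilities

No patient-level data enter the model. Each arm is summarised by four
published medians — overall survival (OS), progression-free survival (PFS)
and duration of response (DoR), in months, plus the derived risk fraction
`rr = (OS − PFS)/OS` — and converted to per-cycle probabilities by the
DEALE device (declining exponential approximation of life expectancy): a
median `m` implies a constant hazard `ln 2 / m`, hence a per-cycle
probability `1 − exp(−0.75 · ln 2 / m)`. Three structural constants are
kept named and overridable rather than inlined:

| constant | value | role |
|---|---|---|
| `CYCLE_MONTH_FACTOR` | 0.75 | scales the monthly hazard to the 21-day cycle |
| `RR_SCALE` | 3 | divisor in the response conversion `1 − exp(−rr/3)` |
| `STABLE_RELAPSE_MULTIPLIER` | 4 | relapse hazard from SD as a multiple of that from RE |

The 0.75 factor is consistent with reading the 21-day cycle as three
quarters of a 28-day month; the 4× stable-relapse rule and the `rr/3`
scaling are taken as given by the source derivation — reproducing the
published numbers takes precedence over re-deriving the constants. The
transition matrix is structural: self-transitions are complements
(`p_ss = 1 − p_sr − p_sp`, `p_rr = 1 − p_rp`, `p_pp = 1 − p_pd`), recovery
from PD is impossible, death is reachable only from PD, and rows are
validated to sum to one.

```{r}
sc <- paper_fixture("whole_group")
build_matrix(sc$strategies$nc$clinical, rounding_mode = "paper_3dp")
```

### Reproducing published tables: rounding modes

`rounding_mode = "paper_3dp"` rounds each *derived* probability to three
decimals before complements and multiples are formed, which is how the
published table was evidently produced. One quirk is documented rather than
hidden: the comparator's remission-to-relapse probability computes to
0.0889 but is printed as 0.088, i.e. truncated, and the truncation cascades
into its ×4 multiple and both complements. `build_matrix()` therefore
exposes `three_dp = "round"` (half away from zero; matches the intervention
column) and `"truncate"` (matches the comparator column). All fourteen
printed entries are reproduced between the two modes; the default analysis
runs in `"full_precision"`, which never rounds. Relatedly, the whole-group
fixture stores the *printed* risk fractions (0.63, 0.7): the unrounded
(24 − 8.8)/24 = 0.6333 would round the stable-to-remission entry to 0.190,
not the printed 0.189. Where no risk fraction is printed (the Asian
subgroup, synthetic scenarios) it is derived from the medians.

## Cohort simulation and accrual

The engine pushes the occupancy vector through the matrix for 86 cycles and
accrues, per cycle, discounted utility-weighted person-time and per-state
costs. Half-cycle correction is the standard trapezoidal (Sonnenberg–Beck)
weighting — half weight on the entry and terminal states — and can be
switched to pure start- or end-of-cycle counting; the corrected total
always lies between those two conventions. The discount factor at cycle
`t` is `1.03^(−t·21/365.25)`.

**Cost accrual** is the model's largest judgement call, because the source
states which costs belong to which states but not their periodicity:

* Drug acquisition cost (dosing schedules priced per whole dispensed unit,
  `ceiling(dose/unit)`, per-m² doses scaled by a 1.67 m² body surface
  area) accrues in **SD only**. SD is the chemotherapeutic period — the
  published utility table labels its 0.74 weight "no recurrence
  (chemotherapeutic period)" — whereas RE represents response off
  intensive treatment. This is deliberately narrower than charging drug
  cost in SD and RE: charging it in RE as well would make the
  longer-responding intervention arm ~$8k costlier and invert the NMB
  ranking, contradicting the qualitative published result under every
  other documented assumption. The accruing states are config-exposed
  (`drug_states` in the cost schedule).
* Health examinations ($4,552) accrue in SD and RE; hospitalization plus
  concomitant medications ($3,200 + $2,176) accrue in PD. Both are read
  as per-year amounts converted by `21/365.25` per cycle (also
  config-exposed via `other_cost_period`).
* Expected adverse-event management cost (incidence × per-event cost over
  the five grade-3/4 events) and the loperamide prophylaxis course are
  one-time costs at model entry, undiscounted: severe toxicity
  concentrates in the first month of treatment. The default prophylaxis
  schedule (4 mg load, 2 mg q4h for three days, then q6h to day 21)
  counts 92 tablets = $21.16; a q8h maintenance reading (74 tablets,
  $17.02) is available by changing `maintenance_interval_h`.
* Death accrues neither cost nor utility. Utilities: SD 0.74, RE 0.85,
  PD 0.50. Two published utilities with no corresponding state (0.94
  post-chemotherapy, 0.74 first-year local recurrence) are carried in
  `extras` but unused — the four-state structure has nowhere to apply
  them.

**Initial distribution.** The source says only that patients entered "in
various health states"; the split is never printed. The default starts
100% in SD and is configurable (`initial_distribution`). This single
unprinted input is the main reason the published five-year totals
(2.24/2.07 QALYs, $31,803/$33,665) cannot be recomputed from the printed
inputs; the package's base case under the documented defaults gives fewer
QALYs and lower costs for both arms but the same ordering: the
intervention gains ≈ 0.15 QALYs at an ICER of ≈ $14,600/QALY, well below
the threshold. Two further published numbers are internally inconsistent
and are therefore *not* targets: the whole-group ICER (−13,294.86 does not
equal the printed increments −1,861.28/0.17 = −10,948.71) and the NMB
column (39,788.07 ≠ 36,000 × 2.24 − 31,803.33 = 48,836.67). The package
implements the standard definitions (`Δcost/ΔQALY`; `wtp × QALY − cost`)
and reports quadrant tags alongside any negative ratio, since a negative
ICER is ambiguous without its quadrant.

## Sensitivity analysis design

**One-way DSA.** Every parameter in `parameter_table()` — fourteen
per-arm transition probabilities with their published ranges, ten
adverse-event incidences (±10%), three utilities, twelve unit costs
(published ranges), and the discount rate (±10%) — is set to each bound
with all others at base, and the ICER swing is the tornado bar. Varying a
transition probability lets its same-row self-transition absorb the change;
varying a self-transition (a complement row such as the remission–remission
probability) is mapped back onto its constituents — `p_rp = 1 − value`, and
for the stable row a proportional rescaling of both exits — so rows stay
stochastic by construction. The initial-state probabilities named in the
published tornado have no printed base values or ranges and so cannot be
included. At every parameter's base value the base-case ICER is reproduced
exactly (a regression test), and the widest bar belongs to the intervention
arm's remission self-transition, matching the published ranking: its lower
bound (0.8469) flips the sign of the QALY increment, which is why it
dwarfs everything else.

**PSA.** Second-order Monte Carlo, 1,000 draws by default. Each sampled
parameter gets a method-of-moments distribution with mean equal to its
base value and standard deviation `(high − low)/(2 × 1.96)` — the range
read as a 95% interval: beta for probabilities, utilities and incidences,
gamma for costs; a zero-width range is a point mass. Only the derived
probabilities (`p_sr`, `p_sp`, `p_rp`, `p_pd` per arm) are sampled —
complements absorb, so a draw can only be invalid if the two sampled
stable-row exits exceed one (such draws are resampled and counted; more
than 1% aborts). The discount rate is varied in the DSA but held fixed in
the PSA, as is conventional for a methodological rather than stochastic
parameter. All randomness flows from one explicit seed; identical seeds
give bit-identical draws. The acceptability curve reports, at each WTP on
a 0–64,000 grid, the fraction of draws in which each strategy has the
strictly higher NMB, ties split evenly, so the two curves sum to one
pointwise. Because the base case here sits in the north-east quadrant
(costlier, more effective) rather than being cost-saving as printed, the
intervention's curve rises with WTP and crosses the comparator's near the
base-case ICER instead of lying above it everywhere; at the $36,000
threshold it is preferred in ≈ 98% of draws.

## The synthetic scenario generator

`generate_scenario()` exists so that every pipeline stage can be tested on
inputs it has never seen. It emulates the *statistical structure* of the
published tables — two arms sharing unit prices, per-event adverse-event
costs and utilities, each arm with its own medians, dosing and incidences,
beta/gamma tags assigned by kind, ±10%/±20% auto-ranges — with validity by
construction: PFS is drawn as a uniform fraction of OS (so OS > PFS
always), and DoR is floored at 2.7 months, which keeps
`4·p_rp + p_sr < 1` for every attainable risk fraction since
`p_sr < 1 − e^{−1/3} ≈ 0.284`. `generate_edge_cases()` adds the stress
corners: near-immortal and near-instant-death cohorts, the relapse
probability just under the 0.25 limit of the 4× rule, an all-zero-cost
scenario, and a full-utility/no-death/no-discount scenario whose QALY
total equals the modelled horizon in closed form.

What passing these tests shows — and does not show. They verify the
arithmetic: conservation of occupancy, absorption of death, closed-form
agreement of the engine with matrix-power series, monotonicity in
utilities and survival, reproducibility of the stochastic machinery. They
cannot validate the DEALE constant-hazard reading of a median, the 4×
stable-relapse assumption, or the accrual periodicity against real-world
data; those remain modelling assumptions inherited from the source
derivation.

## Numerical choices and problem sizes

* Row-stochasticity is enforced to 1e−12 at assembly and 1e−9 at engine
  entry; occupancy conservation is asserted to 1e−10 in tests.
* 3-decimal reproduction uses round-half-away-from-zero (`"round"`) or
  truncation toward zero (`"truncate"`), as discussed above.
* The engine-versus-oracle acceptance sweep uses 1,000 random stochastic
  matrices over 2–10 cycles (tolerance 1e−10); the invariant sweep runs
  1,000 generated scenarios at the full 86-cycle horizon; routine PSA
  tests use 40–200 draws and the analysis scripts 1,000 — sizes chosen to
  exercise the asymptotics the claims need while keeping the default
  suite brisk.
* Ties in the CEAC and zero increments in quadrant classification are
  reported as their own categories, never silently folded.

## Workflow layout

The repository is an analysis workflow over the package: the numbered
scripts under `analysis/` (base case, DSA, PSA, subgroup) are thin
narrative drivers that call the exported functions and write tables,
figures and a run manifest (timestamp, package version, config MD5, seed)
under `results/`; every computation they perform is package code with unit
tests. The shipped YAML configs under `inst/extdata/` are byte-identical
to `save_config(paper_fixture(...))` output and round-trip through
`load_config()` exactly.

## Known limitations

* Cohort-level only: no microsimulation, tunnel states, or background
  all-cause mortality; transition probabilities are time-constant by the
  DEALE assumption.
* The unprinted initial state distribution and cost-accrual periodicity
  mean published absolute totals are not recoverable; comparisons with the
  publication are directional (QALY ordering, NMB ranking, tornado rank)
  plus the exactly recomputable quantities (transition probabilities,
  subgroup ICER arithmetic, adverse-event cost bookkeeping).
* Prices are the printed 2022 USD values; no inflation or currency
  machinery.
* Parameters are sampled independently in the PSA; no correlation
  structure, and no value-of-information analysis.
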