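---
title: "The vitamin D / pediatric ARI cost-utility model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vitamin D / pediatric ARI cost-utility model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdcea)
```

## The decision problem

Should healthy school-age children (roughly 1–16 years) receive daily
vitamin D3 (400 IU) to prevent acute respiratory infections (ARI)? The
package answers this as a cost-utility comparison of two strategies —
supplementation versus none — over a six-month horizon from a societal
perspective, with costs in 2020 US dollars and effectiveness in
quality-adjusted life-years (QALYs). Cost-effectiveness is judged at a
willingness-to-pay of $19,000 per QALY (one GDP per capita for the setting
the cost inputs come from, following the WHO one-to-three-GDP convention).

## Model structure

The model is a single-period decision tree, not a Markov cohort: the
outcome of interest (at least one ARI within six months, and its cost and
utility consequences) resolves at a single time point, and at a six-month
horizon there are no cycles to model and no discounting to apply. Each
strategy's chance tree has four terminal health states:

* **ARI, death** — probability `p_ari * m_ari`, utility 0;
* **ARI, survival** — probability `p_ari * (1 - m_ari)`, utility `1 - du_ari`;
* **no ARI, death (all causes)** — probability `(1 - p_ari) * m_all`, utility 0;
* **no ARI, survival** — probability `(1 - p_ari) * (1 - m_all)`, utility 1.

The only structural difference between the arms is the ARI probability:
supplementation multiplies the baseline `p_ari` by the relative risk
`rr_vitd`. Expected cost and utility per strategy come from
probability-weighted roll-back (`rollback()`); an independent
path-enumeration oracle (`enumerate_paths()`) exists purely so the two can
be checked against each other, which the test suite does on a thousand
randomly shaped trees.

### Conventions where the published description is silent

Several payoff conventions are not fully pinned down by the published
description of this model, so the package fixes them explicitly:

* **Decedent costs.** Children who die after an ARI accrue the full episode
  cost (the episode precedes the death); all-cause deaths on the ARI-free
  branch accrue no disease cost.
* **Supplement cost on every terminal.** The supplementation cost
  `c_vitd_day * suppl_days` is paid in full on every terminal of the
  supplemented arm, deaths included — supplementation is purchased
  prospectively, before outcomes are known.
* **QALYs as unscaled utility weights.** Reported "QALYs" are expected
  utility weights (≈ 0.99 per person), *not* multiplied by the half-year
  horizon. This matches the magnitudes the original evaluation prints; a
  strict QALY over six months would be at most 0.5. Setting
  `scale_by_horizon = TRUE` multiplies by `horizon_days / 365` for users
  who want calendar-time QALYs.
* **Utility of ARI survivors.** The disutility `du_ari` is applied for the
  whole period (utility `1 - du_ari`), since only the decrement, not an
  episode duration on the utility side, is published.

### The costed episode duration

The published inputs price an ARI at $880 *per day* but report per-person
expected costs of roughly $1,900 without supplementation, which is
consistent with a costed episode of about ten days
(0.22 × 880 × 10 = $1,936). The per-day and per-person figures cannot be
reconciled exactly under any single episode duration, so `episode_days` is
exposed as a first-class input with default 10 rather than hard-coded, and
`dominance_threshold_episode_cost()` reports how the cost-saving conclusion
depends on it: the intervention saves money whenever the episode cost
exceeds `c_vitd_day * suppl_days / (p_ari * (1 - rr_vitd))`, about $228 at
base-case values against the ≈ $8,800 default episode cost — a wide margin.

## Parameters

All inputs live in a `vitd_parameters()` object; the defaults are the
published base case.

```{r}
tidy(vitd_parameters())
```

| input | meaning | default | uncertainty |
|---|---|---|---|
| `p_ari` | P(≥1 ARI in 6 months), unsupplemented | 0.22 | beta, SD 0.005 |
| `rr_vitd` | relative risk of ARI under vitamin D | 0.71 | lognormal, sdlog 0.11 |
| `m_ari` | case fatality of ARI | 0.0001 | beta, SD 0.000029 |
| `m_all` | all-cause death, ARI-free branch | 0.0008 | beta, SD 0.00022 |
| `du_ari` | utility decrement during ARI | 0.06 | beta, SD 0.015 |
| `c_ari_day` | ARI cost per day (USD) | 880 | gamma, SD 222 |
| `c_vitd_day` | vitamin D3 400 IU per day (USD) | 0.08 | gamma, SD 0.02 |

Settings: `episode_days = 10`, `suppl_days = 182` (supplementation for the
whole six-month horizon, consistent with the daily-dosing trials the
effectiveness estimate summarises), `horizon_days = 182`,
`wtp = 19000`, `scale_by_horizon = FALSE`.

### Distribution choices

The published inputs give each parameter a family and an SD, nothing more,
so the package parameterizes by the **method of moments**: beta shapes from
mean/SD via `nu = m(1-m)/s^2 - 1`, gamma shape/rate as `(m/s)^2` and
`m/s^2`. For the relative risk the published entry is lognormal with
"SD 0.11"; the package reads this as the **log-scale SD with median 0.71**,
because `exp(log 0.71 ± 1.96 × 0.11) ≈ (0.57, 0.88)` reproduces the lower
limit of the meta-analytic 95% interval (0.57–0.90) the point estimate
comes from, while a natural-scale SD of 0.11 would not. A beta distribution
was considered and rejected for the relative risk: its support cannot
represent RR > 1, which a risk ratio's uncertainty must admit.

## One-way sensitivity (tornado)

`one_way_tornado()` moves each parameter in turn to the ends of the
equal-tailed 95% interval of its own uncertainty distribution
(`interval_bounds()`), keeping all others at base values. The published
analysis does not state its one-way ranges; tying them to the same
distributions the probabilistic analysis samples keeps the two analyses
consistent and requires no extra inputs. The default output metric is the
incremental net monetary benefit at the analysis willingness-to-pay, which
captures both the cost and the QALY channel in one number; `delta_cost`
and `delta_qaly` isolate either channel. Bars are sorted by descending
swing with alphabetical tie-breaks, so the ordering is deterministic.

## Probabilistic sensitivity analysis

`run_psa()` performs a second-order Monte Carlo simulation: `n = 10000`
joint parameter draws by default, each evaluated through the tree for both
strategies with common random numbers (the same drawn values feed both
arms, so per-draw increments isolate parameter uncertainty). Numerical
choices:

* **Sampling streams.** Sampling is parameter-major: a master seed yields
  one sub-seed per parameter in a fixed canonical order, so adding a new
  parameter never perturbs the draws of existing ones, and identical
  `(configuration, n, seed)` is bitwise reproducible.
* **Infeasible joint draws.** A lognormal relative risk can exceed 1, and
  `p_ari * rr` can then exceed 1. Such draws are capped at probability 1
  and counted in the `n_capped` attribute; `resample_infeasible = TRUE`
  redraws them instead. At base-case spreads the event has essentially
  zero probability; the option matters for wider synthetic scenarios.
* **Ties.** A draw with incremental NMB exactly zero counts for the
  comparator, which is conservative toward the intervention. The
  all-increments-zero null scenario therefore gives the intervention an
  acceptability of exactly 0, not 0.5.
* **Cost-effectiveness plane.** Boundary points (one increment exactly
  zero) are assigned to the adjacent quadrant clockwise (positive-QALY
  axis → dominant quadrant, negative-cost axis → south-west, and so on;
  the origin joins the dominant quadrant). With continuous distributions
  these are measure-zero events; the rule only pins down hand-crafted and
  degenerate cases.
* **CEAC grid.** Default willingness-to-pay grid 0–60,000 by 500.

`ceac_curve()` reports, at each willingness-to-pay, the fraction of draws
in which each strategy has the higher NMB; `acceptability_frontier()`
reports the strategy with the higher *mean* NMB together with its CEAC
value; `quadrant_shares()` summarises the plane.

## Synthetic scenarios and what the tests show

`random_scenario()` draws whole parameter tables inside wide but valid
ranges (ARI probability 0.05–0.5, relative risk 0.4–1.2 so both dominant
and non-dominant regimes occur, episode costs from trivial to
catastrophic), with spreads drawn inside each family's feasibility region.
`random_tree()` draws arbitrary small chance trees (simplex-distributed
branch probabilities, depth ≤ 4) with known path enumerations. These
generators emulate the *statistical structure* of the model's inputs —
probabilities with beta uncertainty, costs with gamma uncertainty, a
lognormal risk ratio — not real cohorts: there is no patient-level
variation, no correlation between inputs (the sampler is deliberately
independent, matching the analysis design), and no time dynamics. Passing
tests therefore certify the arithmetic of the pipeline — roll-back,
increments, classification, sampling, curve construction — on inputs like
these, not the external validity of any particular parameter estimate.

Problem sizes used by the test suite: 1,000 random trees for the
roll-back/enumeration oracle, 1,000 random tables for the closed-form
increment identities, and 10,000-draw PSAs for moment-recovery and
reproducibility checks.

## Numerical tolerances

Increments of the four-leaf tree admit closed forms (see README); the
engine matches them to machine precision. In absolute terms that is about
`1e-12` for the QALY increment (a quantity of magnitude ≤ 1) and
`1e-12` *relative to the cost scale* for the cost increment — with episode
costs in the thousands of dollars, double precision cannot deliver
`1e-12` absolute on ΔC, and the tests scale the tolerance by
`episode_cost + supplement_cost` accordingly. Roll-back versus path
enumeration agrees to `1e-9` relative on random trees. Chance-node
probability sums are validated to `1e-12`.

## Known limitations

* Two strategies only; no efficiency frontier over many comparators, and
  no EVPI/EVPPI.
* The effectiveness input is a trial-synthesis relative risk taken as
  given; the package does not model baseline vitamin D status, dosing
  regimens, or adherence.
* Costs are setting-specific (2020 USD, converted from a single middle-
  income health system); transferring the model to another setting means
  replacing the cost inputs, not just the willingness-to-pay.
* The per-person expected costs printed in the original evaluation cannot
  all be reproduced simultaneously from its per-day inputs (see the
  episode-duration section); this package reports the internally consistent
  tree results and exposes the episode duration so users can probe that
  gap themselves.
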