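---
title: "itpcea: model structure, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{itpcea: model structure, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science: what the
model assumes, which parameters matter and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and
where the genuinely open design choices were resolved.

## 1. The decision problem and model structure

Adult patients with chronic immune thrombocytopenia (platelets
< 100 × 10⁹/L) who fail first-line therapy receive one of three oral
thrombopoietin receptor agonists — hetrombopag, eltrombopag, or
avatrombopag. The model compares the three strategies over a lifetime
from the healthcare-system perspective in 2024 CNY.

The structure is a hybrid:

1. **Decision tree, one cycle long.** Time to response is standardized
   to one 4-week cycle for every therapy, so during cycle 1 the whole
   cohort is on the initial TPO-RA and accrues Response-state costs and
   utilities. At the cycle-1 boundary, background mortality is applied
   first and the survivors split by the strategy's initial response
   probability. Non-responders move to *Subsequent treatment* — the
   model's downstream pathway is standardized to rituximab + rhTPO for
   every strategy, which isolates the economic value of the initial
   TPO-RA choice.
2. **Markov cohort, 4-week cycles, horizon to age 100.** Four mutually
   exclusive states: *Response*, *Subsequent treatment*, *BSC*, and
   *Death* (absorbing). Responders face a cyclical risk of losing
   response and then enter subsequent treatment; subsequent treatment
   has its own one-cycle decision node (response rate 79.2%) and its
   own loss-of-response risk; failures accumulate in BSC. Internally
   the engine tracks *Subsequent* as two sub-states (response pending
   vs. responding) so that the one-cycle decision node is exact; the
   exported trace collapses them to the four canonical states.

Within every cycle the competing risks are ordered death-first: the
cycle's mortality is applied to each alive state, and clinical
transitions act on the survivors. This is the common cohort-model
convention and guarantees valid probability rows. Transitions between
the alive states carry no extra mortality: excess bleeding deaths are
deliberately subsumed in the BSC standardized mortality ratio rather
than modelled per event.

Rewards use a half-cycle correction: each cycle's state rewards are
applied to the arithmetic mean of the start-of-cycle and end-of-cycle
occupancy (trapezoidal integration of the occupancy curve). The
one-off terminal-care cost attaches to incident deaths in their cycle
of death and is not averaged. Discounting is per-cycle compound:
cycle *t* rewards are multiplied by `(1.05)^(-t × 28/365.25)`. Whether
the discount steps annually or compounds per cycle was an open choice;
per-cycle compounding is smoother and is what the trapezoidal reward
integral pairs with naturally (the difference is below 0.4% of any
total).

## 2. Parameters

All inputs live in a YAML configuration; `default_config()` ships the
`itp_china_2024` set. Each uncertain parameter carries
`{base, low, high, dist}`.

| Group | Key parameters (units) | Base values |
|---|---|---|
| Efficacy | initial response rate of eltrombopag; OR elt vs het; OR elt vs ava; mean durations of response (cycles) | 0.577; 0.74; 0.56; 42.66 / 46.72 |
| Mortality | SMR in BSC (ratio); age-indexed life table | 4.2; synthetic |
| Bleeding | per-cycle minor (on treatment / BSC) and severe (BSC) probabilities | 0.0108; 0.0381; 0.0015 |
| Costs (CNY/cycle or /event) | drugs, administration, management, bleed events, terminal care | e.g. hetrombopag 6,527.92/cycle; rituximab + rhTPO 18,146.21/cycle; terminal 37,442 |
| Utilities (QALY-weight/yr) | state × bleeding mixtures | 0.863 response no-bleed … 0.038 intracranial |
| Settings | discount 5%/yr; 28-day cycle; WTP 287,391 CNY/QALY; start age 45; horizon age 100 | — |

Notes on the less obvious ones:

* **Odds ratios are labelled reference-vs-comparator** (eltrombopag is
  the reference), so a comparator's odds are the eltrombopag odds
  *divided* by the OR; an OR below 1 favours the comparator.
* **Start age 45.** No baseline age is fixed by the input tables; 45
  is typical of the adult chronic-ITP trial populations in China and
  is configurable.
* **Severe-bleed split (1/3, 1/3, 1/3)** across intracranial /
  gastrointestinal / other is an assumption (the split is not
  reported) and is configurable; it only modulates the small
  severe-bleed cost and utility terms in BSC.
* **`time_to_response` is structurally one cycle** and validated as
  such: the decision-tree geometry assumes it.

## 3. Survival extrapolation

Duration of response is modelled from (pseudo) individual patient data
by maximum likelihood under right censoring over four candidate
families — exponential, Weibull, log-normal, log-logistic — selected by
AIC or BIC (`select_best()`, ties broken by parsimony then a fixed
family order). The exponential family uses its closed-form estimator
(`rate = events / total exposure`); the others are fitted with
`flexsurv::flexsurvreg()`. Closed-form means are attached to each fit;
the log-logistic mean is flagged non-finite when its shape is ≤ 1.

The cohort engine consumes a *mean* duration, converted to a constant
per-cycle exit probability `p = 1 − exp(−1/D)`. This memoryless
approximation is deliberately the default because the shipped
configuration prints only mean durations; it makes the base case
reproducible from the configuration alone. The discrete geometric
sojourn `1/p` exceeds `D` by the half-cycle discretization gap
`1/2 + 1/(12D) + O(D⁻³)` cycles — about 0.502 cycles (≈ 0.5% of `D`)
at `D = 42.66` — which the half-cycle correction of rewards offsets at
the reward level. For research use, `run_markov(..., duration_fit =)`
accepts a fitted log-normal and replaces the constant hazard with the
fitted time-varying hazard, tracked by expanding time-in-state; this
mode applies to the initial response duration (subsequent treatment
stays memoryless) and costs O(T²) instead of O(T).

The network-meta-analysis ORs adjust the initial response probability
only. Whether relative efficacy should also stretch the duration of
response is ambiguous in the underlying evidence (a class effect for
the *shape* of the response-survival curve is assumed); the package
defaults to response-rate-only adjustment with a configuration switch
(`settings.apply_or_to_duration`) that divides the mean duration by
the OR as well.

## 4. Mortality and the synthetic life table

Background mortality comes from an age-indexed annual life table,
looked up at `floor(age)` as the cohort ages by `28/365.25` years per
cycle. Annual probabilities are converted through rates:
`q_cycle = 1 − exp(−(−log(1 − q_annual)) × SMR × 28/365.25)`; Response
and Subsequent use SMR 1, BSC uses SMR 4.2.

The real Chinese national life table is not redistributable here, so
the package generates a Gompertz–Makeham stand-in,
`q(x) = 1 − exp(−(a + c·e^{bx}))` with `a = 2×10⁻⁴`, `b = 0.1/yr`,
`c = 2.276×10⁻⁵`, tuned once so life expectancy at birth is ≈ 78
years (approximately the contemporary Chinese level). It reproduces
the *shape* of adult mortality well but is not a substitute for the
official table at extreme ages; `load_config()` accepts a user life
table as a two-column CSV (`age`, `q`) or inline mapping, and all
results that depend on absolute survival should be read with the
stand-in in mind.

## 5. Economics

For each strategy the engine returns discounted total cost, QALYs,
life-years, and a cost breakdown whose categories sum exactly to the
total. Incremental statistics:

* `inmb(ΔE, ΔC, WTP) = ΔE × WTP − ΔC` — the primary statistic;
  antisymmetric and consistent with net-monetary-benefit ranking by
  construction.
* `icer(ΔC, ΔE) = ΔC/ΔE`, with labels `dominant` / `dominated` /
  `cost-minimization` where a ratio is not interpretable.
* `rank_strategies()` orders by NMB with deterministic tie-breaks
  (lower cost, then name) — the same tie-break used when scoring PSA
  iterations, so CEAC probabilities always partition the iterations.

## 6. Sensitivity and scenario machinery

**DSA.** Every uncertain parameter is set to its printed lower and
upper value in turn (all else at base) and both strategies of a
comparison are rerun; tornado entries are sorted by bar width with
zero-crossing flags. Bounds that would breach a family's hard support
are clipped with a warning. The parameter set is deliberately the
superset of all table entries: the tornado ranking truncates naturally.

**PSA.** Distributions are built from the printed summaries by method
of moments, reading the lower/upper values as a 95% interval
(`SD = (high − low)/3.92`): beta for probabilities and utilities,
gamma for costs, log-normal for relative effect measures and
durations. The analytic mean equals the base-case value by
construction. Utilities with very wide printed ranges can make beta
moments infeasible (`var ≥ m(1−m)`); the builder then truncates the SD
to 95% of the feasibility limit with a warning (none of the shipped
parameters need this). Parameters are sampled independently — no
correlation structure is published — with one OR draw per comparator
applied consistently within an iteration. Draws violating a model
invariant (response probabilities at the boundary, durations ≤ 1
cycle) are redrawn and counted. 5,000 iterations is the configured
default; the test suite uses a 200-iteration smoke version, and the
package's own studies of estimator behaviour use 100 seeded replicates
per survival family at n = 300 — sizes chosen to make the checks sharp
but routine.

**Scenarios.** `wtp_1x_gdp` divides the threshold by 3;
`subsequent_plus30`/`subsequent_minus30` scale the subsequent-treatment
cost and efficacy parameters by 1.3/0.7 (a scaled response rate above
1 is clipped to 0.999 with a warning).

## 7. Synthetic pseudo-IPD

`gen_pseudo_ipd()` draws event times from a chosen family and censors
administratively at a fixed follow-up, emulating reconstructed
duration-of-response data from a long-term extension study (default
illustrations use a log-normal with mean 42.66 cycles, `sdlog` 0.8,
and 78-cycle (~6-year) follow-up). What it emulates: the right-skewed
shape, the censoring fraction, and the information content of such
data at realistic n. What it does not: digitization error from
published curves, dependent censoring, covariate structure, or
between-trial heterogeneity. Passing parameter-recovery and
family-selection tests on these data therefore demonstrates the
estimation machinery, not the fidelity of any specific published
curve.

## 8. Numerical choices and degenerate inputs

* Trace rows are renormalized never; conservation is verified to
  1×10⁻¹² in tests instead.
* `floor(age)` life-table lookup; the horizon is
  `ceiling((100 − start_age)/cycle_fraction)` cycles, with the cohort
  remaining at the horizon contributing its final half-cycle reward.
* Degenerate uncertainty (`low = high`) yields a point-mass
  distribution; the DSA then reports a zero-width bar rather than
  erroring.
* All-censored survival data, non-positive durations, probabilities at
  0/1 where odds are needed, and unknown strategies/scenarios raise
  informative errors naming the offending input.

## 9. Known limitations

* With the shipped input set, each patient passes through subsequent
  treatment at most once and best supportive care carries only
  management and bleeding costs. Lifetime discounted totals are
  therefore dominated by the two active-treatment phases, and the
  three strategies — which differ only in drug price and initial
  response probability — produce modest between-strategy differences:
  at the default threshold the eltrombopag-vs-hetrombopag contrast is
  small (|iNMB| < CNY 10,000) and sign-sensitive to drug prices and
  the OR, as the tornado shows. Conclusions about that pair should be
  drawn from the sensitivity analyses, not the point estimate.
* Absolute totals are sensitive to unmodelled downstream resource use
  (e.g. rescue therapy in BSC): the model assigns none beyond routine
  management, an assumption users can revisit only by editing the cost
  structure, not the configuration.
* Adherence is 100%; dietary-restriction disutilities of the oral
  agents are not quantified; splenectomy is outside the pathway.
* The life table is a tuned stand-in (Section 4), and utilities
  originate from a non-Chinese population — both are replaceable
  through the configuration.
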