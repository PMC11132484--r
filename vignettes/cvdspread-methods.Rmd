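---
title: "Methods: behavioural spread, risk scoring and calibration in cvdspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural spread, risk scoring and calibration in cvdspread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdspread)
```

cvdspread simulates a closed cohort of adult agents whose smoking, alcohol,
diet and physical-activity behaviours spread over a typed social network,
and whose annual probability of a fatal cardiovascular event depends on age,
sex and current behaviour levels. This vignette is the package's own account
of the model: its assumptions, the parameters that matter, the numerical
conventions chosen where several were defensible, and what the synthetic
fixture data can and cannot show.

## The population model

Households are generated sequentially until the target size is reached.
Each household starts from one agent drawn from the joint age/sex
distribution (ages 18–89; children and the over-89s are outside the model).
Marriage is a Bernoulli draw from the agent's age/sex cell; if married, the
spouse's sex is decided first by the same-sex marriage fraction and the
spouse's age then drawn from the conditional distribution restricted to
that sex and renormalised. The sampled adult household size is never allowed
to fall below the members already present, so a married "single-person"
household simply keeps the couple. All household members inherit the
initiator's IMD decile, and household members form a clique (the spousal
pair carries the marriage edge). Because generation stops only after the
household in which the target is crossed, the realised population exceeds
the target by at most the largest household size minus one.

Two consequences of this construction are worth knowing. First, only
household initiators and "extra adults" are drawn i.i.d. from the age/sex
distribution; spouses follow the spouse conditional, so the pooled marginal
deviates slightly (and systematically) from the input distribution. The
test suite therefore checks distribution recovery on the i.i.d.-sampled
agents (chi-square goodness of fit at α = 0.001) and bounds the pooled
deviation in total variation. Second, everyone in a household shares one
IMD, which is how area-based deprivation measures behave.

The friendship layer excludes a uniformly chosen 7% of agents (people
without close friends), then runs a Newman–Watts–Strogatz generator over
the rest: a ring lattice with `round(mean_degree / 2)` neighbours a side
plus shortcut edges added with probability 0.01 per lattice edge. NWS only
*adds* edges, so the realised mean degree stays at ≈ `mean_degree × (1 +
p)` ≈ 6.06 before hierarchy pruning, which is why a small shortcut
probability is the default. A Barabási–Albert alternative (`m =
round(mean_degree / 2)`, via igraph) is available for scale-free
friendship structure. Edges duplicating a marriage or household pair are
removed, never the reverse: the hierarchy marriage ≻ household ≻
friendship ≻ workplace always keeps the higher tie.

Employed agents (employment is Bernoulli per age/sex/IMD cell) are shuffled
and cut into workplace contact groups. Each group draws a workplace size
category (<10, <50, <250, 250+), then a group size
`round(N(category mean, sd))` with a floor of 2; the scenario switch
`contact_mean` forces a single mean (4 or 21) for every category. No
formula for the size sd presented itself, so the default is a quarter of
the mean, exposed as `contact_group_sd` in the settings. The last group
takes whatever agents remain, so at most one group per population falls
short of its sampled size — the shortfall is bounded by the largest group.

## Behaviour spread

Every agent carries one threshold θ ~ N(0.8, 0.05), truncated to (0, 1) by
resampling (a threshold outside that range is meaningless against
nonnegative influence sums). The threshold is scalar: the same resistance
applies to all twelve behaviour–level decisions. Per behaviour, the agent
sums incoming strengths from neighbours currently at each level; levels
whose sum *strictly* exceeds θ are candidates ("reaching" the threshold
exactly is measure-zero under the Gaussian, but strictness is fixed for
reproducibility). No candidate keeps the current level; one candidate is
adopted (re-adopting your own level is a no-op, the natural fixed point);
several candidates are resolved proportionally to their influence sums.
For smoking, level 0 is deleted from the candidate set *before* counting
candidates, so an unobtainable level never absorbs tie-break probability:
anyone who has ever smoked can at best become an ex-smoker.

The update is synchronous: all influence sums use the start-of-step
snapshot and all levels commit together. Internally the sums are sparse
matrix–vector products per relationship type, and the per-agent tie-break
uniforms are drawn in agent-id order for every agent whether needed or not
— that makes the committed state invariant to how the agent table happens
to be ordered, which the suite verifies directly against a loop-based
brute-force oracle on all small graphs.

Dead agents are masked out of every influence sum and never updated; this
is algebraically identical to deleting their edges.

## Risk scoring

The ten-year baseline risk has the survival form `1 − S0^exp(lp)` per sex,
with `lp = const + age1·x + age2·x²`, `x = (age − 60)/10`. The real core
coefficients of the published QRISK3 score (with its default BMI,
cholesterol-ratio and blood-pressure values folded into the linear
predictor) can be supplied through `baseline_risk.csv`; the fixture ships
synthetic coefficients of the same form, chosen so that risk rises
monotonically over 25–84 and is higher for men. The ten-year risk is
multiplied by one user-defined factor per behaviour — keyed by level,
half-open age band `[age_lo, age_hi)` and sex, with the bands defined
entirely by the CSV rows — and divided by 10 for the annual probability,
clamped to [0, 1]. Only the current level matters; the model carries no
duration memory.

The score is applied only at ages 25–84. Younger and older agents have
annual probability 0 and accrue no person-years, which matches reporting in
five-year bands from 25–29 to 80–84. Agents age one year per step with no
upper removal; an agent ageing past 84 simply stops accruing risk and
person-time. A living at-risk agent contributes one full person-year per
step — including the step of its event — binned, like the event itself, by
age at the start of the step. Annual discrete steps admit no sub-year
resolution, and full-year attribution keeps person-year totals at
`N × steps` scale; the convention is a single unambiguous choice applied
everywhere.

## Simulation and reporting

Each step: synchronous behaviour update → annual probabilities → Bernoulli
event tests → removal of events with all their edges → ageing. Reports give
incident cases, person-years and rate per 1,000 person-years per age group
and sex (rate = cases / person-years × 1000 exactly; a zero denominator
yields `NA`, not a number), totals per sex, and level-2 prevalence among
survivors. Replicates use seeds derived from one master seed, so an entire
multi-replicate experiment is reproducible while streams stay uncorrelated;
aggregation reports per-cell means and population standard deviations.
Values are kept at full precision and rounded only for display.

Workplace interventions mark a uniformly random fraction of contact groups
as adopting; inside those groups, workplace edges exert influence for the
targeted behaviours at levels 0 and 1 with half the friendship strength
(both fractions configurable). An adoption rate of zero is exactly the
baseline model, bit for bit.

## Calibration

The fitness of a candidate influence matrix is the mean, over five
simulations, of the summed absolute difference between simulated and
observed rates across all 24 (age-group × sex) cells. Searches accept a
proposal — a ±U(0, 0.05) perturbation of all 36 free entries, clamped to
[0, 1], or with escalating probability a fresh uniform draw — only on
strict improvement, which also makes the best-so-far trace monotone. The
restart probability grows by 0.02 per consecutive failure and caps at 0.5
(the escalation rule needs *some* schedule; both constants are arguments).
Rounds re-centre the sampling and restart range to the incumbent ± 0.1,
clamped to [0, 1], with round 1 sampling the full [0, 1] cube. The full
schedule (500 × 100 × 5) evaluates exactly 250,000 parameter sets; the
workplace row is never searched and stays 0. The population size used
inside fitness evaluations is configurable (package default 50,000 agents)
— calibration cost is dominated by it, and the fitted strengths are
rate-level quantities that stabilise well below full city scale.

On a separable 6-variable L1 surrogate, the search recovers the optimum to
within 0.05 per coordinate in 100% of seeded runs at 10 searches × 100
iterations × 2 rounds (measured over 30 runs); the suite asserts ≥ 90% at
that scale. Dropping the per-search iteration count much below the default
100 (for example to 20) degrades recovery drastically — with ±0.05 moves
accepted only on improvement, a search needs on the order of a hundred
proposals to drift to an interior optimum — so the per-search budget is the
one knob kept at its full default in reduced-scale experiments.

## What the fixture data does and does not show

`fixture_parameter_set()` is a first-class, tested generator of
schema-valid inputs: a smooth age pyramid with a seeded ripple, marriage
probability rising with age, spouses within a few years of their partner,
UK-like adult household sizes (1–5, mean ≈ 2.2), mildly IMD- and
age-dependent employment, behaviour prevalence varying by age and sex, and
synthetic risk coefficients and multipliers with the right qualitative
structure (level 0 protective, level 2 harmful, attenuating with age). The
influence strengths default to the published calibrated values and the
observed-rate table to the published cohort rates.

Runs on fixture data demonstrate the *mechanics*: hierarchy enforcement,
snapshot semantics, smoking irreversibility, conservation of agents,
linear scaling of incident counts in population size with constant rates,
and the expected qualitative epidemiology (rates rising steeply with age,
male above female in essentially every band). They do not reproduce
England's absolute incidence: that requires the real census/health-survey
CSVs and QRISK3 coefficients, which are read via `load_parameter_set()`
when available but are deliberately not transcribed into the package. With
the published influence strengths, fixture populations converge strongly
toward level-2 behaviours (the level-2 strengths are the largest in almost
every relationship–behaviour row), so fixture incidence sits above the
published totals — a property of the strengths interacting with synthetic
prevalence, not a defect of the engine.

## Problem sizes and numerical conventions

The test suite and the acceptance script size experiments to a single CPU:
structural statistics on 10,000-agent generations, engine properties at
500–30,000 agents, scalability on 10K/20K/40K with two replicates per
size, and calibration experiments on surrogates plus small simulator runs
(hundreds to a few thousand agents). These are the package's chosen desk
scales; the engine itself has been run at hundreds of thousands of agents
(a 40K-agent, 10-step simulation takes a few seconds).

Probability tables must sum to 1 within 1e-9 per conditioning cell;
parameter round-trips through CSV are exact to better than 1e-12 (readr
writes shortest round-trip doubles). Degenerate inputs fail loudly:
empty distribution support, non-positive contact means, missing multiplier
cells or baseline terms are configuration errors naming the offending
cell, while `validate_parameter_set()` returns all violations as data.
Unordered pairs are keyed as `lo·2²⁶ + hi`, exact in doubles for the
population sizes the package targets (< 6.7 × 10⁷ agents).

## Limitations

The cohort is closed: no births, ageing-in, migration, or new
relationships; networks change only by removal on death. All CVD events
are fatal and affect only the agent concerned. Children, the over-89s at
generation, and behaviour-duration effects are out of scope, as are
company structures beyond close-contact groups. Behaviour prevalence
conditions on age and sex only — IMD affects behaviour exposure indirectly
through employment and workplace membership, mirroring the available
input data rather than asserting independence.
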