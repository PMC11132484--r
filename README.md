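# cvdspread

An agent-based simulator of how the four major behavioural risk factors for
cardiovascular disease — smoking, harmful alcohol use, poor diet and physical
inactivity — spread through a city-scale population's social networks, and of
the CVD incidence that results. It is aimed at public-health modellers who
want to explore behaviour-targeted interventions (for example workplace diet
or activity programmes) before committing to them, using only CSV-configured
demographic and risk inputs.

## The model

A synthetic adult population (ages 18–89) is generated household by
household from user-supplied distributions: a joint age/sex distribution,
marriage probabilities with a spouse age/sex conditional, adult household
sizes, IMD (Index of Multiple Deprivation) deciles and employment
probabilities. Agents are connected by four relationship types forming a
strict hierarchy

```
marriage ≻ household ≻ friendship ≻ workplace
```

with at most one edge per pair (a pair qualifying for several keeps the
highest). Friendships come from a Newman–Watts–Strogatz small-world
generator (mean degree 6, 7% of agents excluded as having no close friends)
or optionally Barabási–Albert; employed agents are partitioned into
workplace contact groups whose sizes are drawn from a normal distribution
around the workplace-category mean.

Each behaviour has three adoption levels (0 healthiest … 2 riskiest).
Spread follows a multi-level linear-threshold model: agent *v* has a
threshold θ_v ~ N(0.8, 0.05) truncated to (0,1), and per behaviour *b* and
level ℓ receives

```
I_v(b, ℓ) = Σ_{u ∈ N(v), level_u(b) = ℓ}  w(rel(u,v), b, ℓ)
```

Levels with I_v > θ_v are candidates; none → keep the current level, one →
adopt it, several → adopt with probability proportional to I_v. Smoking
level 0 ("never smoked") is permanently unavailable to anyone who has ever
smoked. All agents update synchronously from the start-of-step snapshot.

Annually, each agent's ten-year CVD risk is computed from a simplified
QRISK3-style survival form, `risk10 = 1 − S0^exp(lp)` with per-sex age-term
coefficients, multiplied by four user-defined behaviour-level risk factors
(by age band and sex), divided by 10, and Bernoulli-tested. Events are
fatal: the agent and all its edges are removed. Reports give incident
cases, person-years and rate per 1,000 person-years by five-year age group
(25–84) and sex, plus level-2 prevalence among survivors.

The 36 free influence strengths (workplace is 0 at baseline) can be
calibrated against observed incidence rates by random-restart hill
climbing: perturbations of ±U(0, 0.05), acceptance only on strict fitness
improvement, an escalating restart probability, and refinement rounds that
re-centre the sampling range (±0.1) on the incumbent — 500 searches × 100
iterations × 5 rounds = 250,000 parameter sets at the default schedule.

## Worked example

```r
library(cvdspread)

params  <- fixture_parameter_set(seed = 1)          # synthetic England-like inputs
pop     <- generate_population(20000, params, seed = 42)
pop
#> <cvd_population> 20002 agents (20002 alive), 155571 edges
#>   friendship   56219
#>   household    13072
#>   marriage      4628
#>   workplace    81652

metrics <- run_simulation(params, simulation_config(20000, steps = 10, seed = 42))
glance(metrics)
#>   n_agents steps incident_cases survivors rate_female rate_male
#> 1    20002    10           3494     16508        17.3      24.2

tidy(metrics)
#>   age_group sex    incident_cases person_years  rate
#> 1 25-29     female              4         4857 0.824
#> 2 30-34     female             11         6315 1.74
#> 3 35-39     female             19         7563 2.51
#> ...
```

`generate_population()` overshoots the 20,000 target by at most one
household (here 2 agents). Ten simulated years produce 3,494 fatal CVD
events; the rates per 1,000 person-years rise steeply with age and are
higher for men than for women in every age group, the expected
epidemiological pattern. (The absolute level reflects the synthetic fixture
demographics, which deliberately stand in for real census/health-survey
CSVs; supply a real parameter directory via `load_parameter_set()` to model
an actual population.) `autoplot(metrics)` draws the age–sex rate curves,
and

```r
spec <- intervention_spec(c("diet", "inactivity"), adoption_rate = 1)
run_simulation(params, simulation_config(20000, steps = 10, seed = 42,
                                         contact_mean = 21, intervention = spec))
```

re-runs the scenario with every workplace group promoting healthy diet and
activity at half the friendship influence strength.

A command-line interface wrapping the same functions is installed at
`system.file("cli/cvdsim", package = "cvdspread")` with subcommands
`fixture`, `simulate`, `intervene` and `calibrate`.

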