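test_that("rate arithmetic matches hand division and flags empty denominators", {
  expect_equal(compute_rate(57, 12000), 4.75)
  expect_equal(compute_rate(0, 500), 0)
  expect_true(is.na(compute_rate(3, 0)))
})

test_that("null model: no baseline hazard means no events, full person-time", {
  params <- fixture_parameter_set(1, overrides = list(
    baseline_risk = data.frame(
      sex = rep(c("female", "male"), each = 4),
      term = rep(c("s0", "const", "age1", "age2"), 2),
      coefficient = c(1, 0, 0, 0, 1, 0, 0, 0) # S0 = 1 -> risk 0
    ),
    influence = dplyr::mutate(as.data.frame(fx_params()$influence), strength = 0)
  ))
  pop <- generate_population(1200, params, seed = 14)
  steps <- 6
  m <- run_simulation(params, simulation_config(1200, steps = steps, seed = 2),
    population = pop
  )
  expect_identical(m$total_cases, 0)
  expect_identical(m$survivors, nrow(pop$agents))

  # person-years oracle: walk ages forward and count agents in 25-84
  ages <- dplyr::arrange(pop$agents, id)$age
  expected_py <- 0
  for (s in seq_len(steps)) {
    expected_py <- expected_py + sum(ages >= 25 & ages <= 84)
    ages <- ages + 1L
  }
  expect_equal(sum(m$rates$person_years), expected_py)
})

test_that("agents are conserved: initial N = survivors + incident cases", {
  params <- fx_params()
  for (seed in c(3, 4)) {
    m <- run_simulation(params, simulation_config(2000, steps = 8, seed = seed))
    expect_equal(m$n_agents, m$survivors + m$total_cases)
    expect_equal(sum(m$rates$incident_cases), m$total_cases)
    expect_true(all(m$rates$person_years <= m$n_agents * 8))
  }
})

test_that("reports are bit-identical under a fixed seed", {
  params <- fx_params()
  cfg <- simulation_config(1500, steps = 5, seed = 99)
  m1 <- run_simulation(params, cfg)
  m2 <- run_simulation(params, cfg)
  expect_identical(tidy(m1), tidy(m2))
  expect_identical(m1$prevalence, m2$prevalence)
})

test_that("fixture simulation shows rates rising with age and higher for men", {
  params <- fx_params()
  m <- run_simulation(params, simulation_config(30000, steps = 10, seed = 5))
  rates <- m$rates
  for (sx in c("female", "male")) {
    r <- rates$rate[rates$sex == sx]
    # allow small-sample wobble in neighbouring bands but demand a clear
    # monotone trend: each band above the one two below it
    expect_true(all(r[-(1:2)] > r[seq_len(length(r) - 2)]))
  }
  wide <- tidyr::pivot_wider(rates[c("age_group", "sex", "rate")],
    names_from = "sex", values_from = "rate"
  )
  expect_true(mean(wide$male > wide$female) >= 10 / 12)
  tot <- m$totals
  expect_gt(tot$rate[tot$sex == "male"], tot$rate[tot$sex == "female"])
})

test_that("ten-step cumulative incidence matches the closed form without spread", {
  # constant hazard: S0 chosen so ten-year risk r = 0.1 at every age in
  # window, multipliers 1, no influence; cumulative fraction after k years
  # should be 1 - (1 - r/10)^k
  r <- 0.1
  params <- fixture_parameter_set(1, overrides = list(
    baseline_risk = data.frame(
      sex = rep(c("female", "male"), each = 4),
      term = rep(c("s0", "const", "age1", "age2"), 2),
      coefficient = c(1 - r, 0, 0, 0, 1 - r, 0, 0, 0)
    ),
    multipliers = transform(fx_params()$multipliers, multiplier = 1),
    influence = dplyr::mutate(as.data.frame(fx_params()$influence), strength = 0),
    # keep everyone inside the risk window for the whole run
    age_sex = data.frame(
      age = rep(30:39, 2), sex = rep(c("female", "male"), each = 10),
      probability = 1 / 20
    ),
    marriage = data.frame(
      age = rep(30:39, 2), sex = rep(c("female", "male"), each = 10),
      probability = 0
    ),
    imd = data.frame(
      age = rep(30:39, 2), sex = rep(c("female", "male"), each = 10),
      decile = 5, probability = 1
    ),
    employment = data.frame(
      age = rep(30:39, 2), sex = rep(c("female", "male"), each = 10),
      decile = 5, probability = 0
    ),
    household_size = data.frame(size = 1, probability = 1)
  ))
  steps <- 10
  m <- run_simulation(params, simulation_config(20000, steps = steps, seed = 8))
  frac <- m$total_cases / m$n_agents
  closed <- 1 - (1 - r / 10)^steps
  expect_equal(frac, closed, tolerance = 0.05)
})

test_that("identical replicates aggregate with zero sd; hand means check out", {
  params <- fx_params()
  m <- run_simulation(params, simulation_config(1000, steps = 3, seed = 7))
  agg <- aggregate_runs(list(m, m, m))
  expect_true(all(agg$rates$rate_sd == 0, na.rm = TRUE))
  expect_equal(agg$rates$rate_mean, m$rates$rate)

  # two hand-made reports with total rates 8 and 10 -> mean 9, sd 1
  mk <- function(rate) {
    r <- m
    r$rates$rate <- rate
    r$totals$rate <- rate
    r
  }
  agg2 <- aggregate_runs(list(mk(8), mk(10)))
  expect_equal(unique(agg2$totals$rate_mean), 9)
  expect_equal(unique(agg2$totals$rate_sd), 1)
  expect_error(
    aggregate_runs(list(m, list(rates = m$rates[1:3, ]))),
    "strata"
  )
})

test_that("replicate seeds derive deterministically from the master seed", {
  params <- fx_params()
  cfg <- simulation_config(800, steps = 2, seed = 123, replicates = 3)
  a <- run_replicates(params, cfg)
  b <- run_replicates(params, cfg)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$replicates, 3L)
  # genuine replicate variation
  expect_true(any(a$rates$incident_cases_sd > 0))
})

test_that("level-2 prevalence counts only living agents", {
  pop <- toy_population(
    tibble::tibble(
      id = 1:10,
      smoking = c(rep(2L, 3), rep(0L, 7)),
      alcohol = 0L, diet = 0L, inactivity = 0L
    ),
    tibble::tibble(from = integer(), to = integer(), relationship = character())
  )
  p <- level2_prevalence(pop)
  expect_equal(p$prevalence[p$behaviour == "smoking"], 0.3)
  expect_equal(p$prevalence[p$behaviour == "diet"], 0)

  pop$agents$alive[1] <- FALSE # remove one level-2 smoker
  p2 <- level2_prevalence(pop)
  expect_equal(p2$prevalence[p2$behaviour == "smoking"], 2 / 9)

  pop$agents$alive <- FALSE
  expect_true(all(is.na(level2_prevalence(pop)$prevalence)))
})

test_that("a workplace intervention scales the friendship strengths by half", {
  params <- fx_params()
  pop <- generate_population(3000, params, seed = 31)
  spec <- intervention_spec("diet", adoption_rate = 0.5)
  set.seed(1)
  iv <- apply_workplace_intervention(params$influence, spec, pop)
  # friendship diet level 1 is 0.53 -> active workplace strength 0.265
  expect_equal(iv$active_strengths["diet", "1"], 0.5 * 0.53)
  expect_equal(iv$active_strengths["diet", "0"], 0.5 * 0.169)
  # untargeted cells stay at the baseline workplace strength (0)
  expect_equal(iv$active_strengths["diet", "2"], 0)
  expect_equal(iv$active_strengths["smoking", "1"], 0)
  # about half the groups adopt
  n_groups <- length(unique(na.omit(pop$agents$wp_group)))
  expect_equal(length(iv$adopting_groups), round(0.5 * n_groups))
})

test_that("zero adoption reproduces baseline dynamics exactly", {
  params <- fx_params()
  cfg0 <- simulation_config(2500, steps = 5, seed = 17)
  cfg_iv <- simulation_config(2500, steps = 5, seed = 17,
    intervention = intervention_spec(c("diet", "inactivity"), adoption_rate = 0)
  )
  m0 <- run_simulation(params, cfg0)
  m1 <- run_simulation(params, cfg_iv)
  expect_identical(tidy(m0), tidy(m1))
})

test_that("full adoption of both interventions lowers level-2 diet/inactivity", {
  params <- fx_params()
  prev <- function(intervention, seeds) {
    vals <- sapply(seeds, function(s) {
      cfg <- simulation_config(6000, steps = 10, seed = s,
        contact_mean = 21, intervention = intervention
      )
      m <- run_simulation(params, cfg)
      sum(m$prevalence$prevalence[m$prevalence$behaviour %in% c("diet", "inactivity")])
    })
    mean(vals)
  }
  base <- prev(NULL, 1:3)
  full <- prev(
    intervention_spec(c("diet", "inactivity"), adoption_rate = 1), 1:3
  )
  expect_lt(full, base)
})
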