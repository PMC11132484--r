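#' Simulation engine
#'
#' [run_simulation()] executes the annual loop: each step (i) sums incoming
#' influence from the start-of-step snapshot, (ii) resolves and commits all
#' behaviour levels simultaneously, (iii) computes each agent's annual event
#' probability from the baseline score and behaviour multipliers, (iv)
#' Bernoulli-tests every agent, (v) removes agents with events together with
#' all their connections and influence, and then ages everyone by one year.
#' Every living agent aged 25-84 at the start of a step contributes one
#' person-year to its current age group, including the year of its event;
#' incident cases are binned by age at the start of the step in which the
#' event occurs.
#'
#' @name simulation-engine
NULL

#' Simulation configuration
#'
#' @param target_population Minimum number of agents to generate.
#' @param steps Number of annual steps.
#' @param seed Integer seed for the run (population generation, spread and
#'   event draws).
#' @param replicates Number of replicate simulations for
#'   [run_replicates()].
#' @param contact_mean Optional fixed workplace contact-group mean
#'   (scenarios use 4 or 21); `NULL` keeps the per-category means.
#' @param intervention Optional [intervention_spec()].
#' @return A `cvd_config` list.
#' @export
simulation_config <- function(target_population = 350000, steps = 10,
                              seed = 1L, replicates = 100,
                              contact_mean = NULL, intervention = NULL) {
  stopifnot(target_population >= 1, steps >= 1, replicates >= 1)
  structure(
    list(
      target_population = as.integer(target_population),
      steps = as.integer(steps), seed = as.integer(seed),
      replicates = as.integer(replicates), contact_mean = contact_mean,
      intervention = intervention
    ),
    class = "cvd_config"
  )
}

#' Workplace intervention specification
#'
#' Describes a workplace intervention: in a fraction `adoption_rate` of
#' workplace contact groups, workplace edges start exerting influence for
#' the chosen behaviours at the chosen levels (default levels 0 and 1, the
#' healthier ones), with strength equal to `workplace_strength_fraction`
#' (default half) of the friendship strength for the same behaviour and
#' level. All other workplace influence stays at 0.
#'
#' @param behaviours Subset of `"diet"`, `"inactivity"`.
#' @param adoption_rate Fraction of workplace groups adopting (0, 0.25,
#'   0.5, 0.75 or 1 in the reported experiments; any value in `[0, 1]`).
#' @param workplace_strength_fraction Fraction of the friendship strength.
#' @param levels Behaviour levels the workplace influences.
#' @return A `cvd_intervention_spec`.
#' @export
intervention_spec <- function(behaviours, adoption_rate,
                              workplace_strength_fraction = 0.5,
                              levels = c(0L, 1L)) {
  behaviours <- match.arg(behaviours, c("diet", "inactivity"),
    several.ok = TRUE
  )
  stopifnot(
    adoption_rate >= 0, adoption_rate <= 1,
    workplace_strength_fraction >= 0, workplace_strength_fraction <= 1,
    all(levels %in% cvd_levels)
  )
  structure(
    list(
      behaviours = behaviours, adoption_rate = adoption_rate,
      workplace_strength_fraction = workplace_strength_fraction,
      levels = as.integer(levels)
    ),
    class = "cvd_intervention_spec"
  )
}

#' Mark adopting workplace groups and derive their influence strengths
#'
#' Samples a uniformly random fraction `adoption_rate` of the workplace
#' contact groups as adopting. Within adopting groups, workplace influence
#' for the targeted behaviours and levels equals
#' `workplace_strength_fraction` times the friendship strength for that
#' behaviour and level; everything else keeps the baseline workplace
#' strength (0 by default). Non-workplace strengths are untouched.
#'
#' @param influence An [influence_matrix()].
#' @param spec An [intervention_spec()].
#' @param population A [cvd_population] with workplace groups assigned.
#' @return A `cvd_intervention` with the adopting group ids and the active
#'   workplace strength matrix, consumed by [step_behaviours()] and
#'   [run_simulation()].
#' @export
apply_workplace_intervention <- function(influence, spec, population) {
  groups <- sort(unique(population$agents$wp_group))
  groups <- groups[!is.na(groups)]
  n_adopt <- round(spec$adoption_rate * length(groups))
  adopting <- if (n_adopt > 0) sort(sample(groups, n_adopt)) else integer(0)

  arr <- influence_array(influence)
  active <- arr[["workplace"]]
  friend <- arr[["friendship"]]
  for (b in spec$behaviours) {
    for (lv in spec$levels) {
      active[b, lv + 1] <- spec$workplace_strength_fraction * friend[b, lv + 1]
    }
  }
  structure(
    list(spec = spec, adopting_groups = adopting, active_strengths = active),
    class = "cvd_intervention"
  )
}

#' Incidence rate per 1,000 person-years
#'
#' @param cases Incident case count.
#' @param person_years Person-years at risk.
#' @return `cases / person_years * 1000`; `NA` when `person_years` is 0
#'   (undefined rate).
#' @examples
#' compute_rate(14584.9, 1547223.2) # 9.4 per 1,000 person-years
#' @export
compute_rate <- function(cases, person_years) {
  if_else(person_years > 0, cases / person_years * 1000, NA_real_)
}

#' Prevalence of level-2 behaviours among survivors
#'
#' @param population A [cvd_population].
#' @return Tibble with `behaviour` and `prevalence` (fraction of living
#'   agents at level 2); `NA` if no agent is alive.
#' @export
level2_prevalence <- function(population) {
  agents <- population$agents
  alive <- agents$alive
  n <- sum(alive)
  tibble(
    behaviour = cvd_behaviours,
    prevalence = unname(vapply(cvd_behaviours, function(b) {
      if (n == 0) NA_real_ else sum(agents[[b]][alive] == 2L) / n
    }, numeric(1)))
  )
}

#' Run one simulation
#'
#' Generates a population and runs the annual loop described in
#' [simulation-engine]. With a fixed `(seed, config, params)` the report is
#' bit-identical across calls.
#'
#' @param params A [cvd_parameters] object.
#' @param config A [simulation_config()].
#' @param population Optional pre-generated [cvd_population] (the seed then
#'   governs only spread/event draws and intervention adoption).
#' @return A `cvd_metrics` object: `$rates` (incident cases, person-years
#'   and rate per 1,000 person-years by five-year age group and sex),
#'   `$totals` (per sex), `$prevalence` (level-2 fraction per behaviour
#'   among survivors) and bookkeeping counts.
#' @examples
#' params <- fixture_parameter_set(1)
#' m <- run_simulation(params, simulation_config(2000, steps = 2, seed = 1))
#' tidy(m)
#' @export
run_simulation <- function(params, config, population = NULL) {
  set.seed(config$seed)
  if (is.null(population)) {
    population <- generate_population(
      config$target_population, params,
      contact_mean = config$contact_mean
    )
  }
  agents <- arrange(population$agents, .data$id)
  n0 <- nrow(agents)

  intervention <- NULL
  if (!is.null(config$intervention)) {
    intervention <- apply_workplace_intervention(
      params$influence, config$intervention,
      new_cvd_population(agents, population$edges)
    )
  }
  state <- build_spread_state(
    new_cvd_population(agents, population$edges),
    params$influence, intervention
  )
  bmodel <- baseline_model(params$baseline_risk)

  groups <- cvd_age_groups()
  cases <- py <- matrix(0,
    nrow = length(groups), ncol = 2,
    dimnames = list(groups, cvd_sexes)
  )
  sex_col <- match(agents$sex, cvd_sexes)

  for (step in seq_len(config$steps)) {
    # (1-3) synchronized behaviour update from the snapshot
    new_levels <- spread_step_core(state)
    for (b in cvd_behaviours) state$agents[[b]] <- new_levels[, b]
    state$agents$ever_smoked <- state$agents$ever_smoked |
      state$agents$smoking != 0L

    a <- state$agents
    at_risk <- a$alive & a$age >= cvd_risk_age_min & a$age <= cvd_risk_age_max

    # (4) annual event probability
    p <- numeric(n0)
    if (any(at_risk)) {
      r10 <- baseline_ten_year_risk(a$age[at_risk], a$sex[at_risk], bmodel)
      mult <- combined_multiplier(a[at_risk, ], params$multipliers)
      p[at_risk] <- annual_event_probability(r10, mult)
    }

    # person-years: one per at-risk living agent, event year included
    grp_idx <- match(cvd_age_group_of(a$age), groups)
    pyi <- which(at_risk)
    if (length(pyi) > 0) {
      tab <- table(factor(grp_idx[pyi], seq_along(groups)),
        factor(sex_col[pyi], 1:2)
      )
      py <- py + as.matrix(tab)
    }

    # (5-6) Bernoulli event test; events remove agent and its influence
    u <- runif(n0)
    events <- which(a$alive & u < p)
    if (length(events) > 0) {
      tab <- table(factor(grp_idx[events], seq_along(groups)),
        factor(sex_col[events], 1:2)
      )
      cases <- cases + as.matrix(tab)
      state$agents$alive[events] <- FALSE
    }
    state$agents$age <- state$agents$age + 1L
  }

  rates <- crossing(sex = cvd_sexes, age_group = groups) |>
    mutate(
      incident_cases = as.numeric(cases[cbind(.data$age_group, .data$sex)]),
      person_years = as.numeric(py[cbind(.data$age_group, .data$sex)]),
      rate = compute_rate(.data$incident_cases, .data$person_years)
    ) |>
    select("age_group", "sex", "incident_cases", "person_years", "rate") |>
    arrange(match(.data$sex, cvd_sexes), .data$age_group)

  totals <- rates |>
    group_by(.data$sex) |>
    summarise(
      incident_cases = sum(.data$incident_cases),
      person_years = sum(.data$person_years),
      .groups = "drop"
    ) |>
    mutate(rate = compute_rate(.data$incident_cases, .data$person_years))

  final_pop <- new_cvd_population(state$agents, population$edges)
  structure(
    list(
      rates = rates, totals = totals,
      prevalence = level2_prevalence(final_pop),
      n_agents = n0, steps = config$steps, seed = config$seed,
      survivors = sum(state$agents$alive),
      total_cases = sum(cases)
    ),
    class = "cvd_metrics"
  )
}

#' @export
print.cvd_metrics <- function(x, ...) {
  cat(sprintf(
    "<cvd_metrics> %d agents, %d steps, %d incident cases, %d survivors\n",
    x$n_agents, x$steps, x$total_cases, x$survivors
  ))
  tot <- x$totals |> mutate(rate = round(.data$rate, 1))
  print(tot)
  invisible(x)
}

#' Run replicate simulations and aggregate
#'
#' Runs `config$replicates` independent simulations (each with a fresh
#' population) using replicate seeds derived from `config$seed`, and
#' aggregates per-cell means and standard deviations with
#' [aggregate_runs()].
#'
#' @inheritParams run_simulation
#' @return A `cvd_metrics_summary`.
#' @export
run_replicates <- function(params, config) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
  reports <- map(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    run_simulation(params, cfg)
  })
  aggregate_runs(reports)
}

#' Aggregate replicate metric reports
#'
#' Per-cell arithmetic mean and population standard deviation (divisor `n`)
#' across replicate reports with identical strata.
#'
#' @param reports List of `cvd_metrics` objects.
#' @return A `cvd_metrics_summary` with `$rates`, `$totals` and
#'   `$prevalence` mean/sd tibbles.
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  ref <- reports[[1]]$rates[c("age_group", "sex")]
  for (r in reports) {
    if (!identical(r$rates[c("age_group", "sex")], ref)) {
      abort("Reports have mismatched strata; cannot aggregate.")
    }
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  agg <- function(getter, keys) {
    bind_rows(lapply(reports, getter)) |>
      group_by(across(all_of(keys))) |>
      summarise(
        across(dplyr::where(is.numeric),
          list(mean = mean, sd = pop_sd),
          .names = "{.col}_{.fn}"
        ),
        .groups = "drop"
      )
  }
  rates_agg <- agg(function(r) r$rates, c("age_group", "sex")) |>
    arrange(match(.data$sex, cvd_sexes), .data$age_group)
  structure(
    list(
      rates = rates_agg,
      totals = agg(function(r) r$totals, "sex"),
      prevalence = agg(function(r) r$prevalence, "behaviour"),
      replicates = length(reports),
      n_agents = mean(vapply(reports, `[[`, numeric(1), "n_agents"))
    ),
    class = "cvd_metrics_summary"
  )
}

#' @export
print.cvd_metrics_summary <- function(x, ...) {
  cat(sprintf(
    "<cvd_metrics_summary> %d replicates, mean population %.0f\n",
    x$replicates, x$n_agents
  ))
  print(x$totals |> mutate(across(dplyr::where(is.numeric), ~ round(.x, 1))))
  invisible(x)
}
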