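#' Influence-strength calibration
#'
#' The 36 free influence strengths (marriage, household and friendship, for
#' each behaviour and level; workplace is fixed at 0) are fitted so that the
#' simulated incidence rates match observed rates, by random-restart hill
#' climbing: many independent searches, each accepting a perturbed (or,
#' with an escalating probability after repeated failures, freshly random)
#' candidate only when the fitness strictly improves, followed by rounds
#' that re-centre the sampling range on the best parameter set found. At
#' the published defaults — 500 searches of 100 iterations over 5 rounds —
#' 250,000 parameter sets are evaluated.
#'
#' @name influence-calibration
NULL

#' Calibration fitness of an influence matrix
#'
#' Runs `n_sims` simulations under the given influence strengths and
#' returns the mean, over simulations, of the sum of absolute differences
#' between the simulated and observed incidence rates per 1,000
#' person-years across all (age group, sex) cells. 0 is a perfect match.
#'
#' @param influence An [influence_matrix()] (or a 36-vector of free
#'   strengths in the canonical order).
#' @param observed Observed rate table (`age_group`, `sex`, `rate`).
#' @param params A [cvd_parameters] object.
#' @param config A [simulation_config()]; its `target_population` is the
#'   (reduced) population size used inside calibration.
#' @param n_sims Simulations averaged per evaluation (default 5).
#' @param sim_fn Simulator, `function(params, config) -> cvd_metrics`;
#'   defaults to [run_simulation()]. Replaceable so the fitness can be
#'   exercised against a stub.
#' @return Nonnegative fitness value.
#' @export
calibration_fitness <- function(influence, observed, params, config,
                                n_sims = 5, sim_fn = run_simulation) {
  stopifnot(n_sims >= 1)
  if (is.numeric(influence)) influence <- free_vector_to_influence(influence)
  params$influence <- influence
  vals <- vapply(seq_len(n_sims), function(i) {
    cfg <- config
    cfg$seed <- sample.int(.Machine$integer.max - 1L, 1)
    m <- sim_fn(params, cfg)
    sim <- m$rates |>
      inner_join(observed, by = c("age_group", "sex"),
        suffix = c("_sim", "_obs")
      )
    sum(abs(replace_na(sim$rate_sim, 0) - sim$rate_obs))
  }, numeric(1))
  mean(vals)
}

#' Perturb a strength vector
#'
#' Moves every entry by an independent draw of `sign * Uniform(0, max_step)`
#' and clamps to `[0, 1]`; the default maximum step is 0.05.
#'
#' @param x Numeric vector of strengths in `[0, 1]`.
#' @param max_step Largest per-entry displacement.
#' @return The perturbed vector.
#' @export
perturb_strengths <- function(x, max_step = 0.05) {
  step <- sample(c(-1, 1), length(x), replace = TRUE) * runif(length(x), 0, max_step)
  pmin(pmax(x + step, 0), 1)
}

#' Hill climb from one starting point
#'
#' Iterates propose-accept over a fitness function to be minimised. Each
#' iteration either perturbs the current point ([perturb_strengths()]) or,
#' with a restart probability that grows by 0.02 per consecutive
#' non-improvement (capped at 0.5, reset on improvement), draws a fresh
#' uniform point from `lower`/`upper`. A proposal is accepted only if its
#' fitness strictly improves on the current point; the best point ever seen
#' is tracked separately and returned.
#'
#' @param fitness Function mapping a numeric vector to a scalar fitness.
#' @param init Numeric starting vector.
#' @param iterations Number of proposal evaluations (default 100).
#' @param lower,upper Bounds of the restart sampling range (scalars or
#'   vectors; also used to clamp perturbations implicitly via `[0, 1]`).
#' @param max_step Perturbation bound (default 0.05).
#' @param restart_increment Restart-probability growth per failure.
#' @return List with `best`, `best_fitness`, `evaluations` (number of
#'   proposals evaluated) and `trace` (per-iteration fitness of the best).
#' @export
hill_climb <- function(fitness, init, iterations = 100, lower = 0, upper = 1,
                       max_step = 0.05, restart_increment = 0.02) {
  stopifnot(iterations >= 1)
  iterations <- as.integer(iterations)
  d <- length(init)
  lower <- rep_len(lower, d)
  upper <- rep_len(upper, d)
  cur <- init
  f_cur <- fitness(cur)
  best <- cur
  f_best <- f_cur
  fails <- 0L
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    p_restart <- min(restart_increment * fails, 0.5)
    prop <- if (runif(1) < p_restart) {
      runif(d, lower, upper)
    } else {
      perturb_strengths(cur, max_step)
    }
    f_prop <- fitness(prop)
    if (f_prop < f_cur) {
      cur <- prop
      f_cur <- f_prop
      fails <- 0L
      if (f_prop < f_best) {
        best <- prop
        f_best <- f_prop
      }
    } else {
      fails <- fails + 1L
    }
    trace[it] <- f_best
  }
  list(best = best, best_fitness = f_best, evaluations = iterations, trace = trace)
}

#' Random-restart search with multi-round refinement
#'
#' Round 1 runs `searches` independent hill climbs from uniform starting
#' points in the global range `[0, 1]`. Each later round re-centres the
#' sampling (and restart) range on the best point so far, to plus/minus
#' `window` clamped to `[0, 1]`, and searches again. The total number of
#' parameter sets evaluated is `searches * iterations * rounds`.
#'
#' @inheritParams hill_climb
#' @param d Dimension of the search space (36 for the influence matrix).
#' @param searches Hill climbs per round.
#' @param rounds Refinement rounds.
#' @param window Half-width of the re-centred range.
#' @return List with `best`, `best_fitness`, `evaluations` and a per-round
#'   summary tibble `rounds`.
#' @export
random_restart_search <- function(fitness, d, searches = 500, iterations = 100,
                                  rounds = 5, window = 0.1, max_step = 0.05) {
  stopifnot(searches >= 1, iterations >= 1, rounds >= 1)
  best <- NULL
  f_best <- Inf
  evaluations <- 0L
  lower <- rep(0, d)
  upper <- rep(1, d)
  round_summary <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    if (r > 1) {
      lower <- pmax(best - window, 0)
      upper <- pmin(best + window, 1)
    }
    for (s in seq_len(searches)) {
      init <- runif(d, lower, upper)
      res <- hill_climb(fitness, init,
        iterations = iterations,
        lower = lower, upper = upper, max_step = max_step
      )
      evaluations <- evaluations + res$evaluations
      if (res$best_fitness < f_best) {
        best <- res$best
        f_best <- res$best_fitness
      }
    }
    round_summary[[r]] <- tibble(round = r, best_fitness = f_best)
  }
  list(
    best = best, best_fitness = f_best, evaluations = evaluations,
    rounds = bind_rows(round_summary)
  )
}

#' Calibrate influence strengths against observed rates
#'
#' Full calibration driver: wraps [calibration_fitness()] over the
#' simulator and runs [random_restart_search()] on the 36 free strengths
#' (workplace stays 0). Defaults mirror the published procedure (500
#' searches, 100 iterations, 5 rounds, refinement window 0.1, 5
#' simulations per evaluation); tests and examples use far smaller values.
#'
#' @inheritParams calibration_fitness
#' @param searches,iterations,rounds,window Search-scale parameters.
#' @param seed Integer seed for the whole calibration.
#' @return A `cvd_calibration` with the best [influence_matrix()], its
#'   fitness, and the evaluation count.
#' @export
calibrate_influence <- function(params, observed = params$observed_rates,
                                config = simulation_config(
                                  target_population = 50000, steps = 10
                                ),
                                n_sims = 5, searches = 500, iterations = 100,
                                rounds = 5, window = 0.1, seed = 1L) {
  if (nrow(observed) == 0) abort("No observed rates supplied for calibration.")
  set.seed(as.integer(seed))
  fitness <- function(v) {
    calibration_fitness(v, observed, params, config, n_sims = n_sims)
  }
  res <- random_restart_search(fitness,
    d = 36, searches = searches,
    iterations = iterations, rounds = rounds, window = window
  )
  v <- setNames(res$best, names(free_vector_template()))
  structure(
    list(
      influence = free_vector_to_influence(v),
      best_fitness = res$best_fitness,
      evaluations = res$evaluations,
      rounds = res$rounds,
      settings = list(
        searches = searches, iterations = iterations, rounds = rounds,
        window = window, n_sims = n_sims,
        population = config$target_population, steps = config$steps
      )
    ),
    class = "cvd_calibration"
  )
}

#' @export
print.cvd_calibration <- function(x, ...) {
  cat(sprintf(
    "<cvd_calibration> best fitness %.3f after %d evaluations\n",
    x$best_fitness, x$evaluations
  ))
  invisible(x)
}
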