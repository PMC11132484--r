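#' Tidiers for simulation results
#'
#' `tidy()` returns the per-stratum table of a result; `glance()` a one-row
#' summary. Both follow the broom conventions so results drop straight into
#' dplyr/ggplot2 pipelines.
#'
#' @param x A `cvd_metrics`, `cvd_metrics_summary` or `cvd_calibration`.
#' @param ... Unused.
#' @name cvd-tidiers
NULL

#' @rdname cvd-tidiers
#' @method tidy cvd_metrics
#' @export
tidy.cvd_metrics <- function(x, ...) {
  bind_rows(
    x$rates,
    x$totals |> mutate(age_group = "total", .before = 1)
  )
}

#' @rdname cvd-tidiers
#' @method glance cvd_metrics
#' @export
glance.cvd_metrics <- function(x, ...) {
  wide <- x$totals |>
    select("sex", "rate") |>
    pivot_wider(names_from = "sex", values_from = "rate", names_prefix = "rate_")
  tibble(
    n_agents = x$n_agents, steps = x$steps, incident_cases = x$total_cases,
    survivors = x$survivors
  ) |>
    dplyr::bind_cols(wide)
}

#' @rdname cvd-tidiers
#' @method tidy cvd_metrics_summary
#' @export
tidy.cvd_metrics_summary <- function(x, ...) {
  bind_rows(
    x$rates,
    x$totals |> mutate(age_group = "total", .before = 1)
  )
}

#' @rdname cvd-tidiers
#' @method glance cvd_metrics_summary
#' @export
glance.cvd_metrics_summary <- function(x, ...) {
  x$totals |>
    select("sex", "rate_mean", "rate_sd") |>
    pivot_wider(
      names_from = "sex",
      values_from = c("rate_mean", "rate_sd")
    ) |>
    mutate(replicates = x$replicates, n_agents = x$n_agents)
}

#' @rdname cvd-tidiers
#' @method tidy cvd_calibration
#' @export
tidy.cvd_calibration <- function(x, ...) {
  as_tibble(x$influence)
}

#' @rdname cvd-tidiers
#' @method glance cvd_calibration
#' @export
glance.cvd_calibration <- function(x, ...) {
  tibble(
    best_fitness = x$best_fitness, evaluations = x$evaluations,
    searches = x$settings$searches, iterations = x$settings$iterations,
    rounds = x$settings$rounds
  )
}

#' Plot incidence rates by age group and sex
#'
#' @param object A `cvd_metrics` or `cvd_metrics_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cvd_metrics
#' @export
autoplot.cvd_metrics <- function(object, ...) {
  ggplot(object$rates, aes(
    x = .data$age_group, y = .data$rate,
    colour = .data$sex, group = .data$sex
  )) +
    geom_line() +
    geom_point() +
    labs(
      x = "Age group (years)", y = "Rate per 1,000 person-years",
      colour = NULL
    ) +
    theme_minimal()
}

#' @rdname autoplot.cvd_metrics
#' @method autoplot cvd_metrics_summary
#' @export
autoplot.cvd_metrics_summary <- function(object, ...) {
  ggplot(object$rates, aes(
    x = .data$age_group, y = .data$rate_mean,
    colour = .data$sex, group = .data$sex
  )) +
    geom_line() +
    geom_point() +
    labs(
      x = "Age group (years)", y = "Mean rate per 1,000 person-years",
      colour = NULL
    ) +
    theme_minimal()
}

#' Plot level-2 behaviour prevalence among survivors
#'
#' @param metrics A `cvd_metrics`.
#' @return A ggplot.
#' @export
plot_prevalence <- function(metrics) {
  ggplot(metrics$prevalence, aes(x = .data$behaviour, y = .data$prevalence)) +
    geom_col() +
    labs(x = NULL, y = "Level-2 prevalence among survivors") +
    theme_minimal()
}
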