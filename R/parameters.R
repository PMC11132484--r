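#' Parameter sets
#'
#' A `cvd_parameters` object bundles every distribution and coefficient table
#' that configures one simulation: the joint age/sex distribution, marriage
#' and spouse-matching probabilities, adult household sizes, IMD deciles,
#' employment probabilities, workplace-size categories with contact-group
#' means, behaviour-level prevalence, behaviour risk multipliers, the
#' simplified ten-year baseline risk coefficients, the relationship influence
#' strengths and (optionally) observed incidence rates for calibration.
#' Everything is a tibble, so parameter sets can be inspected and edited with
#' ordinary dplyr verbs before being passed to [run_simulation()].
#'
#' Scalar settings (threshold mean/sd, friendship generator and mean degree,
#' exclusion fraction, same-sex marriage fraction, contact-group sd) live in
#' `$settings`.
#'
#' @name cvd_parameters
NULL

default_settings <- function() {
  list(
    same_sex_marriage_fraction = 0.025,
    threshold_mean = 0.8,
    threshold_sd = 0.05,
    friendship_generator = "NWS",
    friendship_mean_degree = 6,
    friendship_exclusion_fraction = 0.07,
    nws_shortcut_prob = 0.01,
    contact_group_sd = NA_real_, # default: mean / 4 per size category
    contact_group_min = 2
  )
}

new_cvd_parameters <- function(tables, settings) {
  structure(c(tables, list(settings = settings)), class = "cvd_parameters")
}

#' @export
print.cvd_parameters <- function(x, ...) {
  cat("<cvd_parameters>\n")
  for (nm in setdiff(names(x), "settings")) {
    cat(sprintf("  %-15s %d rows\n", nm, nrow(x[[nm]])))
  }
  cat("  settings:", paste(names(x$settings), unlist(lapply(x$settings, format)),
    sep = "=", collapse = ", "
  ), "\n")
  invisible(x)
}

# ---- fixture generation -----------------------------------------------------

# Calibrated influence strengths for marriage/household/friendship by
# behaviour level; workplace exerts no influence unless an intervention
# switches it on.
default_influence_values <- function() {
  wide <- tibble::tribble(
    ~relationship, ~behaviour, ~level0, ~level1, ~level2,
    "marriage", "smoking", 0.554, 0.691, 0.635,
    "marriage", "alcohol", 0.316, 0.525, 0.755,
    "marriage", "diet", 0.331, 0.659, 0.773,
    "marriage", "inactivity", 0.472, 0.959, 0.255,
    "household", "smoking", 0.193, 0.099, 0.497,
    "household", "alcohol", 0.252, 0.460, 0.785,
    "household", "diet", 0.266, 0.192, 0.522,
    "household", "inactivity", 0.037, 0.589, 0.373,
    "friendship", "smoking", 0.276, 0.104, 0.359,
    "friendship", "alcohol", 0.229, 0.371, 0.749,
    "friendship", "diet", 0.169, 0.530, 0.594,
    "friendship", "inactivity", 0.124, 0.487, 0.496,
    "workplace", "smoking", 0, 0, 0,
    "workplace", "alcohol", 0, 0, 0,
    "workplace", "diet", 0, 0, 0,
    "workplace", "inactivity", 0, 0, 0
  )
  influence_matrix(wide)
}

# Observed fatal-CVD incidence per 1,000 person-years by five-year age group
# and sex (QRISK3 derivation cohort), used as the calibration target.
default_observed_rates <- function() {
  tibble(
    age_group = rep(cvd_age_groups(), 2),
    sex = rep(c("female", "male"), each = 12),
    rate = c(
      0.24, 0.49, 1.02, 1.90, 3.20, 4.83, 7.47, 11.36, 17.13, 25.08, 35.11, 48.02,
      0.40, 0.99, 2.12, 3.99, 6.65, 9.86, 14.18, 19.69, 26.55, 35.48, 45.16, 58.29
    )
  )
}

#' Build a synthetic fixture parameter set
#'
#' Constructs a complete, schema-valid [cvd_parameters] object with plausible
#' synthetic demographic and risk distributions: a smooth adult age pyramid,
#' marriage probability rising with age, spouses matched within a few years of
#' their partner's age, UK-like adult household sizes, behaviour prevalence
#' varying with age and sex, and baseline risk coefficients of the
#' survival-model form `risk = 1 - S0^exp(lp)` chosen so that incidence rises
#' with age and is higher for men. The influence strengths default to the
#' calibrated values and the observed-rate table to the published
#' fatal-CVD cohort rates; every demographic table is synthetic and stands in
#' for the England census/health-survey data a production run would supply.
#'
#' @param seed Integer seed; the fixture is a pure function of
#'   `(seed, overrides)`.
#' @param overrides Named list replacing entire components (any table name or
#'   `settings` entry). Unknown names are an error.
#' @return A validated [cvd_parameters] object.
#' @examples
#' params <- fixture_parameter_set(seed = 1)
#' nrow(validate_parameter_set(params)) == 0
#' @export
fixture_parameter_set <- function(seed = 1L, overrides = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  ages <- cvd_age_min:cvd_age_max

  # smooth age pyramid with a mild seeded ripple; slightly more women at
  # older ages
  ripple <- stats::spline(seq(18, 89, length.out = 7),
    runif(7, 0.95, 1.05),
    xout = ages
  )$y
  base_w <- exp(-((ages - 44) / 26)^2 / 2) * ripple
  female_frac <- pmin(pmax(0.5 + 0.0015 * (ages - 50), 0.45), 0.60)
  age_sex <- tibble(
    age = rep(ages, 2L),
    sex = rep(cvd_sexes, each = length(ages)),
    probability = c(base_w * female_frac, base_w * (1 - female_frac))
  ) |>
    mutate(probability = .data$probability / sum(.data$probability))

  marriage <- crossing(age = ages, sex = cvd_sexes) |>
    mutate(probability = 0.68 * stats::plogis((.data$age - 31) / 5) *
      if_else(.data$sex == "female", 1, 0.97))

  # spouse (age, sex) conditional on proband (age, sex); support limited to
  # +/- 6 years, husbands slightly older on average
  spouse <- crossing(
    proband_age = ages, proband_sex = cvd_sexes,
    offset = -6:6, spouse_sex = cvd_sexes
  ) |>
    mutate(spouse_age = pmin(pmax(.data$proband_age + .data$offset, cvd_age_min), cvd_age_max)) |>
    mutate(w = stats::dnorm(
      .data$spouse_age - .data$proband_age,
      mean = if_else(.data$spouse_sex == "male", 1.5, -1.5), sd = 2.5
    )) |>
    group_by(.data$proband_age, .data$proband_sex, .data$spouse_age, .data$spouse_sex) |>
    summarise(w = sum(.data$w), .groups = "drop") |>
    group_by(.data$proband_age, .data$proband_sex) |>
    mutate(probability = .data$w / sum(.data$w)) |>
    ungroup() |>
    select("proband_age", "proband_sex", "spouse_age", "spouse_sex", "probability")

  household_size <- tibble(
    size = 1:5,
    probability = c(0.30, 0.41, 0.15, 0.09, 0.05)
  )

  imd <- crossing(age = ages, sex = cvd_sexes, decile = 1:10) |>
    mutate(w = 1 + 0.02 * (.data$decile - 5.5) * (.data$age - 50) / 35) |>
    group_by(.data$age, .data$sex) |>
    mutate(probability = .data$w / sum(.data$w)) |>
    ungroup() |>
    select("age", "sex", "decile", "probability")

  employment <- crossing(age = ages, sex = cvd_sexes, decile = 1:10) |>
    mutate(probability = pmin(
      0.93 * stats::plogis((.data$age - 19.5) / 1.5) *
        (1 - stats::plogis((.data$age - 64) / 2.5)) *
        (0.72 + 0.028 * .data$decile) *
        if_else(.data$sex == "male", 1.03, 1),
      0.97
    ))

  workplace <- tibble(
    category = c("<10", "<50", "<250", "250+"),
    probability = c(0.20, 0.30, 0.30, 0.20),
    contact_mean = c(4, 6, 10, 21)
  )

  prevalence <- fixture_prevalence(ages)

  multipliers <- crossing(
    behaviour = cvd_behaviours, level = cvd_levels,
    tibble(age_lo = c(18, 45, 65), age_hi = c(45, 65, 90)),
    sex = cvd_sexes
  ) |>
    mutate(multiplier = fixture_multiplier(.data$behaviour, .data$level, .data$age_lo)) |>
    select("behaviour", "level", "age_lo", "age_hi", "sex", "multiplier") |>
    arrange(.data$behaviour, .data$level, .data$age_lo, .data$sex)

  # synthetic stand-in coefficients, same functional form as the real score:
  # linear predictor over x = (age - 60) / 10
  baseline_risk <- tibble(
    sex = rep(cvd_sexes, each = 4),
    term = rep(c("s0", "const", "age1", "age2"), 2),
    coefficient = c(
      0.890, 0, 0.877, -0.067,
      0.829, 0, 0.850, -0.075
    )
  )

  tables <- list(
    age_sex = age_sex, marriage = marriage, spouse = spouse,
    household_size = household_size, imd = imd, employment = employment,
    workplace = workplace, prevalence = prevalence, multipliers = multipliers,
    baseline_risk = baseline_risk, influence = default_influence_values(),
    observed_rates = default_observed_rates()
  )
  settings <- default_settings()

  unknown <- setdiff(names(overrides), c(names(tables), names(settings)))
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown override(s): %s. Valid keys: %s.",
      paste(unknown, collapse = ", "),
      paste(c(names(tables), names(settings)), collapse = ", ")
    ))
  }
  for (nm in intersect(names(overrides), names(tables))) {
    tables[[nm]] <- if (nm == "influence") {
      influence_matrix(overrides[[nm]])
    } else {
      as_tibble(overrides[[nm]])
    }
  }
  for (nm in intersect(names(overrides), names(settings))) {
    settings[[nm]] <- overrides[[nm]]
  }

  new_cvd_parameters(tables, settings)
}

fixture_prevalence <- function(ages) {
  grid <- crossing(behaviour = cvd_behaviours, age = ages, sex = cvd_sexes)
  raw <- grid |>
    mutate(
      p2 = dplyr::case_when(
        .data$behaviour == "smoking" ~
          0.22 * (1 - stats::plogis((.data$age - 60) / 8)) + 0.04,
        .data$behaviour == "alcohol" ~
          0.10 + 0.04 * if_else(.data$sex == "male", 1, 0) -
            0.0008 * (.data$age - 18),
        .data$behaviour == "diet" ~
          0.28 - 0.0015 * (.data$age - 18),
        TRUE ~ 0.20 + 0.0025 * (.data$age - 18)
      ),
      p1 = dplyr::case_when(
        .data$behaviour == "smoking" ~
          0.10 + 0.004 * (.data$age - 18),
        .data$behaviour == "alcohol" ~ 0.25,
        .data$behaviour == "diet" ~ 0.50,
        TRUE ~ 0.35
      )
    ) |>
    mutate(p0 = 1 - .data$p1 - .data$p2)
  raw |>
    pivot_longer(c("p0", "p1", "p2"), names_to = "level", values_to = "probability") |>
    mutate(level = as.integer(sub("p", "", .data$level))) |>
    select("behaviour", "age", "sex", "level", "probability") |>
    arrange(.data$behaviour, .data$age, .data$sex, .data$level)
}

fixture_multiplier <- function(behaviour, level, age_lo) {
  # level-2 relative risks shrink with age; level 0 is protective
  top <- dplyr::case_when(
    behaviour == "smoking" ~ c(1.9, 1.6, 1.35)[match(age_lo, c(18, 45, 65))],
    behaviour == "alcohol" ~ c(1.25, 1.2, 1.12)[match(age_lo, c(18, 45, 65))],
    behaviour == "diet" ~ c(1.45, 1.35, 1.2)[match(age_lo, c(18, 45, 65))],
    TRUE ~ c(1.5, 1.4, 1.25)[match(age_lo, c(18, 45, 65))]
  )
  dplyr::case_when(level == 0 ~ 0.9, level == 1 ~ 1.0, TRUE ~ top)
}

#' Generate a fixture CSV parameter directory
#'
#' Writes the full CSV directory for a synthetic parameter set (see
#' [fixture_parameter_set()]) so that the whole pipeline can be exercised
#' without any external data. Output is byte-identical for identical
#' `(seed, overrides)`.
#'
#' @param path Directory to create/populate.
#' @inheritParams fixture_parameter_set
#' @return The generated [cvd_parameters], invisibly.
#' @export
generate_fixture_parameters <- function(path, seed = 1L, overrides = list()) {
  params <- fixture_parameter_set(seed = seed, overrides = overrides)
  write_parameter_set(params, path)
  invisible(params)
}

# ---- CSV round trip ---------------------------------------------------------

parameter_files <- c(
  age_sex = "age_sex.csv", marriage = "marriage.csv", spouse = "spouse.csv",
  household_size = "household_size.csv", imd = "imd.csv",
  employment = "employment.csv", workplace = "workplace.csv",
  prevalence = "prevalence.csv", multipliers = "multipliers.csv",
  baseline_risk = "baseline_risk.csv", influence = "influence.csv",
  observed_rates = "observed_rates.csv"
)
optional_parameter_files <- c("influence", "observed_rates")

#' Write a parameter set to a CSV directory
#'
#' @param params A [cvd_parameters] object.
#' @param path Directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "cvd_parameters"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(parameter_files)) {
    tab <- params[[nm]]
    if (nm == "influence") tab <- influence_to_wide(tab)
    readr::write_csv(tab, file.path(path, parameter_files[[nm]]), progress = FALSE)
  }
  settings <- tibble(
    key = names(params$settings),
    value = vapply(params$settings, function(v) as.character(v), character(1))
  )
  readr::write_csv(settings, file.path(path, "settings.csv"), progress = FALSE)
  invisible(path)
}

#' Load and validate a parameter directory
#'
#' Reads the documented CSV files into a [cvd_parameters] object and
#' validates it. `settings.csv` and `observed_rates.csv` are optional
#' (defaults / empty); an `influence.csv` lacking workplace rows gets a zero
#' workplace block, matching the baseline assumption that workplace contacts
#' exert no influence.
#'
#' @param path Directory containing the CSV files.
#' @return A validated [cvd_parameters] object.
#' @export
load_parameter_set <- function(path) {
  if (!dir.exists(path)) abort(sprintf("Parameter directory not found: %s", path))
  tables <- list()
  for (nm in names(parameter_files)) {
    f <- file.path(path, parameter_files[[nm]])
    if (!file.exists(f)) {
      if (nm == "influence") {
        tables[[nm]] <- zero_influence()
        next
      }
      if (nm == "observed_rates") {
        tables[[nm]] <- default_observed_rates()[0, ]
        next
      }
      abort(sprintf("Missing mandatory parameter file: %s", parameter_files[[nm]]))
    }
    tab <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    if (nm == "influence") tab <- influence_matrix(tab)
    tables[[nm]] <- tab
  }
  settings <- default_settings()
  sf <- file.path(path, "settings.csv")
  if (file.exists(sf)) {
    raw <- readr::read_csv(sf, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(key = "c", value = "c")
    )
    for (i in seq_len(nrow(raw))) {
      key <- raw$key[[i]]
      if (!key %in% names(settings)) {
        abort(sprintf("settings.csv: unknown key '%s'.", key))
      }
      settings[[key]] <- if (key == "friendship_generator") {
        raw$value[[i]]
      } else {
        as.numeric(raw$value[[i]])
      }
    }
  }
  params <- new_cvd_parameters(tables, settings)
  issues <- validate_parameter_set(params)
  if (nrow(issues) > 0) {
    abort(paste0(
      "Invalid parameter set:\n",
      paste(sprintf("- [%s] %s: %s", issues$field, issues$cell, issues$message),
        collapse = "\n"
      )
    ))
  }
  params
}

# ---- validation -------------------------------------------------------------

issue <- function(field, cell, message) {
  tibble(field = field, cell = cell, message = message)
}

check_cell_sums <- function(tab, field, group_cols, tol = 1e-9) {
  sums <- tab |>
    group_by(across(all_of(group_cols))) |>
    summarise(total = sum(.data$probability), .groups = "drop") |>
    filter(abs(.data$total - 1) > tol)
  if (nrow(sums) == 0) {
    return(issue(character(), character(), character()))
  }
  cells <- if (length(group_cols) == 0) {
    "(whole table)"
  } else {
    apply(sums[group_cols], 1, function(r) paste(group_cols, r, sep = "=", collapse = ", "))
  }
  issue(field, cells, sprintf("probabilities sum to %.6f, expected 1", sums$total))
}

#' Validate a parameter set
#'
#' Checks every structural invariant: per-cell probability normalisation (to
#' 1e-9), probability and strength ranges, positive multipliers and contact
#' means, the modelled age window 18-89, and a positive threshold sd. Issues
#' are returned as data rather than raised, so a caller can inspect all
#' problems at once; [load_parameter_set()] turns a non-empty result into an
#' error.
#'
#' @param params A [cvd_parameters] object.
#' @return A tibble with columns `field`, `cell`, `message`; zero rows iff
#'   the parameter set is valid.
#' @export
validate_parameter_set <- function(params) {
  out <- list()
  add <- function(x) out[[length(out) + 1]] <<- x

  add(check_cell_sums(params$age_sex, "age_sex", character()))
  add(check_cell_sums(params$spouse, "spouse", c("proband_age", "proband_sex")))
  add(check_cell_sums(params$household_size, "household_size", character()))
  add(check_cell_sums(params$imd, "imd", c("age", "sex")))
  add(check_cell_sums(params$workplace, "workplace", character()))
  add(check_cell_sums(params$prevalence, "prevalence", c("behaviour", "age", "sex")))

  for (nm in c("age_sex", "marriage", "imd", "employment")) {
    bad_age <- params[[nm]] |>
      filter(.data$age < cvd_age_min | .data$age > cvd_age_max)
    if (nrow(bad_age) > 0) {
      add(issue(nm, sprintf("age=%d", bad_age$age),
        sprintf("age outside [%d, %d]", cvd_age_min, cvd_age_max)
      ))
    }
  }

  for (nm in c("marriage", "employment")) {
    bad <- params[[nm]] |>
      filter(.data$probability < 0 | .data$probability > 1)
    if (nrow(bad) > 0) {
      add(issue(nm, sprintf("age=%d, sex=%s", bad$age, bad$sex),
        "probability outside [0, 1]"
      ))
    }
  }

  bad_mult <- params$multipliers |> filter(.data$multiplier <= 0)
  if (nrow(bad_mult) > 0) {
    add(issue("multipliers",
      sprintf(
        "behaviour=%s, level=%d, age_band=[%d,%d), sex=%s",
        bad_mult$behaviour, bad_mult$level, bad_mult$age_lo,
        bad_mult$age_hi, bad_mult$sex
      ),
      "risk multiplier must be > 0"
    ))
  }

  infl <- params$influence
  bad_infl <- infl |> filter(.data$strength < 0 | .data$strength > 1)
  if (nrow(bad_infl) > 0) {
    add(issue("influence",
      sprintf(
        "relationship=%s, behaviour=%s, level=%d",
        bad_infl$relationship, bad_infl$behaviour, bad_infl$level
      ),
      "influence strength outside [0, 1]"
    ))
  }
  if (nrow(infl) != 48) {
    add(issue("influence", "(table)", sprintf(
      "expected 48 (relationship, behaviour, level) entries, found %d", nrow(infl)
    )))
  }

  bad_wp <- params$workplace |> filter(.data$contact_mean <= 0)
  if (nrow(bad_wp) > 0) {
    add(issue("workplace", sprintf("category=%s", bad_wp$category),
      "contact-group mean must be positive"
    ))
  }

  if (!is.numeric(params$settings$threshold_sd) ||
    params$settings$threshold_sd <= 0) {
    add(issue("settings", "threshold_sd", "must be > 0"))
  }
  excl <- params$settings$friendship_exclusion_fraction
  if (excl < 0 || excl > 1) {
    add(issue("settings", "friendship_exclusion_fraction", "must be in [0, 1]"))
  }
  if (!params$settings$friendship_generator %in% c("NWS", "BA")) {
    add(issue("settings", "friendship_generator", "must be 'NWS' or 'BA'"))
  }
  if (nrow(params$observed_rates) > 0 && any(params$observed_rates$rate < 0)) {
    bad <- params$observed_rates |> filter(.data$rate < 0)
    add(issue("observed_rates",
      sprintf("age_group=%s, sex=%s", bad$age_group, bad$sex),
      "rates must be >= 0"
    ))
  }

  out <- bind_rows(out)
  if (nrow(out) == 0) {
    tibble(field = character(), cell = character(), message = character())
  } else {
    out
  }
}
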