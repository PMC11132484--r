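#' CVD risk scoring
#'
#' Annual event probabilities follow a simplified ten-year survival score of
#' the same functional form as the published QRISK3 core model:
#' `risk10 = 1 - S0 ^ exp(lp)` with a per-sex baseline survival constant
#' `S0` and a linear predictor over age terms (clinical covariates such as
#' BMI, cholesterol ratio and systolic blood pressure enter only through
#' their defaults, folded into the coefficients). The ten-year risk is then
#' multiplied by one user-defined factor per behaviour — keyed by behaviour,
#' adoption level, age band and sex — and divided by 10 to give the
#' probability of an event in the current year. The score is applied between
#' ages 25 and 84; outside that window the annual probability is 0 and no
#' person-time is accrued.
#'
#' @name cvd-risk
NULL

baseline_model <- function(baseline_risk) {
  out <- list()
  for (sx in unique(baseline_risk$sex)) {
    d <- baseline_risk |> filter(.data$sex == sx)
    coefs <- setNames(d$coefficient, d$term)
    if (!"s0" %in% names(coefs)) {
      abort(sprintf("baseline_risk: missing s0 term for sex=%s", sx))
    }
    out[[sx]] <- coefs
  }
  out
}

#' Ten-year baseline CVD risk
#'
#' Evaluates `1 - S0 ^ exp(lp)` where
#' `lp = const + age1 * x + age2 * x^2`, `x = (age - 60) / 10`, with
#' coefficients taken per sex from the `baseline_risk` table. Ages outside
#' the 25-84 validity window return 0 (the caller treats such agents as not
#' at risk rather than erroring).
#'
#' @param age Integer ages.
#' @param sex `"female"` / `"male"` (recycled with `age`).
#' @param model Result of an internal model build from a `baseline_risk`
#'   table, or the table itself (columns `sex`, `term`, `coefficient`).
#' @return Ten-year event probabilities in `[0, 1]`.
#' @examples
#' tab <- fixture_parameter_set(1)$baseline_risk
#' baseline_ten_year_risk(c(40, 70), "female", tab)
#' @export
baseline_ten_year_risk <- function(age, sex, model) {
  if (is.data.frame(model)) model <- baseline_model(model)
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  x <- (age - 60) / 10
  for (sx in unique(sex)) {
    co <- model[[sx]]
    if (is.null(co)) abort(sprintf("No baseline coefficients for sex=%s", sx))
    i <- sex == sx
    term <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
    lp <- term("const") + term("age1") * x[i] + term("age2") * x[i]^2
    out[i] <- 1 - co[["s0"]]^exp(lp)
  }
  out[age < cvd_risk_age_min | age > cvd_risk_age_max] <- 0
  pmin(pmax(out, 0), 1)
}

# band index lookup keyed (behaviour, level, sex); errors name the full key
multiplier_lookup <- function(multipliers, behaviour, level, age, sex) {
  key <- paste(multipliers$behaviour, multipliers$level, multipliers$sex, sep = "\r")
  q <- paste(behaviour, level, sex, sep = "\r")
  groups <- split(seq_len(nrow(multipliers)), key)
  out <- rep(NA_real_, length(q))
  for (g in unique(q)) {
    rows <- groups[[g]]
    idx <- which(q == g)
    if (is.null(rows)) {
      parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
      abort(sprintf(
        "No risk multiplier rows for behaviour=%s, level=%s, sex=%s",
        parts[1], parts[2], parts[3]
      ))
    }
    d <- multipliers[rows, ]
    d <- d[order(d$age_lo), ]
    band <- findInterval(age[idx], d$age_lo)
    bad <- band == 0 | age[idx] >= d$age_hi[pmax(band, 1)]
    if (any(bad)) {
      parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
      abort(sprintf(
        "No age band covers age=%s for behaviour=%s, level=%s, sex=%s",
        paste(unique(age[idx][bad]), collapse = ","), parts[1], parts[2], parts[3]
      ))
    }
    out[idx] <- d$multiplier[band]
  }
  out
}

#' Combined behaviour risk multiplier
#'
#' The product of exactly four multiplier-table lookups, one per behaviour,
#' keyed by the agent's adoption level, age band (half-open `[age_lo,
#' age_hi)`) and sex. Only the current level matters: an ex-smoker carries
#' the ex-smoker factor regardless of when they quit.
#'
#' @param agents Data frame with columns `age`, `sex` and the four
#'   behaviour-level columns `smoking`, `alcohol`, `diet`, `inactivity`.
#' @param multipliers Multiplier table (columns `behaviour`, `level`,
#'   `age_lo`, `age_hi`, `sex`, `multiplier`).
#' @return A positive multiplier per row of `agents`.
#' @export
combined_multiplier <- function(agents, multipliers) {
  out <- rep(1, nrow(agents))
  for (b in cvd_behaviours) {
    out <- out * multiplier_lookup(
      multipliers, b, agents[[b]], agents$age, agents$sex
    )
  }
  out
}

#' Annual event probability
#'
#' Converts a ten-year risk and a combined behaviour multiplier into the
#' probability of an event in the current one-year step:
#' `clamp(risk10 * multiplier / 10, 0, 1)`.
#'
#' @param ten_year_risk Ten-year probabilities.
#' @param multiplier Positive multipliers.
#' @return Annual probabilities in `[0, 1]`.
#' @examples
#' annual_event_probability(0.2, 1) # 0.02
#' @export
annual_event_probability <- function(ten_year_risk, multiplier) {
  pmin(pmax(ten_year_risk * multiplier / 10, 0), 1)
}
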