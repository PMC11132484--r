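#' Influence strength matrices
#'
#' Influence strengths are stored long: one row per
#' `(relationship, behaviour, level)` with a `strength` in `[0, 1]` — 4
#' relationships x 4 behaviours x 3 levels = 48 entries. The CSV interchange
#' format is wide (`relationship, behaviour, level0, level1, level2`);
#' [influence_matrix()] accepts either and always returns the long form with
#' any missing workplace rows filled with strength 0, the baseline assumption
#' for workplace contacts.
#'
#' @param x A data frame in long or wide form.
#' @return A tibble of class `cvd_influence` with 48 rows.
#' @examples
#' infl <- fixture_parameter_set(1)$influence
#' subset(infl, relationship == "marriage" & behaviour == "smoking")
#' @export
influence_matrix <- function(x) {
  x <- as_tibble(x)
  if ("level0" %in% names(x)) {
    x <- x |>
      pivot_longer(c("level0", "level1", "level2"),
        names_to = "level", values_to = "strength"
      ) |>
      mutate(level = as.integer(sub("level", "", .data$level)))
  }
  required <- c("relationship", "behaviour", "level", "strength")
  if (!all(required %in% names(x))) {
    abort("Influence table needs columns relationship, behaviour, level[0-2]/strength.")
  }
  bad_rel <- setdiff(unique(x$relationship), cvd_relationships)
  if (length(bad_rel) > 0) {
    abort(sprintf("Unknown relationship(s): %s", paste(bad_rel, collapse = ", ")))
  }
  bad_beh <- setdiff(unique(x$behaviour), cvd_behaviours)
  if (length(bad_beh) > 0) {
    abort(sprintf("Unknown behaviour(s): %s", paste(bad_beh, collapse = ", ")))
  }
  full <- crossing(
    relationship = cvd_relationships, behaviour = cvd_behaviours,
    level = cvd_levels
  ) |>
    left_join(x |> select(all_of(required)),
      by = c("relationship", "behaviour", "level")
    ) |>
    mutate(strength = if_else(
      is.na(.data$strength) & .data$relationship == "workplace",
      0, .data$strength
    ))
  if (any(is.na(full$strength))) {
    missing <- full |> filter(is.na(.data$strength))
    abort(sprintf(
      "Influence strengths missing for: %s",
      paste(sprintf(
        "(%s, %s, %d)", missing$relationship, missing$behaviour,
        missing$level
      ), collapse = ", ")
    ))
  }
  full <- full |>
    mutate(
      relationship = factor(.data$relationship, cvd_relationships),
      behaviour = factor(.data$behaviour, cvd_behaviours)
    ) |>
    arrange(.data$relationship, .data$behaviour, .data$level) |>
    mutate(
      relationship = as.character(.data$relationship),
      behaviour = as.character(.data$behaviour)
    )
  class(full) <- c("cvd_influence", class(full))
  full
}

zero_influence <- function() {
  influence_matrix(crossing(
    relationship = cvd_relationships, behaviour = cvd_behaviours,
    level = cvd_levels, strength = 0
  ))
}

influence_to_wide <- function(infl) {
  as_tibble(infl) |>
    mutate(level = paste0("level", .data$level)) |>
    pivot_wider(names_from = "level", values_from = "strength")
}

# Fast lookup array strength[[relationship]][behaviour, level + 1].
influence_array <- function(infl, extra = NULL) {
  infl <- bind_rows(as_tibble(infl), extra)
  split_rel <- split(infl, infl$relationship)
  lapply(split_rel, function(d) {
    m <- matrix(0, nrow = length(cvd_behaviours), ncol = 3,
      dimnames = list(cvd_behaviours, as.character(cvd_levels))
    )
    m[cbind(match(d$behaviour, cvd_behaviours), d$level + 1L)] <- d$strength
    m
  })
}

# Free (non-workplace) entries as a named numeric vector in a fixed order;
# used by the calibration search.
influence_to_free_vector <- function(infl) {
  d <- as_tibble(infl) |>
    filter(.data$relationship != "workplace") |>
    mutate(
      relationship = factor(.data$relationship, cvd_relationships[1:3]),
      behaviour = factor(.data$behaviour, cvd_behaviours)
    ) |>
    arrange(.data$relationship, .data$behaviour, .data$level)
  setNames(d$strength, sprintf("%s.%s.%d", d$relationship, d$behaviour, d$level))
}

free_vector_to_influence <- function(v) {
  stopifnot(length(v) == 36)
  if (is.null(names(v))) names(v) <- names(free_vector_template())
  parts <- strsplit(names(v), ".", fixed = TRUE)
  influence_matrix(tibble(
    relationship = vapply(parts, `[[`, "", 1),
    behaviour = vapply(parts, `[[`, "", 2),
    level = as.integer(vapply(parts, `[[`, "", 3)),
    strength = unname(v)
  ))
}

free_vector_template <- function() {
  influence_to_free_vector(zero_influence())
}
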