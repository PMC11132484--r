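# shared fixture parameter set (built once per test run)
fx_env <- new.env()
fx_params <- function() {
  if (is.null(fx_env$params)) fx_env$params <- fixture_parameter_set(1)
  fx_env$params
}

behaviours4 <- c("smoking", "alcohol", "diet", "inactivity")

# hand-built population: `agents` needs id + behaviour levels; everything
# else gets workable defaults
toy_population <- function(levels, edges, threshold = 0.8,
                           ever_smoked = NULL, alive = NULL) {
  n <- nrow(levels)
  agents <- tibble::tibble(
    id = levels$id,
    age = 40L, sex = "female", imd = 5L, household = seq_len(n),
    employed = FALSE,
    threshold = rep_len(threshold, n),
    smoking = levels$smoking, alcohol = levels$alcohol,
    diet = levels$diet, inactivity = levels$inactivity,
    ever_smoked = ever_smoked %||% (levels$smoking != 0L),
    alive = alive %||% rep(TRUE, n),
    wp_group = NA_integer_
  )
  structure(list(agents = agents, edges = edges), class = "cvd_population")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force influence sums: plain loops over the edge list and
# the long influence tibble
oracle_incoming <- function(pop, infl) {
  agents <- pop$agents
  n <- nrow(agents)
  out <- array(0, dim = c(n, 4, 3),
    dimnames = list(agents$id, behaviours4, 0:2)
  )
  infl <- as.data.frame(infl)
  strength_of <- function(rel, b, lv) {
    infl$strength[infl$relationship == rel & infl$behaviour == b & infl$level == lv]
  }
  for (k in seq_len(nrow(pop$edges))) {
    e <- pop$edges[k, ]
    for (pair in list(c(e$from, e$to), c(e$to, e$from))) {
      i <- match(pair[1], agents$id)
      j <- match(pair[2], agents$id)
      if (!agents$alive[j]) next
      for (b in behaviours4) {
        lv <- agents[[b]][j]
        out[i, b, as.character(lv)] <-
          out[i, b, as.character(lv)] + strength_of(e$relationship, b, lv)
      }
    }
  }
  out
}

# deterministic part of the threshold rule: candidate set per agent/behaviour
oracle_candidates <- function(pop, incoming) {
  agents <- pop$agents
  lapply(seq_len(nrow(agents)), function(i) {
    sets <- list()
    for (b in behaviours4) {
      cand <- which(incoming[i, b, ] > agents$threshold[i]) - 1L
      if (b == "smoking" && agents$ever_smoked[i]) cand <- setdiff(cand, 0L)
      sets[[b]] <- cand
    }
    sets
  })
}

# pair-level audit table: one row per unordered pair carrying an edge
edge_pairs <- function(pop) {
  e <- pop$edges
  data.frame(
    lo = pmin(e$from, e$to), hi = pmax(e$from, e$to),
    relationship = e$relationship
  )
}
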