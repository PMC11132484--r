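#' Behaviour spread
#'
#' One synchronized update of all agents' behaviour levels under the
#' modified linear-threshold model. For each agent the incoming influence
#' from its relationships is summed per behaviour and level (12 values);
#' for each behaviour, every level whose summed influence strictly exceeds
#' the agent's threshold is a candidate. No candidate: the level is kept.
#' One candidate: it is adopted. Several: one is drawn with probability
#' proportional to its influence. Smoking level 0 ("never smoked") is
#' removed from the candidates of any agent that has ever smoked, so the
#' best an ever-smoker can reach is ex-smoker (level 1).
#'
#' All influence sums use the level snapshot from the start of the step and
#' all levels are committed simultaneously afterwards; tie-break draws are
#' made in agent-id order, so the committed state does not depend on how
#' the agent table happens to be ordered.
#'
#' @name behaviour-spread
NULL

# adjacency matrices per effective relationship; workplace edges are split
# into adopting / non-adopting groups when an intervention is active
build_spread_state <- function(population, influence, intervention = NULL) {
  agents <- arrange(population$agents, .data$id)
  n <- nrow(agents)
  edges <- population$edges
  adj <- list()
  strengths <- influence_array(influence)

  split_edges <- split(edges[c("from", "to")], edges$relationship)
  for (rel in intersect(cvd_relationships[1:3], names(split_edges))) {
    adj[[rel]] <- edge_matrix(split_edges[[rel]], n)
  }
  wp <- split_edges[["workplace"]]
  if (!is.null(wp) && nrow(wp) > 0) {
    if (is.null(intervention)) {
      adj[["workplace"]] <- edge_matrix(wp, n)
    } else {
      grp <- agents$wp_group[wp$from] # endpoints share a group by construction
      adopting <- grp %in% intervention$adopting_groups
      if (any(!adopting)) adj[["workplace"]] <- edge_matrix(wp[!adopting, ], n)
      if (any(adopting)) {
        adj[["workplace_adopting"]] <- edge_matrix(wp[adopting, ], n)
        strengths[["workplace_adopting"]] <- intervention$active_strengths
      }
    }
  }
  list(agents = agents, adj = adj, strengths = strengths, n = n)
}

edge_matrix <- function(e, n) {
  Matrix::sparseMatrix(
    i = c(e$from, e$to), j = c(e$to, e$from), x = 1, dims = c(n, n)
  )
}

spread_step_core <- function(state) {
  agents <- state$agents
  n <- state$n
  alive <- agents$alive
  thr <- agents$threshold
  new_levels <- matrix(0L, nrow = n, ncol = length(cvd_behaviours),
    dimnames = list(NULL, cvd_behaviours)
  )
  for (b in cvd_behaviours) {
    cur <- agents[[b]]
    infl <- matrix(0, nrow = n, ncol = 3)
    for (lv in cvd_levels) {
      v <- as.numeric(alive & cur == lv)
      if (!any(v > 0)) next
      for (rel in names(state$adj)) {
        s <- state$strengths[[rel]][b, lv + 1]
        if (s > 0) {
          infl[, lv + 1] <- infl[, lv + 1] + s * as.numeric(state$adj[[rel]] %*% v)
        }
      }
    }
    exceed <- infl > thr
    if (b == "smoking") exceed[, 1] <- exceed[, 1] & !agents$ever_smoked
    w <- infl * exceed
    tot <- rowSums(w)
    any_exceed <- tot > 0
    u <- runif(n) # drawn for every agent in id order, step determinism
    c1 <- w[, 1] / pmax(tot, .Machine$double.xmin)
    c2 <- (w[, 1] + w[, 2]) / pmax(tot, .Machine$double.xmin)
    chosen <- ifelse(u < c1, 0L, ifelse(u < c2, 1L, 2L))
    new_levels[, b] <- ifelse(alive & any_exceed, chosen, cur)
  }
  new_levels
}

#' Incoming influence summary for one agent
#'
#' Sums, for each behaviour and each level, the influence strengths of the
#' agent's neighbours currently at that level — the 12 values the
#' linear-threshold rule compares against the agent's threshold. Uses only
#' the current (snapshot) levels.
#'
#' @param population A [cvd_population].
#' @param influence A [influence_matrix()].
#' @param id Agent id.
#' @param intervention Optional result of [apply_workplace_intervention()].
#' @return A 12-row tibble with columns `behaviour`, `level`, `influence`.
#' @export
incoming_influence <- function(population, influence, id,
                               intervention = NULL) {
  agents <- population$agents
  edges <- population$edges
  touching <- edges[edges$from == id | edges$to == id, ]
  out <- tibble(
    behaviour = rep(cvd_behaviours, each = 3L),
    level = rep(cvd_levels, times = length(cvd_behaviours)),
    influence = 0
  )
  if (nrow(touching) == 0) {
    return(out)
  }
  neigh <- if_else(touching$from == id, touching$to, touching$from)
  rel <- touching$relationship
  arr <- influence_array(influence)
  if (!is.null(intervention)) {
    my_grp <- agents$wp_group[match(neigh, agents$id)]
    active <- rel == "workplace" & my_grp %in% intervention$adopting_groups
    rel[active] <- "workplace_adopting"
    arr[["workplace_adopting"]] <- intervention$active_strengths
  }
  nb <- agents[match(neigh, agents$id), ]
  vals <- out$influence
  for (k in seq_along(neigh)) {
    if (!nb$alive[k]) next
    for (bi in seq_along(cvd_behaviours)) {
      b <- cvd_behaviours[bi]
      lv <- nb[[b]][k]
      row <- (bi - 1L) * 3L + lv + 1L
      vals[row] <- vals[row] + arr[[rel[k]]][b, lv + 1]
    }
  }
  out$influence <- vals
  out
}

#' Resolve one behaviour-level decision
#'
#' Applies the threshold rule to one agent and one behaviour: levels whose
#' incoming influence strictly exceeds `threshold` are candidates; with no
#' candidate the current level is kept, a single candidate is adopted, and
#' among several one is drawn with probability proportional to its
#' influence. For smoking, level 0 is removed from the candidate set first
#' whenever the agent has ever smoked.
#'
#' @param influence_vector Numeric length 3: influence for levels 0, 1, 2.
#' @param threshold Agent threshold in (0, 1).
#' @param current_level Current level (0, 1 or 2).
#' @param behaviour Behaviour name; the smoking exception applies only to
#'   `"smoking"`.
#' @param ever_smoked Has the agent ever been at smoking level > 0?
#' @return The new level.
#' @examples
#' resolve_level(c(0, 0, 0.755), threshold = 0.8, current_level = 0) # keeps 0
#' @export
resolve_level <- function(influence_vector, threshold, current_level,
                          behaviour = "other", ever_smoked = FALSE) {
  stopifnot(length(influence_vector) == 3)
  candidates <- which(influence_vector > threshold) - 1L
  if (behaviour == "smoking" && ever_smoked) {
    candidates <- setdiff(candidates, 0L)
  }
  if (length(candidates) == 0) {
    return(as.integer(current_level))
  }
  if (length(candidates) == 1) {
    return(as.integer(candidates))
  }
  w <- influence_vector[candidates + 1L]
  as.integer(sample(candidates, 1L, prob = w))
}

#' Synchronized behaviour update for the whole population
#'
#' Computes every agent's incoming influence from the start-of-step
#' snapshot, resolves all 4 behaviour decisions per agent, and commits all
#' new levels atomically. The result is independent of the ordering of the
#' agent table; with a fixed RNG state it is fully reproducible.
#'
#' @inheritParams incoming_influence
#' @return The population with updated levels and `ever_smoked` flags.
#' @export
step_behaviours <- function(population, influence, intervention = NULL) {
  state <- build_spread_state(population, influence, intervention)
  new_levels <- spread_step_core(state)
  agents <- state$agents
  for (b in cvd_behaviours) agents[[b]] <- new_levels[, b]
  agents$ever_smoked <- agents$ever_smoked | agents$smoking != 0L
  new_cvd_population(agents, population$edges)
}
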