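#' Synthetic populations
#'
#' A `cvd_population` holds the agent table and the typed relationship edge
#' list. Agents carry the attributes that drive behaviour spread and risk:
#' age (integer years, 18-89 at generation), sex, IMD decile, employment,
#' the personal influence threshold, the current adoption level (0/1/2) of
#' each of the four behaviours, an ever-smoked flag and an alive flag.
#' Edges are undirected, at most one per unordered pair, typed by the strict
#' relationship hierarchy marriage > household > friendship > workplace.
#'
#' @name cvd_population
NULL

new_cvd_population <- function(agents, edges) {
  structure(list(agents = agents, edges = edges), class = "cvd_population")
}

#' @export
print.cvd_population <- function(x, ...) {
  cat(sprintf(
    "<cvd_population> %d agents (%d alive), %d edges\n",
    nrow(x$agents), sum(x$agents$alive), nrow(x$edges)
  ))
  print(count(x$edges, .data$relationship))
  invisible(x)
}

# conditional sampler over `value` given a cell key; returns a closure
# mapping vectors of keys to sampled values
make_cell_sampler <- function(tab, key_cols, value_col, prob_col = "probability") {
  keys <- do.call(paste, c(tab[key_cols], sep = "\r"))
  split_idx <- split(seq_len(nrow(tab)), keys)
  support <- lapply(split_idx, function(i) tab[[value_col]][i])
  cum <- lapply(split_idx, function(i) {
    p <- tab[[prob_col]][i]
    cumsum(p / sum(p))
  })
  function(...) {
    q <- do.call(paste, c(list(...), sep = "\r"))
    cells <- match(q, names(support))
    if (anyNA(cells)) {
      abort(sprintf(
        "No distribution for cell(s): %s",
        paste(unique(q[is.na(cells)]), collapse = "; ")
      ))
    }
    sample_by_cell(cells, support, cum)
  }
}

lookup_prob <- function(tab, key_cols, ...) {
  keys <- do.call(paste, c(tab[key_cols], sep = "\r"))
  q <- do.call(paste, c(list(...), sep = "\r"))
  idx <- match(q, keys)
  if (anyNA(idx)) {
    abort(sprintf(
      "No probability for cell(s): %s",
      paste(unique(q[is.na(idx)]), collapse = "; ")
    ))
  }
  tab$probability[idx]
}

rtruncnorm01 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0 | x >= 1)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0 | x[bad] >= 1]
  }
  x
}

sample_levels <- function(prevalence, age, sex) {
  out <- matrix(NA_integer_, nrow = length(age), ncol = length(cvd_behaviours),
    dimnames = list(NULL, cvd_behaviours)
  )
  for (b in cvd_behaviours) {
    tab <- prevalence |> filter(.data$behaviour == b)
    sampler <- make_cell_sampler(tab, c("age", "sex"), "level")
    out[, b] <- as.integer(sampler(age, sex))
  }
  out
}

#' Generate households, marriages and the base agent set
#'
#' Households are generated sequentially until the target population size is
#' reached: each household starts from one agent drawn from the joint
#' age/sex distribution; marriage is decided by the agent's age/sex
#' probability, the spouse drawn from the conditional age distribution after
#' deciding same- vs opposite-sex by the configured fraction; the adult
#' household size is then sampled (kept at least as large as the members
#' already present) and remaining adults drawn from the age/sex
#' distribution. All members share the initial member's sampled IMD decile.
#' Generation stops after the household in which the target is reached, so
#' the final count overshoots by at most the largest household size minus
#' one. Household members form a clique of `household` edges, with the
#' spousal pair carrying a `marriage` edge instead. Employment, behaviour
#' levels (from prevalence by age/sex) and thresholds (truncated
#' `Normal(threshold_mean, threshold_sd)` on (0,1)) are sampled here too.
#'
#' @param target_size Minimum number of agents to generate.
#' @param params A [cvd_parameters] object.
#' @return A [cvd_population] with marriage and household edges.
#' @export
generate_households <- function(target_size, params) {
  stopifnot(target_size >= 1)
  s <- params$settings

  hs <- params$household_size
  if (sum(hs$probability) <= 0) abort("household_size distribution has empty support.")
  draw_hh_size <- function(n) {
    as.integer(hs$size[sample.int(nrow(hs), n, replace = TRUE, prob = hs$probability)])
  }
  imd_sampler <- make_cell_sampler(params$imd, c("age", "sex"), "decile")
  spouse_sampler <- make_cell_sampler(
    params$spouse, c("proband_age", "proband_sex", "spouse_sex"), "spouse_age"
  )
  as_tab <- params$age_sex
  if (sum(as_tab$probability) <= 0) abort("age_sex distribution has empty support.")
  draw_person <- function(n) {
    idx <- sample.int(nrow(as_tab), n, replace = TRUE, prob = as_tab$probability)
    list(age = as.integer(as_tab$age[idx]), sex = as_tab$sex[idx])
  }
  mean_size <- sum(params$household_size$size * params$household_size$probability)

  hh <- list()
  total <- 0L
  while (total < target_size) {
    b <- max(64L, ceiling((target_size - total) / mean_size * 1.15))
    init <- draw_person(b)
    p_marry <- lookup_prob(params$marriage, c("age", "sex"), init$age, init$sex)
    married <- runif(b) < p_marry
    spouse_age <- rep(NA_integer_, b)
    spouse_sex <- rep(NA_character_, b)
    if (any(married)) {
      m <- which(married)
      same <- runif(length(m)) < s$same_sex_marriage_fraction
      spouse_sex[m] <- if_else(same, init$sex[m],
        if_else(init$sex[m] == "female", "male", "female")
      )
      spouse_age[m] <- as.integer(
        spouse_sampler(init$age[m], init$sex[m], spouse_sex[m])
      )
    }
    size_sampled <- draw_hh_size(b)
    size_final <- pmax(size_sampled, 1L + married)
    imd <- as.integer(imd_sampler(init$age, init$sex))
    batch <- list(
      init_age = init$age, init_sex = init$sex, married = married,
      spouse_age = spouse_age, spouse_sex = spouse_sex,
      size = size_final, imd = imd
    )
    hh[[length(hh) + 1]] <- batch
    total <- total + sum(size_final)
  }

  init_age <- unlist(lapply(hh, `[[`, "init_age"))
  init_sex <- unlist(lapply(hh, `[[`, "init_sex"))
  married <- unlist(lapply(hh, `[[`, "married"))
  spouse_age <- unlist(lapply(hh, `[[`, "spouse_age"))
  spouse_sex <- unlist(lapply(hh, `[[`, "spouse_sex"))
  size <- unlist(lapply(hh, `[[`, "size"))
  imd <- unlist(lapply(hh, `[[`, "imd"))

  keep <- which(cumsum(size) - size < target_size) # stop once target reached
  init_age <- init_age[keep]; init_sex <- init_sex[keep]
  married <- married[keep]; spouse_age <- spouse_age[keep]
  spouse_sex <- spouse_sex[keep]; size <- size[keep]; imd <- imd[keep]

  n_hh <- length(size)
  n_extra <- size - 1L - married
  extras <- draw_person(sum(n_extra))

  # agents laid out household by household: initial member, spouse, extras
  n_agents <- sum(size)
  age <- integer(n_agents); sex <- character(n_agents)
  hh_of <- rep.int(seq_len(n_hh), size)
  starts <- cumsum(size) - size + 1L
  age[starts] <- init_age; sex[starts] <- init_sex
  sp_pos <- starts[married] + 1L
  age[sp_pos] <- spouse_age[married]; sex[sp_pos] <- spouse_sex[married]
  extra_pos <- setdiff(seq_len(n_agents), c(starts, sp_pos))
  age[extra_pos] <- extras$age; sex[extra_pos] <- extras$sex

  levels <- sample_levels(params$prevalence, age, sex)
  employed <- runif(n_agents) <
    lookup_prob(params$employment, c("age", "sex", "decile"),
      age, sex, imd[hh_of]
    )

  agents <- tibble(
    id = seq_len(n_agents),
    age = age,
    sex = sex,
    imd = imd[hh_of],
    household = hh_of,
    employed = employed,
    threshold = rtruncnorm01(n_agents, s$threshold_mean, s$threshold_sd),
    smoking = levels[, "smoking"],
    alcohol = levels[, "alcohol"],
    diet = levels[, "diet"],
    inactivity = levels[, "inactivity"],
    ever_smoked = levels[, "smoking"] != 0L,
    alive = TRUE,
    wp_group = NA_integer_
  )

  edges <- household_clique_edges(starts, size, married)
  new_cvd_population(agents, edges)
}

# clique edges over contiguous id runs, marriage edge for positions (1,2)
# of married households
household_clique_edges <- function(starts, size, married) {
  acc <- list()
  for (sz in sort(unique(size[size >= 2L]))) {
    st <- starts[size == sz]
    is_m <- married[size == sz]
    pairs <- combn(sz, 2L)
    from <- as.vector(outer(st, pairs[1, ] - 1L, "+"))
    to <- as.vector(outer(st, pairs[2, ] - 1L, "+"))
    rel <- rep("household", length(from))
    spousal <- as.vector(outer(is_m, pairs[1, ] == 1L & pairs[2, ] == 2L, "&"))
    rel[spousal] <- "marriage"
    acc[[length(acc) + 1]] <- tibble(from = from, to = to, relationship = rel)
  }
  # married households of sampled size 1 were forced to size 2 already, so
  # every spousal pair is inside a clique
  if (length(acc) == 0) {
    return(tibble(from = integer(), to = integer(), relationship = character()))
  }
  bind_rows(acc)
}

#' Build the friendship network
#'
#' A configured fraction of agents (default 7%) is uniformly excluded,
#' modelling individuals without close friends. Over the included agents a
#' friendship graph is generated with the configured generator: `"NWS"`
#' (Newman-Watts-Strogatz: ring lattice of degree `round(mean_degree)` plus
#' random shortcut edges added with the configured probability per lattice
#' edge) or `"BA"` (Barabasi-Albert preferential attachment with
#' `m = round(mean_degree / 2)`, via igraph). Edges duplicating an existing
#' marriage or household pair are removed to enforce the relationship
#' hierarchy.
#'
#' @param population A [cvd_population] from [generate_households()].
#' @param params A [cvd_parameters] object.
#' @return The population with friendship edges appended.
#' @export
build_friendship_network <- function(population, params) {
  s <- params$settings
  agents <- population$agents
  n <- nrow(agents)
  included <- which(runif(n) >= s$friendship_exclusion_fraction)
  m <- length(included)
  if (m == 0) {
    return(population)
  }
  perm <- included[sample.int(m)]

  if (identical(s$friendship_generator, "NWS")) {
    nei <- max(1L, round(s$friendship_mean_degree / 2))
    if (m < 2L * nei + 2L) {
      abort("Too few included agents for the NWS friendship generator.")
    }
    ring_from <- rep(seq_len(m), each = nei)
    ring_to <- ring_from + rep(seq_len(nei), times = m)
    ring_to <- ((ring_to - 1L) %% m) + 1L
    shortcut <- which(runif(length(ring_from)) < s$nws_shortcut_prob)
    sc_from <- ring_from[shortcut]
    sc_to <- sample.int(m, length(shortcut), replace = TRUE)
    ef <- c(ring_from, sc_from)
    et <- c(ring_to, sc_to)
  } else if (identical(s$friendship_generator, "BA")) {
    m_ba <- max(1L, round(s$friendship_mean_degree / 2))
    if (m <= m_ba) {
      abort("Too few included agents for the BA friendship generator.")
    }
    g <- igraph::sample_pa(m, m = m_ba, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    ef <- el[, 1]
    et <- el[, 2]
  } else {
    abort("friendship_generator must be 'NWS' or 'BA'.")
  }

  from <- perm[ef]
  to <- perm[et]
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  key <- pair_key(from, to)
  dup <- duplicated(key)
  from <- from[!dup]; to <- to[!dup]; key <- key[!dup]
  # hierarchy: drop pairs already tied by marriage or household
  higher <- pair_key(population$edges$from, population$edges$to)
  ok <- !(key %in% higher)
  lo <- pmin(from[ok], to[ok])
  hi <- pmax(from[ok], to[ok])
  fe <- tibble(from = lo, to = hi, relationship = "friendship")
  new_cvd_population(agents, bind_rows(population$edges, fe))
}

#' Assign workplace contact groups
#'
#' Employed agents are assigned, in random order, to workplace contact
#' groups. Each group first draws a workplace size category from the
#' configured distribution; the group size is then
#' `round(Normal(contact_mean_for_category, sd))` with a minimum of 2 (sd
#' defaults to a quarter of the mean). Groups are filled until every
#' employed agent has a workplace, so the final group may fall short of its
#' sampled size. Each group forms a clique of `workplace` edges except for
#' pairs already holding a higher-ranked relationship.
#'
#' @param population A [cvd_population].
#' @param params A [cvd_parameters] object.
#' @param contact_mean Optional fixed contact-group mean (e.g. 4 or 21)
#'   overriding the per-category means.
#' @return The population with `wp_group` filled and workplace edges added.
#' @export
assign_workplaces <- function(population, params, contact_mean = NULL) {
  agents <- population$agents
  emp <- which(agents$employed)
  if (length(emp) == 0) {
    return(population)
  }
  wp <- params$workplace
  if (!is.null(contact_mean)) wp$contact_mean <- contact_mean
  if (any(wp$contact_mean <= 0)) abort("Workplace contact means must be positive.")
  sd_setting <- params$settings$contact_group_sd
  min_size <- params$settings$contact_group_min

  order_emp <- emp[sample.int(length(emp))]
  n_emp <- length(order_emp)
  sizes <- integer(0)
  while (sum(sizes) < n_emp) {
    k <- max(16L, ceiling((n_emp - sum(sizes)) / mean(wp$contact_mean)))
    cat_idx <- sample.int(nrow(wp), k, replace = TRUE, prob = wp$probability)
    mu <- wp$contact_mean[cat_idx]
    sdv <- if (is.na(sd_setting)) mu / 4 else rep(sd_setting, k)
    sizes <- c(sizes, pmax(min_size, as.integer(round(rnorm(k, mu, sdv)))))
  }
  n_groups <- which(cumsum(sizes) >= n_emp)[1]
  sizes <- sizes[seq_len(n_groups)]
  sizes[n_groups] <- n_emp - sum(sizes[-n_groups]) # final group may fall short
  sizes <- sizes[sizes > 0]
  n_groups <- length(sizes)

  group_of <- rep.int(seq_len(n_groups), sizes)
  agents$wp_group[order_emp] <- group_of

  starts <- cumsum(sizes) - sizes + 1L
  acc <- list()
  for (sz in sort(unique(sizes[sizes >= 2L]))) {
    st <- starts[sizes == sz]
    pairs <- combn(sz, 2L)
    fi <- as.vector(outer(st, pairs[1, ] - 1L, "+"))
    ti <- as.vector(outer(st, pairs[2, ] - 1L, "+"))
    acc[[length(acc) + 1]] <- tibble(
      from = order_emp[fi], to = order_emp[ti]
    )
  }
  if (length(acc) == 0) {
    return(new_cvd_population(agents, population$edges))
  }
  we <- bind_rows(acc)
  key <- pair_key(we$from, we$to)
  higher <- pair_key(population$edges$from, population$edges$to)
  we <- we[!(key %in% higher), ]
  lo <- pmin(we$from, we$to)
  hi <- pmax(we$from, we$to)
  we <- tibble(from = lo, to = hi, relationship = "workplace")
  new_cvd_population(agents, bind_rows(population$edges, we))
}

#' Generate a complete population
#'
#' Runs [generate_households()], [build_friendship_network()] and
#' [assign_workplaces()] in sequence.
#'
#' @inheritParams generate_households
#' @inheritParams assign_workplaces
#' @param seed Optional integer seed; if supplied the generation is fully
#'   reproducible.
#' @return A [cvd_population].
#' @examples
#' params <- fixture_parameter_set(1)
#' pop <- generate_population(500, params, seed = 7)
#' @export
generate_population <- function(target_size, params, contact_mean = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  generate_households(target_size, params) |>
    build_friendship_network(params) |>
    assign_workplaces(params, contact_mean = contact_mean)
}

#' Dump / load a population as CSV
#'
#' `write_population()` writes `agents.csv` and `edges.csv` (deterministic id
#' order); `read_population()` reads them back.
#'
#' @param population A [cvd_population].
#' @param path Directory for the CSV pair.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns a [cvd_population].
#' @export
write_population <- function(population, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(arrange(population$agents, .data$id),
    file.path(path, "agents.csv"),
    progress = FALSE
  )
  readr::write_csv(
    arrange(population$edges, .data$from, .data$to),
    file.path(path, "edges.csv"),
    progress = FALSE
  )
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  agents <- readr::read_csv(file.path(path, "agents.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  edges <- readr::read_csv(file.path(path, "edges.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  new_cvd_population(as_tibble(agents), as_tibble(edges))
}
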