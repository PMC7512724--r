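# Seeded generators: random networks, Dirichlet expert panels with
# covariate-linked subgroup shifts, and the packaged wayfinding fixture.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (all(g == 0)) g <- alpha  # numerically degenerate; fall back to the mean
  g / sum(g)
}

#' Random discrete Bayesian network
#'
#' Samples a valid network: a random topological order over the nodes, each
#' node picking up to `max_parents` parents uniformly among its
#' predecessors, and every CPT row drawn from a flat Dirichlet. Identical
#' seeds give identical networks; the caller's RNG state is left untouched.
#'
#' @param n_nodes Number of nodes (>= 1); named `N1`, `N2`, ...
#' @param max_parents Maximum number of parents per node (>= 0).
#' @param n_states Number of states per node (`s1`, `s2`, ...).
#' @param seed Integer seed.
#' @return A valid [discrete_bn()] object.
#' @export
random_network <- function(n_nodes, max_parents = 2L, n_states = 2L, seed = 1L) {
  stopifnot(n_nodes >= 1L, max_parents >= 0L, n_states >= 2L)
  with_seed(seed, {
    nodes <- sprintf("N%d", seq_len(n_nodes))
    states <- sprintf("s%d", seq_len(n_states))
    order <- sample(nodes)
    cps <- vector("list", n_nodes)
    for (i in seq_len(n_nodes)) {
      nd <- order[i]
      avail <- order[seq_len(i - 1L)]
      k <- if (length(avail) == 0L) 0L else sample(0:min(max_parents, length(avail)), 1L)
      parents <- if (k > 0L) sort(sample(avail, k)) else character()
      pst <- stats::setNames(rep(list(states), length(parents)), parents)
      n_rows <- max(1L, n_states^length(parents))
      prob <- t(vapply(seq_len(n_rows), function(r) rdirichlet1(rep(1, n_states)),
                       numeric(n_states)))
      cps[[i]] <- cpt(nd, states, prob, parents, pst)
    }
    # declaration order independent of the sampled topological order
    cps <- cps[match(nodes, vapply(cps, `[[`, "", "child"))]
    discrete_bn(cps, name = sprintf("random-%d-%d", n_nodes, seed))
  })
}

#' One covariate-linked shift of a consensus CPT column
#'
#' Describes a systematic opinion difference of a subgroup: before the
#' per-expert Dirichlet noise is applied, experts in `category` of
#' `covariate` have `delta` added to the probability of `state` in every row
#' of `node`'s CPT (entries clipped to stay inside (0, 1), rows
#' renormalised).
#'
#' @param covariate,category Which experts the shift applies to.
#' @param node,state Which CPT column is shifted.
#' @param delta Signed shift on the probability scale.
#' @return A `subgroup_effect` list.
#' @export
subgroup_effect <- function(covariate, category, node, state, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, abs(delta) < 1)
  structure(list(covariate = covariate, category = category, node = node,
                 state = state, delta = delta),
            class = "subgroup_effect")
}

#' Recipe for a synthetic expert panel
#'
#' Fixes the study conditions of a simulated elicitation: `n_experts`
#' respondents whose CPT rows scatter around a consensus network as
#' `Dirichlet(concentration * consensus_row)` (so larger `concentration`
#' means tighter agreement; the expected row is the consensus row),
#' covariates assigned by exact largest-remainder counts from the stated
#' frequencies and then shuffled, and optional [subgroup_effect()] shifts
#' applied to the consensus before perturbation.
#'
#' @param n_experts Number of experts.
#' @param concentration Dirichlet concentration kappa > 0.
#' @param subgroup_effects List of [subgroup_effect()] objects.
#' @param covariate_frequencies Named list: covariate -> named numeric vector
#'   of category proportions summing to 1.
#' @param seed Integer seed.
#' @return A `panel_recipe` list.
#' @export
panel_recipe <- function(n_experts, concentration,
                         subgroup_effects = list(),
                         covariate_frequencies = list(), seed = 1L) {
  if (!is.numeric(concentration) || concentration <= 0) {
    stop_bnpool("`concentration` must be > 0", "bnpool_input_error")
  }
  if (!is.numeric(n_experts) || n_experts < 1L) {
    stop_bnpool("`n_experts` must be >= 1", "bnpool_input_error")
  }
  if (inherits(subgroup_effects, "subgroup_effect")) {
    subgroup_effects <- list(subgroup_effects)
  }
  for (ef in subgroup_effects) {
    if (!inherits(ef, "subgroup_effect")) {
      stop_bnpool("`subgroup_effects` must be subgroup_effect() objects",
                  "bnpool_input_error")
    }
    if (!ef$covariate %in% names(covariate_frequencies)) {
      stop_bnpool(sprintf("effect covariate '%s' has no stated frequencies",
                          ef$covariate), "bnpool_input_error")
    }
  }
  for (cv in names(covariate_frequencies)) {
    fr <- covariate_frequencies[[cv]]
    if (is.null(names(fr)) || any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
      stop_bnpool(sprintf("frequencies of '%s' must be named, non-negative and sum to 1",
                          cv), "bnpool_input_error")
    }
  }
  structure(list(n_experts = as.integer(n_experts),
                 concentration = concentration,
                 subgroup_effects = subgroup_effects,
                 covariate_frequencies = covariate_frequencies,
                 seed = as.integer(seed)),
            class = "panel_recipe")
}

# exact largest-remainder category counts, then a seeded shuffle
assign_covariates <- function(ids, covariate_frequencies) {
  out <- tibble::tibble(expert_id = ids)
  n <- length(ids)
  for (cv in names(covariate_frequencies)) {
    fr <- covariate_frequencies[[cv]]
    raw <- fr * n
    counts <- floor(raw)
    short <- n - sum(counts)
    if (short > 0L) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
      counts[extra] <- counts[extra] + 1L
    }
    labels <- rep(names(fr), times = counts)
    out[[cv]] <- sample(labels)
  }
  out
}

# move the target state's probability by delta (clipped to stay inside
# (0, 1)) and rescale the remaining states proportionally, so the injected
# shift is exactly delta wherever clipping does not bind
shift_row <- function(row, state_idx, delta, eps = 1e-6) {
  target <- min(max(row[state_idx] + delta, eps), 1 - eps)
  others <- row[-state_idx]
  if (sum(others) <= 0) {
    others <- rep(1, length(others))
  }
  row[-state_idx] <- others * (1 - target) / sum(others)
  row[state_idx] <- target
  row
}

#' Generate a synthetic expert panel around a consensus network
#'
#' Draws `n_experts` CPT assessment sets: each expert's version of every CPT
#' row is `Dirichlet(kappa * base_row)`, where the base row is the consensus
#' row after any [subgroup_effect()] shifts applicable to that expert's
#' covariates. Experts get equal pooling weights. The generator is a pure
#' function of `(consensus, recipe)` — the recipe's seed drives covariate
#' assignment and all draws.
#'
#' @param consensus A valid [discrete_bn()]: the shared structure and the
#'   centre of the opinion distribution.
#' @param recipe A [panel_recipe()].
#' @return An [expert_panel()].
#' @export
generate_panel <- function(consensus, recipe) {
  stopifnot(inherits(consensus, "bn"), inherits(recipe, "panel_recipe"))
  report <- validate_network(consensus)
  if (nrow(report) > 0L) {
    stop_bnpool("`consensus` fails validate_network()", "bnpool_validation_error")
  }
  for (ef in recipe$subgroup_effects) {
    if (!ef$node %in% node_names(consensus) ||
        !ef$state %in% consensus$nodes[[ef$node]]) {
      stop_bnpool(sprintf("effect targets unknown node/state %s=%s",
                          ef$node, ef$state), "bnpool_input_error")
    }
  }
  n <- recipe$n_experts
  ids <- sprintf("e%0*d", nchar(as.character(n)), seq_len(n))
  with_seed(recipe$seed, {
    covs <- assign_covariates(ids, recipe$covariate_frequencies)
    experts <- vector("list", n)
    names(experts) <- ids
    for (i in seq_len(n)) {
      id <- ids[i]
      cps <- lapply(node_names(consensus), function(nd) {
        cp <- consensus$cpts[[nd]]
        base <- cp$prob
        for (ef in recipe$subgroup_effects) {
          if (ef$node != nd) next
          if (!identical(as.character(covs[[ef$covariate]][i]), ef$category)) next
          k <- match(ef$state, cp$states)
          for (r in seq_len(nrow(base))) base[r, ] <- shift_row(base[r, ], k, ef$delta)
        }
        drawn <- t(vapply(seq_len(nrow(base)), function(r) {
          rdirichlet1(recipe$concentration * base[r, ])
        }, numeric(ncol(base))))
        cpt(cp$child, cp$states, drawn, cp$parents, cp$parent_states)
      })
      names(cps) <- node_names(consensus)
      experts[[id]] <- cps
    }
    expert_panel(consensus, experts, covariates = covs, check = FALSE)
  })
}

#' The packaged six-node wayfinding fixture
#'
#' A schematic binary network about wayfinding in airport terminals, plus a
#' synthetic 99-respondent panel. The six nodes and their state labels are
#' the standard ones of the airport wayfinding literature (Communication:
#' Effective/Ineffective; Environmental Factors: Good/Bad; Human Factors:
#' Good/Bad; Navigation Pathway: Simple/Complex; Visual Elements of
#' Communication: Good/Bad; Wayfinding: Effective/Ineffective). The edge set
#' is a schematic reading of those node descriptions — Visual Elements of
#' Communication feeds Communication, Navigation Pathway feeds Environmental
#' Factors, and Human Factors, Environmental Factors and Communication feed
#' Wayfinding — **not** a transcription of the full 49-node wayfinding
#' model, whose topology and CPTs are unpublished. All CPT values here are
#' synthetic by construction.
#'
#' The panel emulates the published survey composition: 99 respondents with
#' covariates Gender (46 Female / 53 Male), Travel Purpose (32 Business /
#' 67 Personal) and Travel Experience (85 Experienced / 14 Inexperienced),
#' equal weights, Dirichlet concentration `kappa` around the consensus, and
#' two documented synthetic subgroup shifts (Inexperienced respondents rate
#' Wayfinding less Effective; Female respondents rate Human Factors more
#' Good).
#'
#' @param kappa Dirichlet concentration of the panel (default 20).
#' @param seed Integer seed (default 2018) — the packaged panel is the
#'   default-seed one.
#' @return List with elements `network` (the consensus [discrete_bn()]) and
#'   `panel` (the 99-expert [expert_panel()]).
#' @examples
#' fx <- wayfinding_fixture()
#' table(fx$panel$covariates$Gender)
#' @export
wayfinding_fixture <- function(kappa = 20, seed = 2018L) {
  g2 <- c("Good", "Bad")
  e2 <- c("Effective", "Ineffective")
  s2 <- c("Simple", "Complex")
  net <- discrete_bn(list(
    cpt("Human Factors", g2, prob = c(0.75, 0.25)),
    cpt("Navigation Pathway", s2, prob = c(0.65, 0.35)),
    cpt("Visual Elements of Communication", g2, prob = c(0.80, 0.20)),
    cpt("Environmental Factors", g2,
        parents = "Navigation Pathway",
        parent_states = list(`Navigation Pathway` = s2),
        prob = rbind(c(0.85, 0.15), c(0.55, 0.45))),
    cpt("Communication", e2,
        parents = "Visual Elements of Communication",
        parent_states = list(`Visual Elements of Communication` = g2),
        prob = rbind(c(0.85, 0.15), c(0.40, 0.60))),
    cpt("Wayfinding", e2,
        parents = c("Human Factors", "Environmental Factors", "Communication"),
        parent_states = list(`Human Factors` = g2, `Environmental Factors` = g2,
                             Communication = e2),
        # canonical rows: Communication fastest, Human Factors slowest
        prob = rbind(c(0.95, 0.05), c(0.80, 0.20), c(0.80, 0.20), c(0.60, 0.40),
                     c(0.60, 0.40), c(0.40, 0.60), c(0.35, 0.65), c(0.10, 0.90)))),
    name = "wayfinding")
  recipe <- panel_recipe(
    n_experts = 99L,
    concentration = kappa,
    subgroup_effects = list(
      subgroup_effect("Travel Experience", "Inexperienced",
                      "Wayfinding", "Effective", -0.10),
      subgroup_effect("Gender", "Female", "Human Factors", "Good", 0.05)),
    covariate_frequencies = list(
      Gender = c(Female = 46 / 99, Male = 53 / 99),
      `Travel Purpose` = c(Business = 32 / 99, Personal = 67 / 99),
      `Travel Experience` = c(Experienced = 85 / 99, Inexperienced = 14 / 99)),
    seed = seed)
  list(network = net, panel = generate_panel(net, recipe))
}
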