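#' A panel of experts sharing one network structure
#'
#' Represents `n` experts who agree on the structure of a discrete Bayesian
#' network — its nodes, state spaces and arcs — but hold their own opinions
#' about every conditional probability. Each expert contributes a full CPT
#' set over the shared skeleton; a covariate table (categorical descriptors
#' such as Gender or Travel Experience) supports subgroup analysis, and a
#' positive weight vector summing to 1 drives the linear opinion pool. By
#' default every expert receives equal weight `1/n`.
#'
#' @param structure A [discrete_bn()] object supplying the shared skeleton
#'   (nodes, states, edges); its own CPT values are ignored.
#' @param experts Named list: `expert_id -> list of` [cpt()] objects (or a
#'   named list `node -> cpt`) over the shared structure.
#' @param covariates Optional data frame with an `expert_id` column and one
#'   column per categorical covariate; missing entries are kept as `NA`
#'   ("missing" category). Defaults to an empty covariate table.
#' @param weights Optional named numeric vector of pooling weights (positive,
#'   summing to 1). Default: equal weights `1/n`.
#' @param check Validate the panel on construction (default `TRUE`).
#'
#' @return An object of class `expert_panel`.
#' @seealso [validate_panel()], [filter_subgroup()], [pool_prior()],
#'   [pool_posterior()]
#' @export
expert_panel <- function(structure, experts, covariates = NULL, weights = NULL,
                         check = TRUE) {
  stopifnot(inherits(structure, "bn"), is.list(experts))
  if (is.null(names(experts)) || any(!nzchar(names(experts)))) {
    stop_bnpool("`experts` must be a named list keyed by expert id",
                "bnpool_input_error")
  }
  experts <- lapply(experts, function(cps) {
    if (inherits(cps, "cpt")) cps <- list(cps)
    if (is.null(names(cps))) names(cps) <- vapply(cps, `[[`, "", "child")
    cps
  })
  n <- length(experts)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / n, n), names(experts))
  }
  if (is.null(covariates)) {
    covariates <- tibble::tibble(expert_id = names(experts))
  }
  covariates <- tibble::as_tibble(covariates)
  panel <- structure(
    list(structure = structure, experts = experts,
         covariates = covariates, weights = weights),
    class = "expert_panel")
  if (check) {
    report <- validate_panel(panel)
    if (nrow(report) > 0L) {
      stop_bnpool(paste0("invalid panel:\n",
                         paste0("  - ", report$message, collapse = "\n")),
                  "bnpool_validation_error")
    }
  }
  panel
}

#' @export
print.expert_panel <- function(x, ...) {
  cat(sprintf("<expert panel> %d experts over '%s' (%d nodes)\n",
              length(x$experts), x$structure$name, length(x$structure$nodes)))
  covs <- setdiff(names(x$covariates), "expert_id")
  if (length(covs)) cat("  covariates:", paste(covs, collapse = ", "), "\n")
  eq <- length(unique(round(x$weights, 12))) == 1L
  cat(sprintf("  weights: %s\n", if (eq) sprintf("equal (1/%d)", length(x$experts))
                                  else "unequal"))
  invisible(x)
}

n_experts <- function(panel) length(panel$experts)
expert_ids <- function(panel) names(panel$experts)

# build the i-th expert's own network on the shared skeleton
expert_bn <- function(panel, id) {
  cps <- panel$experts[[id]]
  discrete_bn(unname(cps[node_names(panel$structure)]),
              name = sprintf("%s (expert %s)", panel$structure$name, id),
              check = FALSE)
}

#' Validate an expert panel
#'
#' Reports structure mismatches per expert (missing or extra CPTs, different
#' parents, parent order, or state spaces from the shared skeleton),
#' per-expert CPT violations (via [validate_network()]), weight violations
#' (non-positive or not summing to 1), and covariate rows that do not match
#' the expert ids. Reporting only; [expert_panel()] refuses panels whose
#' report is non-empty. A missing CPT is a hard failure — no imputation of
#' opinions is ever attempted.
#'
#' @param panel An `expert_panel`.
#' @return Tibble with columns `expert_id`, `node`, `violation`, `message`;
#'   zero rows for a valid panel.
#' @export
validate_panel <- function(panel) {
  bad <- list()
  add <- function(expert_id, node, violation, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      expert_id = expert_id, node = node, violation = violation, message = message)
  }
  skel <- panel$structure
  for (id in expert_ids(panel)) {
    cps <- panel$experts[[id]]
    miss <- setdiff(node_names(skel), names(cps))
    for (nd in miss) {
      add(id, nd, "missing_cpt",
          sprintf("expert '%s' has no CPT for node '%s'", id, nd))
    }
    extra <- setdiff(names(cps), node_names(skel))
    for (nd in extra) {
      add(id, nd, "extra_cpt",
          sprintf("expert '%s' has a CPT for unknown node '%s'", id, nd))
    }
    for (nd in intersect(names(cps), node_names(skel))) {
      cp <- cps[[nd]]
      if (!identical(cp$states, skel$nodes[[nd]])) {
        add(id, nd, "state_mismatch",
            sprintf("expert '%s', node '%s': states differ from the shared structure",
                    id, nd))
      }
      if (!identical(cp$parents, skel$parents[[nd]])) {
        add(id, nd, "parent_mismatch",
            sprintf("expert '%s', node '%s': parents differ from the shared structure (%s vs %s)",
                    id, nd, paste(cp$parents, collapse = ","),
                    paste(skel$parents[[nd]], collapse = ",")))
      }
    }
    if (length(miss) == 0L && length(extra) == 0L) {
      rep_i <- validate_network(expert_bn(panel, id))
      for (k in seq_len(nrow(rep_i))) {
        add(id, rep_i$node[k], rep_i$violation[k],
            sprintf("expert '%s': %s", id, rep_i$message[k]))
      }
    }
  }
  w <- panel$weights
  if (!setequal(names(w), expert_ids(panel)) || length(w) != n_experts(panel)) {
    add(NA_character_, NA_character_, "weight_names",
        "weights must be named by the expert ids, one weight per expert")
  } else {
    if (any(w <= 0)) {
      add(NA_character_, NA_character_, "weight_sign",
          "all pooling weights must be strictly positive")
    }
    if (abs(sum(w) - 1) > 1e-9) {
      add(NA_character_, NA_character_, "weight_sum",
          sprintf("weights sum %.10g != 1", sum(w)))
    }
  }
  if (!"expert_id" %in% names(panel$covariates)) {
    add(NA_character_, NA_character_, "covariate_ids",
        "covariate table lacks an `expert_id` column")
  } else {
    missing_cov <- setdiff(expert_ids(panel), panel$covariates$expert_id)
    for (id in missing_cov) {
      add(id, NA_character_, "covariate_row",
          sprintf("expert '%s' has no covariate row", id))
    }
  }
  if (length(bad) == 0L) {
    tibble::tibble(expert_id = character(), node = character(),
                   violation = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Restrict a panel to a covariate-defined subgroup
#'
#' Keeps the experts matching *all* the given covariate constraints and
#' renormalises their weights proportionally (`w_i / sum_subgroup w_j`), so
#' equal weights stay equal. The original panel is unchanged. Filtering down
#' to zero experts is an error — a linear pool over no experts is undefined.
#'
#' @param panel An `expert_panel`.
#' @param constraints Named character vector / list `covariate = category`;
#'   an empty constraint set returns the panel unchanged.
#' @return A new `expert_panel` holding the matching experts.
#' @examples
#' \dontrun{
#' females <- filter_subgroup(panel, c(Gender = "Female"))
#' }
#' @export
filter_subgroup <- function(panel, constraints = character()) {
  constraints <- unlist(as.list(constraints))
  if (length(constraints) == 0L) return(panel)
  covs <- panel$covariates
  for (cv in names(constraints)) {
    if (!cv %in% names(covs)) {
      stop_bnpool(sprintf("unknown covariate '%s'", cv), "bnpool_input_error")
    }
  }
  keep_ids <- covs$expert_id
  for (cv in names(constraints)) {
    match_ids <- covs$expert_id[!is.na(covs[[cv]]) & covs[[cv]] == constraints[[cv]]]
    keep_ids <- intersect(keep_ids, match_ids)
  }
  keep_ids <- intersect(expert_ids(panel), keep_ids)
  if (length(keep_ids) == 0L) {
    stop_bnpool(sprintf("no experts match the constraints: %s",
                        paste(sprintf("%s=%s", names(constraints), constraints),
                              collapse = ", ")),
                "bnpool_empty_subgroup")
  }
  w <- panel$weights[keep_ids]
  expert_panel(panel$structure, panel$experts[keep_ids],
               covariates = covs[covs$expert_id %in% keep_ids, , drop = FALSE],
               weights = w / sum(w), check = FALSE)
}

#' Enumerate the subgroups of one or more covariates
#'
#' Convenience used by [subgroup_report()]: returns one constraint set per
#' observed category of each named covariate (e.g. for `"Gender"`:
#' `Female`, `Male`), labelled by the category.
#'
#' @param panel An `expert_panel`.
#' @param covariates Character vector of covariate names.
#' @return Named list of single-constraint character vectors.
#' @export
subgroup_partitions <- function(panel, covariates) {
  out <- list()
  for (cv in covariates) {
    if (!cv %in% names(panel$covariates)) {
      stop_bnpool(sprintf("unknown covariate '%s'", cv), "bnpool_input_error")
    }
    cats <- unique(stats::na.omit(panel$covariates[[cv]]))
    for (cat in cats) out[[as.character(cat)]] <- stats::setNames(as.character(cat), cv)
  }
  out
}
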