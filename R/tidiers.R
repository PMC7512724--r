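#' Tidy a pooled result into a long tibble
#'
#' @param x A `pooled_result` from [pool_posterior()] or
#'   [pool_prior_marginals()].
#' @param ... Unused.
#' @return Tibble with columns `method`, `subgroup`, `node`, `state`,
#'   `prob`.
#' @method tidy pooled_result
#' @export
tidy.pooled_result <- function(x, ...) {
  out <- dplyr::bind_rows(lapply(x$marginals, as_tibble))
  tibble::tibble(method = x$method, subgroup = x$panel_label,
                 node = out$node, state = out$state, prob = out$prob)
}

#' One-row summary of a pooled result
#'
#' @param x A `pooled_result`.
#' @param ... Unused.
#' @return Tibble with `method`, `subgroup`, `n_experts`, `n_targets`,
#'   `n_evidence`.
#' @method glance pooled_result
#' @export
glance.pooled_result <- function(x, ...) {
  tibble::tibble(method = x$method, subgroup = x$panel_label,
                 n_experts = x$n_experts, n_targets = length(x$marginals),
                 n_evidence = length(x$evidence))
}

#' Tidy a network into its long CPT table
#'
#' @param x A [discrete_bn()] object.
#' @param ... Unused.
#' @return Tibble with one row per CPT entry: `node`, the parent state
#'   columns of that node, `state`, `prob`. Nodes are stacked, so parent
#'   columns not applying to a node are `NA`.
#' @method tidy bn
#' @export
tidy.bn <- function(x, ...) {
  dplyr::bind_rows(lapply(x$cpts, as_tibble))
}

#' One-row summary of a network
#'
#' @param x A [discrete_bn()] object.
#' @param ... Unused.
#' @return Tibble with `name`, `n_nodes`, `n_edges`, `n_parameters` (free
#'   CPT entries, i.e. rows times (states - 1)).
#' @method glance bn
#' @export
glance.bn <- function(x, ...) {
  n_par <- sum(vapply(x$cpts, function(cp) nrow(cp$prob) * (ncol(cp$prob) - 1L), 1L))
  tibble::tibble(name = x$name, n_nodes = length(x$nodes),
                 n_edges = sum(lengths(x$parents)), n_parameters = n_par)
}

#' Tidy an expert panel into its covariate/weight table
#'
#' @param x An [expert_panel()].
#' @param ... Unused.
#' @return The covariate tibble with a `weight` column appended.
#' @method tidy expert_panel
#' @export
tidy.expert_panel <- function(x, ...) {
  covs <- x$covariates
  covs$weight <- unname(x$weights[covs$expert_id])
  covs
}

#' One-row summary of an expert panel
#'
#' @param x An [expert_panel()].
#' @param ... Unused.
#' @return Tibble with `n_experts`, `n_nodes`, `n_covariates`,
#'   `equal_weights`.
#' @method glance expert_panel
#' @export
glance.expert_panel <- function(x, ...) {
  tibble::tibble(
    n_experts = n_experts(x),
    n_nodes = length(x$structure$nodes),
    n_covariates = length(setdiff(names(x$covariates), "expert_id")),
    equal_weights = isTRUE(all.equal(unname(x$weights),
                                     rep(1 / n_experts(x), n_experts(x)))))
}
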