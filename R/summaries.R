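#' Propagate a what-if scenario through a network
#'
#' Clamps the scenario nodes to the given states (e.g. "Wayfinding is 100%
#' Effective") and reports the updated conditional marginals of the nodes of
#' interest. Conditioning against the arc direction is diagnostic reasoning
#' (from effect to cause), with the arcs it is predictive reasoning; both are
#' the same computation here.
#'
#' @param net A [discrete_bn()] object (typically a pooled network).
#' @param clamp Named character vector of clamped states.
#' @param report_nodes Nodes whose updated marginals to report; must be
#'   disjoint from `clamp`.
#' @return Tibble with columns `node`, `state`, `prob` (one block per report
#'   node), carrying the clamp as the `evidence` attribute.
#' @examples
#' \dontrun{
#' diagnostic_scenario(pooled, c(Wayfinding = "Effective"),
#'                     c("Human Factors", "Communication"))
#' }
#' @export
diagnostic_scenario <- function(net, clamp, report_nodes) {
  clamp <- check_evidence(net, clamp)
  overlap <- intersect(report_nodes, names(clamp))
  if (length(overlap)) {
    stop_bnpool(sprintf("report node(s) %s appear in the clamp",
                        paste(overlap, collapse = ", ")), "bnpool_input_error")
  }
  out <- dplyr::bind_rows(lapply(report_nodes, function(nd) {
    as_tibble(marginal(net, nd, clamp))
  }))
  attr(out, "evidence") <- clamp
  out
}

#' Absolute-difference table between a baseline and scenarios
#'
#' Tabulates, state by state, the absolute change of each scenario's
#' marginals against a baseline — the "value [absolute difference]" layout
#' used when comparing subgroups or clamped scenarios against a full model.
#'
#' @param baseline Tibble of marginals with columns `node`, `state`, `prob`
#'   (as returned by [diagnostic_scenario()] or `tidy()` on a pooled
#'   result).
#' @param scenarios Named list of tibbles with the same columns, covering
#'   the baseline's (node, state) pairs; names become the `label` column.
#' @return Tibble with columns `label`, `node`, `state`, `baseline`,
#'   `scenario`, `abs_diff` (`abs_diff = |scenario - baseline|`).
#' @export
delta_table <- function(baseline, scenarios) {
  stopifnot(is.list(scenarios))
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    stop_bnpool("`scenarios` must be a named list of marginal tables",
                "bnpool_input_error")
  }
  base <- dplyr::select(tibble::as_tibble(baseline),
                        node = "node", state = "state", baseline = "prob")
  rows <- purrr::imap(scenarios, function(tbl, label) {
    tbl <- dplyr::select(tibble::as_tibble(tbl),
                         node = "node", state = "state", scenario = "prob")
    joined <- dplyr::left_join(base, tbl, by = c("node", "state"))
    if (anyNA(joined$scenario)) {
      miss <- joined[is.na(joined$scenario), ]
      stop_bnpool(sprintf("scenario '%s' lacks (node, state) pair(s): %s", label,
                          paste(sprintf("%s=%s", miss$node, miss$state), collapse = ", ")),
                  "bnpool_input_error")
    }
    dplyr::mutate(joined, label = label, abs_diff = abs(.data$scenario - .data$baseline))
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("label", "node", "state", "baseline", "scenario", "abs_diff")
}

#' Per-expert propagated probabilities at one node state
#'
#' Propagates every expert's network individually under the evidence and
#' returns each expert's probability for `node = state`, in panel order.
#' This is the raw material behind across-expert spread summaries
#' (means, standard-deviation bars, boxplots) and, weighted by the panel
#' weights, its mean is exactly the Posterior Linear Pool value.
#'
#' @inheritParams pool_posterior
#' @param node Target node name.
#' @param state State label of `node` to report.
#' @return Tibble with columns `expert_id`, `prob` (one row per expert, in
#'   panel order; experts dropped for impossible evidence are omitted when
#'   `drop_impossible = TRUE`).
#' @export
per_expert_marginals <- function(panel, node, state, evidence = character(),
                                 drop_impossible = FALSE) {
  refuse_invalid_panel(panel)
  if (!node %in% node_names(panel$structure)) {
    stop_bnpool(sprintf("unknown node '%s'", node), "bnpool_input_error")
  }
  k <- match(state, panel$structure$nodes[[node]])
  if (is.na(k)) {
    stop_bnpool(sprintf("'%s' is not a state of node '%s'", state, node),
                "bnpool_input_error")
  }
  ids <- expert_ids(panel)
  vals <- stats::setNames(rep(NA_real_, length(ids)), ids)
  impossible <- character()
  for (id in ids) {
    m <- tryCatch(marginal(expert_bn(panel, id), node, evidence),
                  bnpool_impossible_evidence = function(e) e)
    if (inherits(m, "condition")) impossible <- c(impossible, id)
    else vals[[id]] <- m$probabilities[[k]]
  }
  if (length(impossible) > 0L) {
    if (!drop_impossible) {
      stop_bnpool(sprintf("evidence is impossible for expert(s): %s",
                          paste(impossible, collapse = ", ")),
                  "bnpool_impossible_evidence")
    }
    warning(sprintf("dropping %d expert(s) with impossible evidence",
                    length(impossible)), call. = FALSE)
    vals <- vals[setdiff(ids, impossible)]
  }
  tibble::tibble(expert_id = names(vals), prob = unname(vals))
}

#' Descriptive spread of per-expert probabilities
#'
#' Mean, sample standard deviation (n - 1 denominator; 0 when n = 1) and the
#' five-number summary of a vector of per-expert probabilities. Quartiles use
#' linear interpolation between order statistics (`stats::quantile()` type
#' 7, the common default of mainstream numeric stacks).
#'
#' @param values Data frame with a `prob` column (e.g. from
#'   [per_expert_marginals()]) or a bare numeric vector of probabilities.
#' @param node,state,label Optional metadata carried into the output.
#' @return One-row tibble: `node`, `state`, `label`, `n`, `mean`, `sd`,
#'   `min`, `q1`, `median`, `q3`, `max`.
#' @examples
#' describe_spread(c(0.2, 0.4, 0.6, 0.8))  # median 0.5, q1 0.35, q3 0.65
#' @export
describe_spread <- function(values, node = NA_character_, state = NA_character_,
                            label = NA_character_) {
  if (is.data.frame(values)) values <- values$prob
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop_bnpool("`values` must be a non-empty numeric vector without NAs",
                "bnpool_input_error")
  }
  if (any(values < 0 | values > 1)) {
    stop_bnpool("probabilities must lie in [0, 1]", "bnpool_input_error")
  }
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  tibble::tibble(
    node = node, state = state, label = label, n = length(values),
    mean = mean(values),
    sd = if (length(values) == 1L) 0 else stats::sd(values),
    min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Subgroup comparison report
#'
#' The across-subgroup workflow: pool the full panel, pool each subgroup,
#' and tabulate every subgroup's marginals at the target nodes against the
#' full-panel baseline with absolute differences. Two routes to a
#' "subgroup" are supported and may be combined with fixed evidence:
#'
#' * **filter route** (`subgroups`): covariate constraints select the
#'   experts, the pool is recomputed on the sub-panel (the natural route for
#'   Posterior Linear Pooling, where each respondent has their own network);
#' * **conditioning route** (`subgroup_evidence`): the subgroup is a node of
#'   the network itself and is clamped as evidence in the full pooled model
#'   (the natural route for Prior Linear Pooling when the structure contains
#'   e.g. a Gender node).
#'
#' @inheritParams pool_posterior
#' @param subgroups Named list of covariate constraint vectors (see
#'   [filter_subgroup()]); use [subgroup_partitions()] to enumerate the
#'   categories of a covariate.
#' @param subgroup_evidence Named list of evidence vectors, each clamped on
#'   top of `evidence` in the full-panel pooled model.
#' @param method `"PrLP"` or `"PoLP"`.
#' @return Tibble with columns `method`, `subgroup`, `n_experts`, `node`,
#'   `state`, `value`, `abs_diff` (difference against the `"All"` rows,
#'   which carry `abs_diff = 0`).
#' @export
subgroup_report <- function(panel, targets, subgroups = list(),
                            subgroup_evidence = list(),
                            evidence = character(),
                            method = c("PoLP", "PrLP"),
                            drop_impossible = FALSE) {
  method <- match.arg(method)
  pool_fun <- function(p, ev) {
    if (method == "PoLP") pool_posterior(p, targets, ev, drop_impossible = drop_impossible)
    else pool_prior_marginals(p, targets, ev)
  }
  full <- pool_fun(panel, evidence)
  blocks <- list(result_block(full, "All", baseline = NULL))
  baseline <- generics::tidy(full)
  for (lab in names(subgroups)) {
    sub <- filter_subgroup(panel, subgroups[[lab]])
    blocks[[length(blocks) + 1L]] <- result_block(pool_fun(sub, evidence), lab, baseline)
  }
  for (lab in names(subgroup_evidence)) {
    ev2 <- c(evidence, unlist(as.list(subgroup_evidence[[lab]])))
    blocks[[length(blocks) + 1L]] <- result_block(pool_fun(panel, ev2), lab, baseline)
  }
  dplyr::bind_rows(blocks)
}

result_block <- function(res, label, baseline) {
  tbl <- generics::tidy(res)
  if (is.null(baseline)) {
    diff <- rep(0, nrow(tbl))
  } else {
    joined <- dplyr::left_join(tbl, dplyr::select(baseline, "node", "state", base = "prob"),
                               by = c("node", "state"))
    diff <- abs(joined$prob - joined$base)
  }
  tibble::tibble(method = res$method, subgroup = label, n_experts = res$n_experts,
                 node = tbl$node, state = tbl$state, value = tbl$prob,
                 abs_diff = diff)
}

#' Spread report across a panel and its subgroups
#'
#' For each (node, state) of interest and each subgroup, propagates every
#' expert individually and summarises the spread of their probabilities with
#' [describe_spread()] — the tabular counterpart of mean/standard-deviation
#' bar plots and per-subgroup boxplots.
#'
#' @inheritParams subgroup_report
#' @param nodes Named character vector `node = state` giving, for each node
#'   of interest, the state to report (for binary nodes, one state carries
#'   all the information).
#' @return Tibble: one [describe_spread()] row per (subgroup, node), plus
#'   the `"All"` rows for the full panel.
#' @export
spread_report <- function(panel, nodes, subgroups = list(),
                          evidence = character(), drop_impossible = FALSE) {
  groups <- c(list(All = NULL), subgroups)
  rows <- purrr::imap(groups, function(constr, lab) {
    p <- if (is.null(constr)) panel else filter_subgroup(panel, constr)
    dplyr::bind_rows(lapply(names(nodes), function(nd) {
      vals <- per_expert_marginals(p, nd, nodes[[nd]], evidence,
                                   drop_impossible = drop_impossible)
      describe_spread(vals, node = nd, state = nodes[[nd]], label = lab)
    }))
  })
  dplyr::bind_rows(rows)
}
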