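#' Linear opinion pool of probability vectors
#'
#' The convex combination `sum_i w_i P_i` of `n` experts' probability
#' distributions over one common state space, with positive weights summing
#' to 1. This is the primitive behind both pooling strategies: Prior Linear
#' Pooling applies it to each CPT row, Posterior Linear Pooling to each
#' propagated marginal.
#'
#' @param distributions List of numeric probability vectors, all of the same
#'   length, each summing to 1 (within 1e-9).
#' @param weights Numeric vector of positive weights summing to 1 (within
#'   1e-9); default equal weights.
#' @return A single pooled probability vector, renormalised to absorb float
#'   error.
#' @examples
#' linear_pool(list(c(0.6, 0.4), c(0.8, 0.2)))  # c(0.7, 0.3)
#' @export
linear_pool <- function(distributions, weights = NULL) {
  if (is.matrix(distributions)) {
    distributions <- asplit(distributions, 1L)
  }
  stopifnot(is.list(distributions), length(distributions) >= 1L)
  len <- unique(lengths(distributions))
  if (length(len) != 1L) {
    stop_bnpool("all distributions must have the same length", "bnpool_input_error")
  }
  if (is.null(weights)) weights <- rep(1 / length(distributions), length(distributions))
  if (length(weights) != length(distributions) || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop_bnpool("weights must be positive, one per distribution, and sum to 1",
                "bnpool_input_error")
  }
  for (p in distributions) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_bnpool("each distribution must be non-negative and sum to 1",
                  "bnpool_input_error")
    }
  }
  out <- rep(0, len)
  for (i in seq_along(distributions)) out <- out + weights[i] * distributions[[i]]
  out / sum(out)
}

#' Prior Linear Pooling: pool the CPTs, then propagate one network
#'
#' Pools the experts' elicited probabilities *within each CPT entry*: every
#' row of every node's table in the returned network is the weighted linear
#' pool of the experts' corresponding rows. The single pooled network can
#' then be propagated directly for predictive, diagnostic or intercausal
#' queries (see [marginal()], [diagnostic_scenario()]). Note that the pooled
#' network is an average of opinions, not any one expert's coherent model:
#' the conditional independence structure among the pooled numbers is
#' imposed, not elicited.
#'
#' @param panel An [expert_panel()].
#' @return A [discrete_bn()] on the shared structure.
#' @examples
#' \dontrun{
#' pooled <- pool_prior(panel)
#' marginal(pooled, "Wayfinding")
#' }
#' @export
pool_prior <- function(panel) {
  refuse_invalid_panel(panel)
  w <- panel$weights
  ids <- expert_ids(panel)
  cps <- lapply(node_names(panel$structure), function(nd) {
    proto <- panel$experts[[ids[1L]]][[nd]]
    acc <- matrix(0, nrow(proto$prob), ncol(proto$prob))
    for (id in ids) acc <- acc + w[[id]] * panel$experts[[id]][[nd]]$prob
    acc <- acc / rowSums(acc)
    cpt(proto$child, proto$states, acc, proto$parents, proto$parent_states)
  })
  discrete_bn(cps, name = sprintf("%s (PrLP, n=%d)", panel$structure$name,
                                  n_experts(panel)))
}

refuse_invalid_panel <- function(panel) {
  report <- validate_panel(panel)
  if (nrow(report) > 0L) {
    stop_bnpool(paste0("panel fails validation:\n",
                       paste0("  - ", report$message, collapse = "\n")),
                "bnpool_validation_error")
  }
  invisible(panel)
}

new_pooled_result <- function(method, evidence, marginals, panel_label, n_experts) {
  structure(list(method = method, evidence = evidence, marginals = marginals,
                 panel_label = panel_label, n_experts = n_experts),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("<pooled result> %s, %d expert(s)%s\n", x$method, x$n_experts,
              if (nzchar(x$panel_label)) paste0(", ", x$panel_label) else ""))
  if (length(x$evidence)) {
    cat("  evidence:", paste(sprintf("%s=%s", names(x$evidence), x$evidence),
                             collapse = ", "), "\n")
  }
  print(generics::tidy(x), n = 20)
  invisible(x)
}

#' Posterior Linear Pooling: propagate each expert, then pool the marginals
#'
#' Builds one Bayesian network per expert, propagates each under the given
#' evidence, and linearly pools the resulting marginal distributions at the
#' requested target nodes with the panel weights. Pooling is performed at
#' individual nodes, never over joint distributions of several nodes, which
#' side-steps the failure of linear pools to preserve independence in
#' multivariate settings.
#'
#' If the evidence has probability zero under some expert's network that
#' expert has no posterior to contribute; by default this is an error naming
#' the expert, and with `drop_impossible = TRUE` the expert is excluded and
#' the remaining weights renormalised (with a warning).
#'
#' The panel weights are used unchanged under evidence — each expert's
#' posterior is pooled with weight `w_i` regardless of how likely the
#' evidence was under their network. Reweighting by the evidence likelihood
#' (the Bayesian-mixture posterior) is a deliberate non-behaviour; see the
#' package vignette.
#'
#' @param panel An [expert_panel()].
#' @param targets Character vector of target node names, disjoint from the
#'   evidence.
#' @param evidence Named character vector of clamped states (may be empty).
#' @param drop_impossible Drop experts for whom the evidence is impossible
#'   instead of erroring (default `FALSE`).
#' @param panel_label Free-text label stored on the result (e.g. a subgroup
#'   description).
#' @return A `pooled_result`; `tidy()` it into a tibble of
#'   `(method, node, state, prob)`.
#' @examples
#' \dontrun{
#' pool_posterior(panel, targets = "Wayfinding", evidence = c(Communication = "Effective"))
#' }
#' @export
pool_posterior <- function(panel, targets, evidence = character(),
                           drop_impossible = FALSE, panel_label = "") {
  refuse_invalid_panel(panel)
  evidence <- check_evidence(panel$structure, evidence)
  overlap <- intersect(targets, names(evidence))
  if (length(overlap)) {
    stop_bnpool(sprintf("target(s) %s appear in the evidence",
                        paste(overlap, collapse = ", ")), "bnpool_input_error")
  }
  ids <- expert_ids(panel)
  nets <- lapply(ids, function(id) expert_bn(panel, id))
  names(nets) <- ids
  per_expert <- vector("list", length(ids))
  names(per_expert) <- ids
  impossible <- character()
  for (id in ids) {
    res <- tryCatch(
      lapply(targets, function(tg) marginal(nets[[id]], tg, evidence)),
      bnpool_impossible_evidence = function(e) e)
    if (inherits(res, "condition")) {
      impossible <- c(impossible, id)
    } else {
      per_expert[[id]] <- res
    }
  }
  if (length(impossible) > 0L) {
    if (!drop_impossible) {
      stop_bnpool(sprintf("evidence is impossible for expert(s): %s (set drop_impossible = TRUE to exclude them)",
                          paste(impossible, collapse = ", ")),
                  "bnpool_impossible_evidence")
    }
    warning(sprintf("dropping %d expert(s) with impossible evidence: %s",
                    length(impossible), paste(impossible, collapse = ", ")),
            call. = FALSE)
    ids <- setdiff(ids, impossible)
    if (length(ids) == 0L) {
      stop_bnpool("evidence is impossible for every expert", "bnpool_impossible_evidence")
    }
  }
  w <- panel$weights[ids]
  w <- w / sum(w)
  marginals <- lapply(seq_along(targets), function(k) {
    tg <- targets[k]
    vecs <- lapply(ids, function(id) per_expert[[id]][[k]]$probabilities)
    pooled <- rep(0, length(vecs[[1L]]))
    for (i in seq_along(ids)) pooled <- pooled + w[[ids[i]]] * vecs[[i]]
    new_marginal(tg, stats::setNames(pooled / sum(pooled),
                                     panel$structure$nodes[[tg]]), evidence)
  })
  names(marginals) <- targets
  new_pooled_result("PoLP", evidence, marginals, panel_label, length(ids))
}

#' Pooled marginals by the prior route, as a `pooled_result`
#'
#' Convenience wrapper: [pool_prior()] then [marginal()] at each target,
#' packaged like [pool_posterior()]'s output so the two methods can be put
#' side by side.
#'
#' @inheritParams pool_posterior
#' @return A `pooled_result` with method tag `"PrLP"`.
#' @export
pool_prior_marginals <- function(panel, targets, evidence = character(),
                                 panel_label = "") {
  net <- pool_prior(panel)
  evidence <- check_evidence(net, evidence)
  marginals <- lapply(targets, function(tg) marginal(net, tg, evidence))
  names(marginals) <- targets
  new_pooled_result("PrLP", evidence, marginals, panel_label, n_experts(panel))
}

#' Compare Prior and Posterior Linear Pooling head to head
#'
#' Runs both pooling strategies on the same panel, targets and evidence and
#' tabulates them state by state with the absolute difference. The two
#' methods agree exactly when all experts are identical, and at root nodes
#' without evidence (averaging commutes with reading off a root row), but
#' genuinely diverge in general.
#'
#' @inheritParams pool_posterior
#' @return Tibble with columns `node`, `state`, `prlp`, `polp`, `abs_diff`.
#' @examples
#' \dontrun{
#' pool_compare(panel, targets = c("Wayfinding", "Communication"))
#' }
#' @export
pool_compare <- function(panel, targets, evidence = character(),
                         drop_impossible = FALSE) {
  prior <- pool_prior_marginals(panel, targets, evidence)
  post <- pool_posterior(panel, targets, evidence, drop_impossible = drop_impossible)
  a <- generics::tidy(prior)
  b <- generics::tidy(post)
  dplyr::inner_join(
    dplyr::select(a, node = "node", state = "state", prlp = "prob"),
    dplyr::select(b, node = "node", state = "state", polp = "prob"),
    by = c("node", "state")) |>
    dplyr::mutate(abs_diff = abs(.data$prlp - .data$polp))
}
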