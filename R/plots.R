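#' Boxplots of per-expert probabilities by subgroup
#'
#' Mirrors the across-expert boxplot view: one box per (node, subgroup)
#' showing the spread of the experts' propagated probabilities for the
#' reported state of each node.
#'
#' @param panel An [expert_panel()].
#' @param nodes Named character vector `node = state` (the state shown per
#'   node; for binary nodes one state carries all the information).
#' @param subgroups Named list of covariate constraints (see
#'   [filter_subgroup()]); the full panel is always shown as `"All"`.
#' @param evidence Named character vector of clamped states.
#' @return A ggplot object.
#' @export
plot_expert_spread <- function(panel, nodes, subgroups = list(),
                               evidence = character()) {
  groups <- c(list(All = NULL), subgroups)
  dat <- dplyr::bind_rows(purrr::imap(groups, function(constr, lab) {
    p <- if (is.null(constr)) panel else filter_subgroup(panel, constr)
    dplyr::bind_rows(lapply(names(nodes), function(nd) {
      vals <- per_expert_marginals(p, nd, nodes[[nd]], evidence)
      tibble::tibble(subgroup = lab, node = sprintf("%s = %s", nd, nodes[[nd]]),
                     prob = vals$prob)
    }))
  }))
  dat$subgroup <- factor(dat$subgroup, levels = names(groups))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$subgroup, y = .data$prob)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$node)) +
    ggplot2::labs(x = NULL, y = "per-expert probability") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean and standard-deviation bars of per-expert probabilities
#'
#' @param spread A tibble from [spread_report()].
#' @return A ggplot object: mean points with +/- one sample-sd bars, one
#'   panel per node, subgroups on the x axis.
#' @export
plot_spread_bars <- function(spread) {
  spread$label <- factor(spread$label, levels = unique(spread$label))
  ggplot2::ggplot(spread, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$node)) +
    ggplot2::labs(x = NULL, y = "probability (mean ± sd)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a pooled result
#'
#' Bar chart of the pooled marginal probabilities per target node.
#'
#' @param object A `pooled_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pooled_result
#' @export
autoplot.pooled_result <- function(object, ...) {
  dat <- generics::tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$state, y = .data$prob)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$node), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "pooled probability",
                  title = sprintf("%s, %d expert(s)", object$method, object$n_experts)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
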