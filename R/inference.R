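# Exact inference: factor algebra + variable elimination, and a brute-force
# enumeration oracle used in tests and for small-network sanity checks.

# A factor is a list(vars, values) where `values` is an array whose k-th
# dimension ranges over the states of vars[k] (dimnames carry the labels).
new_factor <- function(vars, states, values) {
  dims <- vapply(states, length, 1L)
  arr <- array(values, dim = dims, dimnames = states)
  list(vars = vars, values = arr)
}

factor_from_cpt <- function(cp) {
  vars <- c(cp$child, cp$parents)
  states <- c(stats::setNames(list(cp$states), cp$child), cp$parent_states)
  # prob rows enumerate parents with the LAST parent fastest; the array wants
  # its first dimension (the child) fastest, then vars in order. Build by
  # filling an array with dims (parents reversed, child) then permuting.
  if (length(cp$parents) == 0L) {
    return(new_factor(vars, states, as.vector(cp$prob[1L, ])))
  }
  rev_par <- rev(cp$parents)
  dims0 <- c(vapply(cp$parent_states[rev_par], length, 1L), length(cp$states))
  # as.vector(cp$prob) runs down columns: parent configs (last parent
  # fastest) for state 1, then state 2, ... which is exactly dims0 order
  arr0 <- array(as.vector(cp$prob), dim = dims0,
                dimnames = c(cp$parent_states[rev_par],
                             stats::setNames(list(cp$states), cp$child)))
  perm <- match(vars, c(rev_par, cp$child))
  list(vars = vars, values = aperm(arr0, perm))
}

# expand a factor's array to range over `vars` (a superset of f$vars, in the
# given order), replicating along the missing dimensions
factor_expand <- function(f, vars, states) {
  cur <- f$vars
  if (length(cur) == 0L) {
    scalar <- as.vector(f$values)
    if (length(vars) == 0L) return(scalar)
    return(array(scalar, dim = vapply(states[vars], length, 1L),
                 dimnames = states[vars]))
  }
  arr <- array(as.vector(f$values), dim = vapply(states[cur], length, 1L),
               dimnames = states[cur])
  for (v in setdiff(vars, cur)) {
    k <- length(states[[v]])
    arr <- array(rep(as.vector(arr), times = k), dim = c(dim(arr), k))
    cur <- c(cur, v)
  }
  dimnames(arr) <- states[cur]
  aperm(arr, match(vars, cur))
}

factor_product <- function(f, g, states) {
  vars <- union(f$vars, g$vars)
  list(vars = vars,
       values = factor_expand(f, vars, states) * factor_expand(g, vars, states))
}

factor_marginalize <- function(f, var) {
  k <- match(var, f$vars)
  keep <- setdiff(seq_along(f$vars), k)
  if (length(keep) == 0L) {
    return(list(vars = character(), values = sum(f$values)))
  }
  list(vars = f$vars[keep], values = apply(f$values, keep, sum))
}

factor_reduce <- function(f, var, state) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[k]] <- state
  arr <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), k)
  if (length(keep) == 0L) {
    return(list(vars = character(), values = as.vector(arr)))
  }
  dn <- dimnames(f$values)[keep]
  arr <- array(as.vector(arr), dim = dim(f$values)[keep], dimnames = dn)
  list(vars = f$vars[keep], values = arr)
}

check_evidence <- function(net, evidence) {
  evidence <- unlist(as.list(evidence))
  if (length(evidence) == 0L) return(stats::setNames(character(), character()))
  if (!is_named_character(evidence)) {
    stop_bnpool("evidence must be a named character vector, e.g. c(A = 't')",
                "bnpool_input_error")
  }
  if (anyDuplicated(names(evidence))) {
    dup <- unique(names(evidence)[duplicated(names(evidence))])
    clash <- vapply(dup, function(d) length(unique(evidence[names(evidence) == d])) > 1L, TRUE)
    if (any(clash)) {
      stop_bnpool(sprintf("conflicting evidence for node(s): %s",
                          paste(dup[clash], collapse = ", ")), "bnpool_input_error")
    }
    evidence <- evidence[!duplicated(names(evidence))]
  }
  for (nd in names(evidence)) {
    if (!nd %in% node_names(net)) {
      stop_bnpool(sprintf("evidence names unknown node '%s'", nd), "bnpool_input_error")
    }
    if (!evidence[[nd]] %in% net$nodes[[nd]]) {
      stop_bnpool(sprintf("'%s' is not a state of node '%s'", evidence[[nd]], nd),
                  "bnpool_input_error")
    }
  }
  evidence
}

# min-degree elimination order over the factor interaction graph,
# lexicographic tie-break; deterministic for fixed input
elimination_order <- function(scopes, to_eliminate) {
  adj <- stats::setNames(vector("list", length(to_eliminate)), to_eliminate)
  for (v in to_eliminate) {
    nb <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, TRUE)]))
    adj[[v]] <- setdiff(nb, v)
  }
  order_out <- character()
  remaining <- sort(to_eliminate)
  while (length(remaining) > 0L) {
    degs <- vapply(remaining, function(v) length(intersect(adj[[v]], remaining)), 1L)
    v <- remaining[which(degs == min(degs))[1L]]  # remaining is sorted
    nb <- intersect(adj[[v]], remaining)
    for (u in nb) adj[[u]] <- union(adj[[u]], setdiff(nb, u))
    order_out <- c(order_out, v)
    remaining <- setdiff(remaining, v)
  }
  order_out
}

#' Probability of a complete assignment
#'
#' The joint probability of a full instantiation of the network, computed as
#' the product over nodes of the CPT entry selected by the assignment — the
#' factorisation that defines a Bayesian network.
#'
#' @param net A [discrete_bn()] object.
#' @param assignment Named character vector mapping *every* node to one of
#'   its states.
#' @return A single probability.
#' @examples
#' net <- discrete_bn(list(
#'   cpt("A", c("t", "f"), prob = c(0.8, 0.2)),
#'   cpt("B", c("t", "f"), parents = "A",
#'       parent_states = list(A = c("t", "f")),
#'       prob = rbind(c(0.9, 0.1), c(0.2, 0.8)))))
#' joint_probability(net, c(A = "t", B = "t"))  # 0.72
#' @export
joint_probability <- function(net, assignment) {
  assignment <- unlist(as.list(assignment))
  miss <- setdiff(node_names(net), names(assignment))
  if (length(miss) > 0L) {
    stop_bnpool(sprintf("assignment misses node(s): %s", paste(miss, collapse = ", ")),
                "bnpool_input_error")
  }
  p <- 1
  for (nd in node_names(net)) {
    k <- match(assignment[[nd]], net$nodes[[nd]])
    if (is.na(k)) {
      stop_bnpool(sprintf("'%s' is not a state of node '%s'", assignment[[nd]], nd),
                  "bnpool_input_error")
    }
    p <- p * cpt_row(net$cpts[[nd]], assignment)[k]
  }
  unname(p)
}

#' Exact conditional marginal of one node
#'
#' Computes `P(target | evidence)` exactly by variable elimination
#' (min-degree elimination order with lexicographic tie-break, so the
#' computation is deterministic). Equivalent to renormalising the sum of
#' [joint_probability()] over all completions consistent with the evidence,
#' which is how the test-suite oracle checks it.
#'
#' @param net A [discrete_bn()] object.
#' @param target Node name to query; must not appear in the evidence.
#' @param evidence Named character vector of clamped states (may be empty).
#'   Clamping a node to a state with zero probability raises an
#'   `bnpool_impossible_evidence` error carrying `p_evidence`.
#' @return A `marginal` object: the probability vector aligned to the
#'   target's state order, with the node name and evidence attached.
#'   `as_tibble()` yields columns `node`, `state`, `prob`.
#' @examples
#' net <- discrete_bn(list(
#'   cpt("A", c("t", "f"), prob = c(0.8, 0.2)),
#'   cpt("B", c("t", "f"), parents = "A",
#'       parent_states = list(A = c("t", "f")),
#'       prob = rbind(c(0.9, 0.1), c(0.2, 0.8)))))
#' marginal(net, "B")                    # P(B = t) = 0.76
#' marginal(net, "A", c(B = "t"))        # P(A = t | B = t) = 0.72/0.76
#' @export
marginal <- function(net, target, evidence = character()) {
  if (!target %in% node_names(net)) {
    stop_bnpool(sprintf("unknown target node '%s'", target), "bnpool_input_error")
  }
  evidence <- check_evidence(net, evidence)
  if (target %in% names(evidence)) {
    stop_bnpool(sprintf("target '%s' appears in the evidence", target),
                "bnpool_input_error")
  }
  states <- net$nodes
  factors <- lapply(net$cpts, factor_from_cpt)
  for (nd in names(evidence)) {
    factors <- lapply(factors, factor_reduce, var = nd, state = evidence[[nd]])
  }
  to_elim <- setdiff(node_names(net), c(target, names(evidence)))
  ord <- elimination_order(lapply(factors, `[[`, "vars"), to_elim)
  for (v in ord) {
    touches <- vapply(factors, function(f) v %in% f$vars, TRUE)
    if (!any(touches)) next
    prod_f <- Reduce(function(a, b) factor_product(a, b, states), factors[touches])
    factors <- c(factors[!touches], list(factor_marginalize(prod_f, v)))
  }
  res <- Reduce(function(a, b) factor_product(a, b, states), factors)
  if (!identical(sort(res$vars), sort(target))) {
    # constant factors (fully reduced) multiply in via factor_product already;
    # anything else left over is a bug
    stop("internal error: variable elimination left unexpected scope")
  }
  vec <- as.vector(factor_expand(res, target, states))
  z <- sum(vec)
  if (z <= 0) {
    rlang::abort(sprintf("impossible evidence: P(%s) = %g",
                         paste(sprintf("%s=%s", names(evidence), evidence), collapse = ", "),
                         z),
                 class = c("bnpool_impossible_evidence", "bnpool_error"),
                 p_evidence = z)
  }
  new_marginal(target, stats::setNames(vec / z, net$nodes[[target]]), evidence)
}

new_marginal <- function(node, probabilities, evidence) {
  structure(list(node = node, probabilities = probabilities, evidence = evidence),
            class = "marginal")
}

#' @export
print.marginal <- function(x, ...) {
  ev <- if (length(x$evidence))
    paste0(" | ", paste(sprintf("%s=%s", names(x$evidence), x$evidence), collapse = ", "))
  else ""
  cat(sprintf("<marginal> P(%s%s)\n", x$node, ev))
  print(round(x$probabilities, 6))
  invisible(x)
}

#' @method as_tibble marginal
#' @export
as_tibble.marginal <- function(x, ...) {
  tibble::tibble(node = x$node, state = names(x$probabilities),
                 prob = unname(x$probabilities))
}

#' Brute-force enumeration of the full joint distribution
#'
#' Enumerates every complete assignment of the network and its
#' [joint_probability()]. This is the independent oracle against which the
#' variable-elimination path is verified; it is only feasible for small
#' networks, so the joint size is capped.
#'
#' @param net A [discrete_bn()] object.
#' @param cap Maximum number of joint configurations (default `2^20`);
#'   exceeding it is an error reporting the required size.
#' @return Tibble with one column per node (state labels) plus `prob`;
#'   the `prob` column sums to 1. Rows enumerate nodes in declaration order
#'   with the last node varying fastest.
#' @export
enumerate_joint <- function(net, cap = 2^20) {
  sizes <- vapply(net$nodes, length, 1L)
  total <- prod(sizes)
  if (total > cap) {
    stop_bnpool(sprintf("joint table needs %.0f entries, above the cap of %.0f",
                        total, cap), "bnpool_input_error")
  }
  grid <- parent_config_grid(net$nodes)
  prob <- rep(1, nrow(grid))
  for (nd in node_names(net)) {
    cp <- net$cpts[[nd]]
    col <- match(grid[[nd]], cp$states)
    if (length(cp$parents) == 0L) {
      row <- rep(1L, nrow(grid))
    } else {
      sizes_p <- vapply(cp$parent_states, length, 1L)
      pos <- vapply(cp$parents, function(p) match(grid[[p]], cp$parent_states[[p]]),
                    integer(nrow(grid)))
      pos <- matrix(pos, nrow = nrow(grid))
      row <- rep(1L, nrow(grid))
      idx <- rep(0, nrow(grid))
      for (j in seq_along(sizes_p)) idx <- idx * sizes_p[j] + (pos[, j] - 1L)
      row <- as.integer(idx + 1L)
    }
    prob <- prob * cp$prob[cbind(row, col)]
  }
  dplyr::bind_cols(grid, tibble::tibble(prob = prob))
}

# oracle marginal from the enumerated joint (used by tests and properties)
marginal_from_joint <- function(joint, target, evidence = character()) {
  keep <- rep(TRUE, nrow(joint))
  for (nd in names(evidence)) keep <- keep & joint[[nd]] == evidence[[nd]]
  sub <- joint[keep, , drop = FALSE]
  z <- sum(sub$prob)
  if (z <= 0) {
    rlang::abort("impossible evidence in oracle",
                 class = c("bnpool_impossible_evidence", "bnpool_error"),
                 p_evidence = z)
  }
  tapply(sub$prob, sub[[target]], sum) / z
}
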