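#' Discrete Bayesian network
#'
#' Builds a discrete Bayesian network from a list of [cpt()] objects, one per
#' node. The directed edge set is derived from each table's declared parents;
#' the joint distribution of the network is the product over nodes of
#' `P(node | parents)`. Node order is the order of the supplied tables and is
#' preserved through serialisation round-trips.
#'
#' With `check = TRUE` (the default) the candidate network is passed through
#' [validate_network()]: rows whose sum deviates from 1 by more than 1e-9 but
#' at most 1e-6 are renormalised with a warning (elicited probabilities are
#' typically rounded to a few decimals); any larger deviation, a cycle, or an
#' inconsistent state space is an error citing the validation report.
#'
#' @param cpts List of [cpt()] objects, one per node.
#' @param name Network name (used by the file writers).
#' @param check Validate (and possibly renormalise) the network. Set to
#'   `FALSE` only to build a deliberately invalid candidate for inspection
#'   with [validate_network()].
#'
#' @return An object of class `bn` with elements `nodes` (named list of state
#'   vectors), `parents` (named list), `cpts` (named list of `cpt`) and
#'   `name`.
#'
#' @examples
#' net <- discrete_bn(list(
#'   cpt("A", c("t", "f"), prob = c(0.8, 0.2)),
#'   cpt("B", c("t", "f"), parents = "A",
#'       parent_states = list(A = c("t", "f")),
#'       prob = rbind(c(0.9, 0.1), c(0.2, 0.8)))))
#' net
#' topological_order(net)
#' @export
discrete_bn <- function(cpts, name = "network", check = TRUE) {
  if (inherits(cpts, "cpt")) cpts <- list(cpts)
  stopifnot(is.list(cpts), all(vapply(cpts, inherits, TRUE, "cpt")))
  children <- vapply(cpts, `[[`, "", "child")
  if (anyDuplicated(children)) {
    stop_bnpool(sprintf("duplicate CPT for node(s): %s",
                        paste(unique(children[duplicated(children)]), collapse = ", ")),
                "bnpool_structure_error")
  }
  names(cpts) <- children
  net <- structure(
    list(nodes = lapply(cpts, `[[`, "states"),
         parents = lapply(cpts, `[[`, "parents"),
         cpts = cpts,
         name = name),
    class = "bn")
  if (check) {
    report <- validate_network(net)
    fixable <- report$violation == "row_sum" &
      abs(report$detail_num) <= 1e-6
    if (any(fixable)) {
      for (k in which(fixable)) {
        nd <- report$node[k]
        i <- report$row[k]
        net$cpts[[nd]]$prob[i, ] <-
          net$cpts[[nd]]$prob[i, ] / sum(net$cpts[[nd]]$prob[i, ])
      }
      warning(sprintf("renormalised %d CPT row(s) with |sum - 1| <= 1e-6",
                      sum(fixable)), call. = FALSE)
      report <- report[!fixable, , drop = FALSE]
    }
    if (nrow(report) > 0L) {
      stop_bnpool(
        paste0("invalid network:\n",
               paste0("  - ", report$message, collapse = "\n")),
        "bnpool_validation_error")
    }
  }
  net
}

node_names <- function(net) names(net$nodes)

#' @export
print.bn <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("<discrete Bayesian network '%s'>\n  %d nodes, %d edges\n",
              x$name, length(x$nodes), n_edges))
  for (nd in node_names(x)) {
    cat(sprintf("  %s [%s]%s\n", nd, paste(x$nodes[[nd]], collapse = "/"),
                if (length(x$parents[[nd]]))
                  paste0(" <- ", paste(x$parents[[nd]], collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Edge list of a network
#'
#' @param net A [discrete_bn()] object.
#' @return Tibble with columns `from`, `to`, one row per directed edge.
#' @export
bn_edges <- function(net) {
  rows <- purrr::imap(net$parents, function(ps, child) {
    if (length(ps) == 0L) return(NULL)
    tibble::tibble(from = ps, to = child)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) tibble::tibble(from = character(), to = character()) else out
}

#' Validate a candidate discrete Bayesian network
#'
#' Reports every violation of the network invariants: unique non-empty state
#' labels (at least two per node), parents that exist and quote their
#' parents' true state spaces, complete CPTs (one row per parent
#' configuration), rows that are probability distributions (entries in
#' `[0, 1]`, sum within 1e-9 of 1), and acyclicity. A valid network yields a
#' zero-row report. This function never throws: it is the reporting half of
#' the contract, and the constructors/operations refuse networks whose
#' report is non-empty.
#'
#' @param net A `bn` object (possibly built with `check = FALSE`).
#' @return Tibble with columns `node`, `row` (CPT row index or `NA`),
#'   `violation` (machine-readable tag), `detail_num` (e.g. the offending row
#'   sum deviation) and `message`.
#' @export
validate_network <- function(net) {
  bad <- list()
  add <- function(node, row, violation, detail_num, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      node = node, row = row, violation = violation,
      detail_num = detail_num, message = message)
  }
  for (nd in node_names(net)) {
    st <- net$nodes[[nd]]
    if (length(st) < 2L) {
      add(nd, NA_integer_, "state_count", NA_real_,
          sprintf("node '%s' has %d state(s); at least 2 required", nd, length(st)))
    }
    if (anyDuplicated(st) || any(!nzchar(st))) {
      add(nd, NA_integer_, "state_labels", NA_real_,
          sprintf("node '%s' has duplicate or empty state labels", nd))
    }
    cp <- net$cpts[[nd]]
    for (p in cp$parents) {
      if (!p %in% node_names(net)) {
        add(nd, NA_integer_, "unknown_parent", NA_real_,
            sprintf("node '%s' declares unknown parent '%s'", nd, p))
      } else if (!identical(cp$parent_states[[p]], net$nodes[[p]])) {
        add(nd, NA_integer_, "parent_states", NA_real_,
            sprintf("node '%s' quotes states of parent '%s' that differ from its declaration",
                    nd, p))
      }
    }
    for (i in seq_len(nrow(cp$prob))) {
      row <- cp$prob[i, ]
      if (any(row < 0 | row > 1)) {
        add(nd, i, "range", NA_real_,
            sprintf("CPT of '%s', row %d: entries outside [0, 1]", nd, i))
      }
      dev <- sum(row) - 1
      if (abs(dev) > 1e-9) {
        add(nd, i, "row_sum", dev,
            sprintf("CPT of '%s', row %d: row sum %.10g != 1", nd, i, sum(row)))
      }
    }
  }
  cyc <- find_cycle(net$parents)
  if (!is.null(cyc)) {
    add(NA_character_, NA_integer_, "cycle", NA_real_,
        sprintf("cycle detected through edge %s -> %s", cyc[1], cyc[2]))
  }
  if (length(bad) == 0L) {
    tibble::tibble(node = character(), row = integer(), violation = character(),
                   detail_num = double(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

# returns c(parent, child) on some cycle, or NULL if the graph is acyclic
find_cycle <- function(parents) {
  nodes <- names(parents)
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  hit <- NULL
  visit <- function(v) {
    if (!is.null(hit)) return()
    state[[v]] <<- 1L
    for (p in parents[[v]]) {
      if (!p %in% nodes) next
      if (state[[p]] == 1L) { hit <<- c(p, v); return() }
      if (state[[p]] == 0L) visit(p)
      if (!is.null(hit)) return()
    }
    state[[v]] <<- 2L
  }
  for (v in nodes) if (state[[v]] == 0L) visit(v)
  hit
}

#' Topological order of a network's nodes
#'
#' Deterministic Kahn ordering: every parent precedes its children, and among
#' simultaneously available nodes ties are broken lexicographically by node
#' name, so the result does not depend on the insertion order of nodes or
#' edges.
#'
#' @param net A valid `bn` object.
#' @return Character vector of node names.
#' @export
topological_order <- function(net) {
  cyc <- find_cycle(net$parents)
  if (!is.null(cyc)) {
    stop_bnpool(sprintf("network is cyclic (edge %s -> %s lies on a cycle)",
                        cyc[1], cyc[2]), "bnpool_structure_error")
  }
  remaining <- sort(node_names(net))
  placed <- character()
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(v) {
      all(intersect(net$parents[[v]], node_names(net)) %in% placed)
    }, TRUE)]
    nxt <- ready[1L]  # `remaining` is sorted, so this is the lexicographic min
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  placed
}
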