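#' Conditional probability table for one node
#'
#' A `cpt` quantifies one categorical node given the joint state of its
#' parents: the table holds one probability row per parent configuration
#' (a single row when the node has no parents), each row a distribution over
#' the node's own states. Rows are kept in a canonical order in which the
#' *last* declared parent varies fastest; this fixes a bit-exact layout used
#' by all readers, writers and pooling operations.
#'
#' @param child Node name (non-empty string).
#' @param states Character vector of the node's state labels, length >= 2,
#'   unique, order-significant. Labels are case-sensitive exact strings, so
#'   `"Good"` and `"good"` are different states.
#' @param prob Numeric matrix with one column per state of `child` and one
#'   row per parent configuration in canonical order (a 1-row matrix, or a
#'   plain vector, for a root node). Rows are expected to be probability
#'   distributions; normalisation is enforced by [validate_network()] and the
#'   [discrete_bn()] constructor, not here, so that candidate tables can be
#'   inspected for violations.
#' @param parents Character vector of parent node names in declared order
#'   (default none).
#' @param parent_states Named list giving the state labels of each parent,
#'   in the same order as `parents`.
#'
#' @return An object of class `cpt`.
#'
#' @examples
#' # root node
#' a <- cpt("A", c("t", "f"), prob = c(0.8, 0.2))
#' # child with one binary parent: rows are the parent's states in order
#' b <- cpt("B", c("t", "f"), parents = "A",
#'          parent_states = list(A = c("t", "f")),
#'          prob = rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' as_tibble(b)
#' @export
cpt <- function(child, states, prob, parents = character(),
                parent_states = list()) {
  stopifnot(is.character(child), length(child) == 1L, nzchar(child))
  states <- as.character(states)
  parents <- as.character(parents)
  if (length(parents) == 0L) parent_states <- list()
  if (length(parents) != length(parent_states) ||
      (length(parents) > 0L && !identical(names(parent_states), parents))) {
    stop_bnpool(
      sprintf("cpt(%s): `parent_states` must be a named list aligned to `parents`",
              child),
      "bnpool_input_error")
  }
  if (is.vector(prob) && is.numeric(prob)) prob <- matrix(prob, nrow = 1L)
  prob <- as.matrix(prob)
  storage.mode(prob) <- "double"
  n_rows <- prod(vapply(parent_states, length, 1L))
  if (ncol(prob) != length(states) || nrow(prob) != n_rows) {
    stop_bnpool(
      sprintf("cpt(%s): `prob` must be %d x %d (parent configurations x states), got %d x %d",
              child, n_rows, length(states), nrow(prob), ncol(prob)),
      "bnpool_input_error")
  }
  dimnames(prob) <- list(NULL, states)
  structure(
    list(child = child, states = states, parents = parents,
         parent_states = parent_states, prob = prob),
    class = "cpt")
}

#' @export
print.cpt <- function(x, ...) {
  cat(sprintf("<cpt> P(%s%s)\n", x$child,
              if (length(x$parents)) paste0(" | ", paste(x$parents, collapse = ", ")) else ""))
  print(as_tibble(x), n = 12)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble cpt
#' @export
as_tibble.cpt <- function(x, ...) {
  grid <- parent_config_grid(x$parent_states)
  grid <- grid[rep(seq_len(nrow(x$prob)), each = length(x$states)),
               , drop = FALSE]
  out <- tibble::tibble(
    node = x$child,
    state = rep(x$states, times = nrow(x$prob)),
    prob = as.vector(t(x$prob)))
  dplyr::bind_cols(tibble::tibble(node = out$node), grid,
                   out[c("state", "prob")])
}

# probability row for one parent assignment (named character of parent states)
cpt_row <- function(cp, assignment) {
  if (length(cp$parents) == 0L) return(cp$prob[1L, ])
  pos <- integer(length(cp$parents))
  for (j in seq_along(cp$parents)) {
    p <- cp$parents[j]
    pos[j] <- match(assignment[[p]], cp$parent_states[[p]])
    if (is.na(pos[j])) {
      stop_bnpool(sprintf("state '%s' is not a state of node '%s'",
                          assignment[[p]], p), "bnpool_input_error")
    }
  }
  sizes <- vapply(cp$parent_states, length, 1L)
  cp$prob[config_row_index(sizes, pos), ]
}
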