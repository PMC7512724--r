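# internal helpers shared across modules

# canonical enumeration of parent configurations: the LAST parent varies
# fastest, so for parents (A, B) the rows are (a1,b1), (a1,b2), (a2,b1), ...
parent_config_grid <- function(parent_states) {
  if (length(parent_states) == 0L) {
    return(tibble::tibble(.rows = 1L))
  }
  grid <- expand.grid(rev(parent_states),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(grid[, rev(seq_along(parent_states)), drop = FALSE])
}

# row index of one parent configuration in canonical order; `positions` are
# 1-based state positions aligned to the declared parent order
config_row_index <- function(sizes, positions) {
  if (length(sizes) == 0L) return(1L)
  idx <- 0L
  for (j in seq_along(sizes)) idx <- idx * sizes[j] + (positions[j] - 1L)
  idx + 1L
}

# fixed float formatting used by every writer (17 significant digits keeps
# doubles bit-stable across write -> read)
format_prob <- function(x) sprintf("%.17g", x)

is_named_character <- function(x) {
  is.character(x) && (length(x) == 0L || !is.null(names(x)))
}

stop_bnpool <- function(msg, class) {
  rlang::abort(msg, class = c(class, "bnpool_error"))
}
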