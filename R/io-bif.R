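# Classic Bayesian Interchange Format (BIF) reader/writer.
# Dialect: `network`, `variable` (type discrete), `probability` blocks;
# root tables as `table p1, p2, ...;`, conditional tables as one
# `( parent states ) p1, p2;` line per parent configuration in canonical
# order (last declared parent fastest). Identifiers are [A-Za-z_][A-Za-z0-9_]*,
# so node/state names containing spaces cannot be written to BIF (use XMLBIF
# or the panel JSON schema for those).

bif_identifier_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)

check_bif_names <- function(net) {
  all_names <- c(node_names(net), unlist(net$nodes, use.names = FALSE))
  bad <- all_names[!vapply(all_names, bif_identifier_ok, TRUE)]
  if (length(bad) > 0L) {
    stop_bnpool(
      sprintf("BIF identifiers may only contain letters, digits and '_'; offending name(s): %s. Use XMLBIF for such networks.",
              paste(unique(bad), collapse = ", ")),
      "bnpool_io_error")
  }
}

write_bif <- function(net, path) {
  check_bif_names(net)
  out <- c(sprintf("network %s {",
                   if (bif_identifier_ok(net$name)) net$name
                   else gsub("[^A-Za-z0-9_]", "_", net$name)),
           "}")
  for (nd in node_names(net)) {
    st <- net$nodes[[nd]]
    out <- c(out,
             sprintf("variable %s {", nd),
             sprintf("  type discrete [ %d ] { %s };", length(st),
                     paste(st, collapse = ", ")),
             "}")
  }
  for (nd in node_names(net)) {
    cp <- net$cpts[[nd]]
    if (length(cp$parents) == 0L) {
      out <- c(out,
               sprintf("probability ( %s ) {", nd),
               sprintf("  table %s;", paste(format_prob(cp$prob[1L, ]), collapse = ", ")),
               "}")
    } else {
      grid <- parent_config_grid(cp$parent_states)
      lines <- vapply(seq_len(nrow(grid)), function(r) {
        sprintf("  ( %s ) %s;",
                paste(unlist(grid[r, ]), collapse = ", "),
                paste(format_prob(cp$prob[r, ]), collapse = ", "))
      }, "")
      out <- c(out,
               sprintf("probability ( %s | %s ) {", nd,
                       paste(cp$parents, collapse = ", ")),
               lines,
               "}")
    }
  }
  writeLines(out, path)
  invisible(path)
}

bif_tokenize <- function(text) {
  text <- gsub("//[^\n]*", " ", text)
  text <- gsub("/\\*.*?\\*/", " ", text, perl = TRUE)
  m <- gregexpr("[A-Za-z_][A-Za-z0-9_.-]*|[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?|[{}()|,;\\[\\]=]",
                text, perl = TRUE)
  regmatches(text, m)[[1L]]
}

bif_parse_error <- function(path, msg) {
  stop_bnpool(sprintf("BIF parse error in '%s': %s", path, msg), "bnpool_io_error")
}

read_bif <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  toks <- bif_tokenize(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  nxt <- function() { t <- peek(); i <<- i + 1L; t }
  expect <- function(t) {
    got <- nxt()
    if (!identical(got, t)) bif_parse_error(path, sprintf("expected '%s', got '%s'", t, got))
    got
  }
  skip_block <- function() {  # consume a balanced { ... }
    expect("{")
    depth <- 1L
    while (depth > 0L) {
      t <- nxt()
      if (is.na(t)) bif_parse_error(path, "unbalanced '{'")
      if (t == "{") depth <- depth + 1L
      if (t == "}") depth <- depth - 1L
    }
  }
  name <- "network"
  states <- list()
  cpt_specs <- list()
  while (!is.na(peek())) {
    kw <- nxt()
    if (kw == "network") {
      name <- nxt()
      skip_block()
    } else if (kw == "variable") {
      var <- nxt()
      expect("{")
      expect("type"); expect("discrete"); expect("[")
      k <- as.integer(nxt())
      expect("]"); expect("{")
      st <- character()
      repeat {
        st <- c(st, nxt())
        t <- nxt()
        if (t == "}") break
        if (t != ",") bif_parse_error(path, sprintf("bad state list for '%s'", var))
      }
      expect(";")
      expect("}")
      if (length(st) != k) {
        bif_parse_error(path, sprintf("variable '%s' declares %d states but lists %d",
                                      var, k, length(st)))
      }
      states[[var]] <- st
    } else if (kw == "probability") {
      expect("(")
      child <- nxt()
      parents <- character()
      t <- nxt()
      if (t == "|") {
        repeat {
          parents <- c(parents, nxt())
          t <- nxt()
          if (t == ")") break
          if (t != ",") bif_parse_error(path, sprintf("bad parent list for '%s'", child))
        }
      } else if (t != ")") {
        bif_parse_error(path, sprintf("bad probability header for '%s'", child))
      }
      expect("{")
      rows <- list()
      flat <- NULL
      repeat {
        t <- nxt()
        if (t == "}") break
        if (t == "table") {
          vals <- numeric()
          repeat {
            vals <- c(vals, as.numeric(nxt()))
            t2 <- nxt()
            if (t2 == ";") break
            if (t2 != ",") bif_parse_error(path, sprintf("bad table for '%s'", child))
          }
          flat <- vals
        } else if (t == "(") {
          cfg <- character()
          repeat {
            cfg <- c(cfg, nxt())
            t2 <- nxt()
            if (t2 == ")") break
            if (t2 != ",") bif_parse_error(path, sprintf("bad row header for '%s'", child))
          }
          vals <- numeric()
          repeat {
            vals <- c(vals, as.numeric(nxt()))
            t2 <- nxt()
            if (t2 == ";") break
            if (t2 != ",") bif_parse_error(path, sprintf("bad row for '%s'", child))
          }
          rows[[length(rows) + 1L]] <- list(cfg = cfg, vals = vals)
        } else {
          bif_parse_error(path, sprintf("unexpected token '%s' in probability block of '%s'",
                                        t, child))
        }
      }
      cpt_specs[[child]] <- list(parents = parents, rows = rows, flat = flat)
    } else {
      bif_parse_error(path, sprintf("unexpected token '%s'", kw))
    }
  }
  build_net_from_specs(name, states, cpt_specs, path)
}

build_net_from_specs <- function(name, states, cpt_specs, path) {
  ghost <- setdiff(names(cpt_specs), names(states))
  if (length(ghost) > 0L) {
    stop_bnpool(sprintf("'%s': probability block for undeclared node(s): %s", path,
                        paste(ghost, collapse = ", ")), "bnpool_io_error")
  }
  miss <- setdiff(names(states), names(cpt_specs))
  if (length(miss) > 0L) {
    stop_bnpool(sprintf("'%s': no probability block for node(s): %s", path,
                        paste(miss, collapse = ", ")), "bnpool_io_error")
  }
  cps <- lapply(names(states), function(nd) {
    spec <- cpt_specs[[nd]]
    if (is.null(spec)) {
      stop_bnpool(sprintf("'%s': probability block for undeclared node '%s'", path, nd),
                  "bnpool_io_error")
    }
    for (p in spec$parents) {
      if (!p %in% names(states)) {
        stop_bnpool(sprintf("'%s': node '%s' has undeclared parent '%s'", path, nd, p),
                    "bnpool_io_error")
      }
    }
    pst <- stats::setNames(states[spec$parents], spec$parents)
    n_rows <- prod(vapply(pst, length, 1L))
    k <- length(states[[nd]])
    prob <- matrix(NA_real_, n_rows, k)
    if (!is.null(spec$flat)) {
      if (length(spec$flat) != n_rows * k) {
        stop_bnpool(sprintf("'%s': table for '%s' has %d values, expected %d",
                            path, nd, length(spec$flat), n_rows * k), "bnpool_io_error")
      }
      prob <- matrix(spec$flat, n_rows, k, byrow = TRUE)
    }
    grid <- parent_config_grid(pst)
    for (rw in spec$rows) {
      if (length(rw$cfg) != length(spec$parents) || length(rw$vals) != k) {
        stop_bnpool(sprintf("'%s': malformed row for '%s'", path, nd), "bnpool_io_error")
      }
      hit <- rep(TRUE, n_rows)
      for (j in seq_along(spec$parents)) hit <- hit & grid[[j]] == rw$cfg[j]
      if (sum(hit) != 1L) {
        stop_bnpool(sprintf("'%s': row (%s) of '%s' matches %d configurations",
                            path, paste(rw$cfg, collapse = ","), nd, sum(hit)),
                    "bnpool_io_error")
      }
      prob[which(hit), ] <- rw$vals
    }
    if (anyNA(prob)) {
      stop_bnpool(sprintf("'%s': CPT of '%s' is incomplete", path, nd), "bnpool_io_error")
    }
    cpt(nd, states[[nd]], prob, spec$parents, pst)
  })
  discrete_bn(cps, name = name)
}
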