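#' Read or write a discrete Bayesian network file
#'
#' Dispatches on format: classic BIF (`.bif`) or XMLBIF 0.3 (`.xml`,
#' `.xmlbif`). Both writers emit canonical, byte-stable output (fixed
#' ordering, probabilities at 17 significant digits), so writing the same
#' network twice gives byte-identical files and write -> read is
#' value-identical. The reader validates on load: malformed files raise an
#' `bnpool_io_error` with file context, and structurally parsed networks
#' whose CPT rows fail normalisation are rejected citing the offending row.
#'
#' @param path File path.
#' @param format `"bif"`, `"xmlbif"`, or `NULL` to guess from the extension.
#' @param net A [discrete_bn()] object (for the writer).
#' @return `read_network()`: a valid `bn`; `write_network()`: the path,
#'   invisibly.
#' @export
read_network <- function(path, format = NULL) {
  format <- resolve_format(path, format)
  switch(format, bif = read_bif(path), xmlbif = read_xmlbif(path))
}

#' @rdname read_network
#' @export
write_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "bn"))
  format <- resolve_format(path, format)
  switch(format, bif = write_bif(net, path), xmlbif = write_xmlbif(net, path))
  invisible(path)
}

resolve_format <- function(path, format) {
  if (!is.null(format)) {
    format <- match.arg(format, c("bif", "xmlbif"))
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "bif") "bif"
  else if (ext %in% c("xml", "xmlbif")) "xmlbif"
  else stop_bnpool(sprintf("cannot guess network format from '%s'; pass `format`", path),
                   "bnpool_io_error")
}

# ---- panel JSON schema ------------------------------------------------------
# {
#   "format": "bnpool-panel", "version": 1,
#   "structure": {"name": ..., "nodes": [{"name","states"}...],
#                 "parents": {node: [parents]}},
#   "experts": [{"id": ..., "cpts": {node: [[row], ...]}}],   (canonical rows)
#   "covariates": [{"expert_id": ..., <covariate>: <category>}, ...],
#   "weights": {id: w}          (optional; equal weights assumed if absent)
# }

#' Read or write an expert panel as JSON
#'
#' The panel schema stores the shared structure once (nodes with ordered
#' states, parent lists), then each expert's CPT rows in canonical order
#' (last parent fastest), the covariate table, and optionally the pooling
#' weights — a panel without a weights block gets equal weights on read.
#' Output is canonical and byte-stable; probabilities keep full double
#' precision, so write -> read is value-identical.
#'
#' @param path File path.
#' @param panel An [expert_panel()] (for the writer).
#' @return `read_panel()`: a validated `expert_panel`; `write_panel()`: the
#'   path, invisibly.
#' @export
read_panel <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_bnpool(sprintf("panel JSON parse error in '%s': %s",
                                        path, conditionMessage(e)), "bnpool_io_error")
                  })
  if (!identical(obj$format, "bnpool-panel")) {
    stop_bnpool(sprintf("'%s' is not a bnpool panel file", path), "bnpool_io_error")
  }
  st <- obj$structure
  states <- list()
  for (nd in st$nodes) states[[nd$name]] <- unlist(nd$states)
  parents <- lapply(st$parents, function(p) as.character(unlist(p)))
  parents <- parents[names(states)]
  skeleton_cpts <- lapply(names(states), function(nd) {
    ps <- parents[[nd]]
    pst <- stats::setNames(states[ps], ps)
    n_rows <- prod(vapply(pst, length, 1L))
    k <- length(states[[nd]])
    cpt(nd, states[[nd]], matrix(1 / k, n_rows, k), ps, pst)
  })
  skeleton <- discrete_bn(skeleton_cpts, name = st$name %||% "network")
  experts <- list()
  for (ex in obj$experts) {
    cps <- lapply(names(states), function(nd) {
      rows <- ex$cpts[[nd]]
      if (is.null(rows)) {
        stop_bnpool(sprintf("'%s': expert '%s' lacks a CPT for node '%s'",
                            path, ex$id, nd), "bnpool_io_error")
      }
      prob <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
      ps <- parents[[nd]]
      cpt(nd, states[[nd]], prob, ps, stats::setNames(states[ps], ps))
    })
    names(cps) <- names(states)
    experts[[as.character(ex$id)]] <- cps
  }
  covariates <- NULL
  if (!is.null(obj$covariates)) {
    covariates <- dplyr::bind_rows(lapply(obj$covariates, function(row) {
      tibble::as_tibble(lapply(row, function(x) if (is.null(x)) NA_character_ else as.character(x)))
    }))
  }
  weights <- NULL
  if (!is.null(obj$weights)) {
    weights <- unlist(obj$weights)
  }
  expert_panel(skeleton, experts, covariates = covariates, weights = weights)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "expert_panel"))
  skel <- panel$structure
  esc <- function(x) gsub('"', '\\\\"', x)
  j_str <- function(x) sprintf('"%s"', esc(x))
  j_arr <- function(xs) sprintf("[%s]", paste(xs, collapse = ", "))
  nodes_json <- j_arr(vapply(node_names(skel), function(nd) {
    sprintf('{"name": %s, "states": %s}', j_str(nd),
            j_arr(j_str(skel$nodes[[nd]])))
  }, ""))
  parents_json <- sprintf("{%s}", paste(vapply(node_names(skel), function(nd) {
    sprintf("%s: %s", j_str(nd), j_arr(j_str(skel$parents[[nd]])))
  }, ""), collapse = ", "))
  experts_json <- j_arr(vapply(expert_ids(panel), function(id) {
    cps <- panel$experts[[id]]
    cpts_json <- paste(vapply(node_names(skel), function(nd) {
      rows <- apply(cps[[nd]]$prob, 1L, function(r) j_arr(format_prob(r)))
      sprintf("%s: %s", j_str(nd), j_arr(rows))
    }, ""), collapse = ", ")
    sprintf('{"id": %s, "cpts": {%s}}', j_str(id), cpts_json)
  }, ""))
  cov <- panel$covariates
  cov_json <- j_arr(vapply(seq_len(nrow(cov)), function(i) {
    fields <- vapply(names(cov), function(cn) {
      v <- cov[[cn]][i]
      sprintf("%s: %s", j_str(cn), if (is.na(v)) "null" else j_str(as.character(v)))
    }, "")
    sprintf("{%s}", paste(fields, collapse = ", "))
  }, ""))
  weights_json <- sprintf("{%s}", paste(vapply(expert_ids(panel), function(id) {
    sprintf("%s: %s", j_str(id), format_prob(panel$weights[[id]]))
  }, ""), collapse = ", "))
  out <- c("{",
           '  "format": "bnpool-panel",',
           '  "version": 1,',
           sprintf('  "structure": {"name": %s, "nodes": %s, "parents": %s},',
                   j_str(skel$name), nodes_json, parents_json),
           sprintf('  "experts": %s,', experts_json),
           sprintf('  "covariates": %s,', cov_json),
           sprintf('  "weights": %s', weights_json),
           "}")
  writeLines(out, path)
  invisible(path)
}

#' Read or write a covariate table as CSV
#'
#' One row per expert (`expert_id` column) and one column per categorical
#' covariate. All columns are read as character; empty cells become `NA`
#' (the "missing" category).
#'
#' @param path File path.
#' @param covariates Data frame with an `expert_id` column (for the writer).
#' @return `read_covariates()`: a tibble; `write_covariates()`: the path,
#'   invisibly.
#' @export
read_covariates <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"expert_id" %in% names(out)) {
    stop_bnpool(sprintf("'%s': covariate CSV needs an `expert_id` column", path),
                "bnpool_io_error")
  }
  out
}

#' @rdname read_covariates
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(tibble::as_tibble(covariates), path, progress = FALSE)
  invisible(path)
}
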