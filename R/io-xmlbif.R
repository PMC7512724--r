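# XMLBIF 0.3 reader/writer. TABLE entries are listed row by row in the
# canonical parent order (last GIVEN varying fastest), with the child's
# outcomes fastest within each row. Unlike classic BIF, names may contain
# arbitrary characters (they live in element text), so the wayfinding
# fixture with its multi-word node names round-trips through XMLBIF.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

write_xmlbif <- function(net, path) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<BIF VERSION="0.3">',
             "<NETWORK>",
             sprintf("<NAME>%s</NAME>", xml_escape(net$name)))
  for (nd in node_names(net)) {
    lines <- c(lines,
               '<VARIABLE TYPE="nature">',
               sprintf("  <NAME>%s</NAME>", xml_escape(nd)),
               sprintf("  <OUTCOME>%s</OUTCOME>", xml_escape(net$nodes[[nd]])),
               "</VARIABLE>")
  }
  for (nd in node_names(net)) {
    cp <- net$cpts[[nd]]
    lines <- c(lines,
               "<DEFINITION>",
               sprintf("  <FOR>%s</FOR>", xml_escape(nd)),
               if (length(cp$parents))
                 sprintf("  <GIVEN>%s</GIVEN>", xml_escape(cp$parents)),
               sprintf("  <TABLE>%s</TABLE>",
                       paste(format_prob(as.vector(t(cp$prob))), collapse = " ")),
               "</DEFINITION>")
  }
  lines <- c(lines, "</NETWORK>", "</BIF>")
  writeLines(lines, path)
  invisible(path)
}

read_xmlbif <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_bnpool(sprintf("XMLBIF parse error in '%s': %s", path, conditionMessage(e)),
                "bnpool_io_error")
  })
  network <- xml2::xml_find_first(doc, ".//NETWORK")
  if (inherits(network, "xml_missing")) {
    stop_bnpool(sprintf("'%s': no <NETWORK> element", path), "bnpool_io_error")
  }
  name_node <- xml2::xml_find_first(network, "./NAME")
  name <- if (inherits(name_node, "xml_missing")) "network" else xml2::xml_text(name_node)
  states <- list()
  for (v in xml2::xml_find_all(network, "./VARIABLE")) {
    nm <- xml2::xml_text(xml2::xml_find_first(v, "./NAME"))
    states[[nm]] <- xml2::xml_text(xml2::xml_find_all(v, "./OUTCOME"))
  }
  cpt_specs <- list()
  for (d in xml2::xml_find_all(network, "./DEFINITION")) {
    child <- xml2::xml_text(xml2::xml_find_first(d, "./FOR"))
    parents <- xml2::xml_text(xml2::xml_find_all(d, "./GIVEN"))
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(
      xml2::xml_find_first(d, "./TABLE"))), "\\s+")[[1L]])
    cpt_specs[[child]] <- list(parents = parents, rows = list(), flat = vals)
  }
  build_net_from_specs(name, states, cpt_specs, path)
}
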