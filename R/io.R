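# Canonical network serialization is JSON (variables, edges, cpts,
# experience); XMLBIF export/import is provided for interoperability with
# standard BN software (structure and CPTs only — bin edges, tags and
# experience have no XMLBIF representation). Case tables are CSV with a
# header row of variable names and empty cells for missing values.

#' Write a network to JSON
#'
#' @param net A [bn_network()] (validated or not).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "bn_network"))
  doc <- list(
    format = "nanoband-network",
    version = 1L,
    variables = lapply(unname(net$variables), function(v) {
      out <- list(name = v$name, kind = v$kind, states = as.list(v$states),
                  tag = v$tag)
      if (!is.null(v$bin_edges)) out$bin_edges <- v$bin_edges
      out
    }),
    edges = apply(net$edges, 1L, function(e) list(parent = e[[1]], child = e[[2]]),
                  simplify = FALSE),
    cpts = lapply(unname(net$cpts), function(cp) {
      list(child = cp$child, parents = as.list(cp$parents),
           prob = lapply(seq_len(nrow(cp$prob)), function(i) cp$prob[i, ]))
    }))
  if (!is.null(net$experience)) doc$experience <- net$experience
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

schema_stop <- function(path, msg) {
  stop("network file '", path, "': ", msg, call. = FALSE)
}

#' Read a network from JSON
#'
#' Parses, rebuilds and validates the network; schema violations are
#' reported with the offending field.
#'
#' @param path JSON file written by [write_network()].
#' @return A validated [bn_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file '", path, "' not found", call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) schema_stop(path, conditionMessage(e)))
  if (!identical(doc$format, "nanoband-network"))
    schema_stop(path, "missing or wrong 'format' field")
  for (field in c("variables", "cpts"))
    if (is.null(doc[[field]])) schema_stop(path, paste0("missing '", field, "'"))
  vars <- lapply(doc$variables, function(v) {
    if (is.null(v$name) || is.null(v$states))
      schema_stop(path, "variable entry missing 'name' or 'states'")
    bn_variable(v$name, unlist(v$states),
                bin_edges = if (!is.null(v$bin_edges)) unlist(v$bin_edges),
                tag = v$tag %||% "physicochemical")
  })
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e) {
      if (is.null(e$parent) || is.null(e$child))
        schema_stop(path, "edge entry missing 'parent' or 'child'")
      c(e$parent, e$child)
    }))
  }
  cpts <- lapply(doc$cpts, function(cp) {
    if (is.null(cp$child) || is.null(cp$prob))
      schema_stop(path, "cpt entry missing 'child' or 'prob'")
    prob <- do.call(rbind, lapply(cp$prob, unlist))
    bn_cpt(cp$child, unlist(cp$parents) %||% character(), prob)
  })
  net <- bn_network(vars, edges, cpts,
                    experience = if (!is.null(doc$experience))
                      lapply(doc$experience, unlist))
  tryCatch(validate_network(net),
           error = function(e) schema_stop(path, conditionMessage(e)))
}

# Row-emission permutation for XMLBIF: entries iterate over GIVEN variables
# with the first GIVEN slowest and the FOR (child) outcomes fastest; internal
# CPT rows have the first parent fastest, so a permutation maps between them.
xmlbif_row_perm <- function(parent_card) {
  if (length(parent_card) == 0L) return(1L)
  cfg <- as.data.frame(expand.grid(lapply(parent_card, seq_len),
                                   KEEP.OUT.ATTRS = FALSE))
  do.call(order, cfg)
}

#' Export a network to XMLBIF 0.3
#'
#' Structure and CPTs only; bin edges, tags and experience are JSON-format
#' features. Posteriors computed after a round trip agree with the original
#' network.
#'
#' @inheritParams write_network
#' @export
write_xmlbif <- function(net, path) {
  stopifnot(inherits(net, "bn_network"))
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  nw <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(nw, "NAME", "nanoband")
  for (v in net$variables) {
    vn <- xml2::xml_add_child(nw, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(vn, "NAME", v$name)
    for (s in v$states) xml2::xml_add_child(vn, "OUTCOME", s)
  }
  for (cp in net$cpts) {
    dn <- xml2::xml_add_child(nw, "DEFINITION")
    xml2::xml_add_child(dn, "FOR", cp$child)
    for (p in cp$parents) xml2::xml_add_child(dn, "GIVEN", p)
    perm <- xmlbif_row_perm(bn_card(net, cp$parents))
    vals <- as.numeric(t(cp$prob[perm, , drop = FALSE]))
    xml2::xml_add_child(dn, "TABLE", paste(format(vals, digits = 17), collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network from XMLBIF 0.3
#'
#' @param path XMLBIF file.
#' @return A validated [bn_network()]; all variables come back categorical.
#' @export
read_xmlbif <- function(path) {
  if (!file.exists(path)) stop("XMLBIF file '", path, "' not found", call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) schema_stop(path, conditionMessage(e)))
  var_nodes <- xml2::xml_find_all(doc, ".//VARIABLE")
  vars <- lapply(var_nodes, function(vn) {
    bn_variable(xml2::xml_text(xml2::xml_find_first(vn, "./NAME")),
                xml2::xml_text(xml2::xml_find_all(vn, "./OUTCOME")))
  })
  names(vars) <- vapply(vars, `[[`, "", "name")
  card <- vapply(vars, function(v) length(v$states), 0L)
  edges <- NULL
  cpts <- list()
  for (dn in xml2::xml_find_all(doc, ".//DEFINITION")) {
    child <- xml2::xml_text(xml2::xml_find_first(dn, "./FOR"))
    parents <- xml2::xml_text(xml2::xml_find_all(dn, "./GIVEN"))
    vals <- as.numeric(strsplit(trimws(
      xml2::xml_text(xml2::xml_find_first(dn, "./TABLE"))), "\\s+")[[1]])
    k <- card[[child]]
    emitted <- matrix(vals, ncol = k, byrow = TRUE)
    perm <- xmlbif_row_perm(card[parents])
    prob <- emitted
    prob[perm, ] <- emitted
    cpts[[child]] <- bn_cpt(child, parents, prob)
    if (length(parents)) edges <- rbind(edges, cbind(parents, child))
  }
  validate_network(bn_network(unname(vars), edges, cpts))
}

#' Read / write case tables as CSV
#'
#' Header row = variable names; empty cell = missing.
#'
#' @param path CSV file.
#' @return A tibble of character state labels with `NA` for missing cells.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stop("case file '", path, "' not found", call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = c("", "NA"), progress = FALSE)
}

#' @rdname read_cases
#' @param cases Case tibble/data frame.
#' @export
write_cases <- function(cases, path) {
  readr::write_csv(cases, path, na = "")
  invisible(path)
}
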