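# OBO 1.4 subset reader/writer.  The OBO dialect covers classes, is-a edges
# and equivalence-strength EQ definitions rendered as genus-differentia
# intersection_of lines (genus = quality, differentia = characteristic_of
# entity and optionally has_modifier abnormal, with the has_part wrapping
# implicit).  Nominals, negation and universal restrictions are not
# expressible in OBO; axioms needing them are dropped on write with a logged
# manifest.  Full fidelity lives in the OWL functional dialect.

default_namespace_for_prefix <- function(prefix) {
  switch(prefix,
    CL = , UBERON = , NBO = "entity",
    PATO = "quality",
    COLL = "collection",
    GXP = , GQ = "grouping",
    "phenotype"
  )
}

#' Read an ontology from an OBO-subset file
#'
#' Supported stanza tags: `id`, `name`, `namespace`, `is_a`,
#' `intersection_of`, `equivalent_to` (named-to-named; merged as synonyms).
#' Trailing `! comment` text is ignored.  An `intersection_of` block with a
#' quality genus and a `characteristic_of` differentia is loaded as the
#' canonical EQ equivalence axiom; a `has_modifier` differentia adds the
#' abnormal-modifier conjunct.  Terms without a `namespace` tag get a
#' default from their CURIE prefix (CL/UBERON/NBO entity, PATO quality,
#' otherwise phenotype).
#'
#' @param path file path.
#' @param config a [cardinality_config()] (for EQ canonicalisation).
#' @return a `phen_ontology`.
#' @export
read_obo <- function(path, config = cardinality_config()) {
  lines <- readLines(path, warn = FALSE)
  strip <- function(x) sub("\\s*!.*$", "", trimws(x))
  ont <- ontology(basename(path))
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    warning("empty OBO file: ", path)
    return(ont)
  }
  # split stanzas
  terms <- list(); cur <- NULL; in_term <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    t <- trimws(line)
    if (!nzchar(t) || startsWith(t, "!")) next
    if (t == "[Term]") {
      if (!is.null(cur)) terms[[length(terms) + 1L]] <- cur
      cur <- list(); in_term <- TRUE
      next
    }
    if (startsWith(t, "[")) {          # other stanza types: skip
      if (!is.null(cur)) terms[[length(terms) + 1L]] <- cur
      cur <- NULL; in_term <- FALSE
      next
    }
    if (!grepl("^[A-Za-z_-]+:\\s*", t)) {
      stop("OBO syntax error at line ", ln, ": ", line)
    }
    if (!in_term) {                    # header tag
      if (startsWith(t, "ontology:")) {
        ont$name <- strip(sub("^ontology:\\s*", "", t))
      }
      next
    }
    tag <- sub(":.*$", "", t)
    val <- strip(sub("^[A-Za-z_-]+:\\s*", "", t))
    cur[[length(cur) + 1L]] <- c(tag = tag, val = val)
  }
  if (!is.null(cur)) terms[[length(terms) + 1L]] <- cur
  tag_vals <- function(term, tag) {
    vals <- vapply(term, function(p) if (p[["tag"]] == tag) p[["val"]] else
      NA_character_, character(1L))
    vals[!is.na(vals)]
  }
  # pass 1: declare classes
  for (term in terms) {
    id <- tag_vals(term, "id")
    if (length(id) != 1L) stop("OBO term without a single id tag")
    nm <- tag_vals(term, "name")
    ns <- tag_vals(term, "namespace")
    if (!length(ns)) ns <- default_namespace_for_prefix(curie_prefix(id))
    ont <- add_class(ont, id, label = if (length(nm)) nm[[1L]] else id,
                     namespace = ns[[1L]])
  }
  # pass 2: edges, EQ definitions, merges
  for (term in terms) {
    id <- tag_vals(term, "id")
    for (sup in tag_vals(term, "is_a")) ont <- add_subclass(ont, id, sup)
    inter <- tag_vals(term, "intersection_of")
    if (length(inter)) {
      genus <- NULL; entity <- NULL; modifier <- FALSE
      for (v in inter) {
        parts <- strsplit(v, "\\s+")[[1L]]
        if (length(parts) == 1L) genus <- parts
        else if (parts[[1L]] == "characteristic_of") entity <- parts[[2L]]
        else if (parts[[1L]] == "has_modifier") modifier <- TRUE
        else stop("unsupported intersection_of differentia: ", v)
      }
      if (is.null(genus) || is.null(entity)) {
        stop("incomplete genus-differentia definition for ", id)
      }
      ont <- add_axiom(ont, equivalence_axiom(
        id, canonical_eq_rhs(genus, ce_class(entity), modifier, config)))
    }
    for (eq in tag_vals(term, "equivalent_to")) {
      ont <- merge_equivalent(ont, id, eq)
    }
  }
  canonicalize_eq_axioms(ont, config)
}

#' Write an ontology to an OBO-subset file
#'
#' Deterministic output (terms and tags sorted).  Axioms that the OBO
#' subset cannot encode (nominal enumerations, negation, universal
#' restrictions, collection-expression bearers) are dropped; their count is
#' reported in a message and attached as the `dropped_axioms` attribute of
#' the returned path.
#'
#' @param ont a `phen_ontology`.
#' @param path file path.
#' @param config a [cardinality_config()].
#' @return `path`, invisibly, with attribute `dropped_axioms`.
#' @export
write_obo <- function(ont, path, config = cardinality_config()) {
  out <- c("format-version: 1.4", paste0("ontology: ", ont$name), "")
  dropped <- 0L
  for (id in class_ids(ont)) {
    term <- c("[Term]", paste0("id: ", id),
              paste0("name: ", class_label(ont, id)),
              paste0("namespace: ", class_namespace(ont, id)))
    supers <- sort(ont$edges$super[ont$edges$sub == id])
    if (length(supers)) term <- c(term, paste0("is_a: ", supers))
    for (ax in axioms_for(ont, id)) {
      eqdef <- parse_eq_definition(ax, config = config)
      if (!is.null(eqdef) && ax$strength == "equivalent" &&
          has_class(ont, eqdef$entity_id) &&
          class_namespace(ont, eqdef$entity_id) != "collection") {
        term <- c(term,
                  paste0("intersection_of: ", eqdef$quality_id),
                  paste0("intersection_of: characteristic_of ",
                         eqdef$entity_id),
                  if (eqdef$has_abnormal_modifier) {
                    paste0("intersection_of: has_modifier ",
                           config$abnormal_id)
                  })
      } else {
        dropped <- dropped + 1L
      }
    }
    syns <- sort(names(ont$synonyms)[ont$synonyms == id])
    if (length(syns)) term <- c(term, paste0("alt_id: ", syns))
    out <- c(out, term, "")
  }
  if (dropped) {
    message("OBO export dropped ", dropped,
            " axiom(s) not expressible in the OBO subset (see OWL ",
            "functional dialect for full fidelity)")
  }
  writeLines(out, path)
  invisible(structure(path, dropped_axioms = dropped))
}
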