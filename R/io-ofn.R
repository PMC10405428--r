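# OWL 2 Functional-Style Syntax subset writer/reader.  This dialect has
# full fidelity for the collection axioms: existential and universal
# restrictions, intersections, complement, nominal enumerations and the
# bottom concept.  IRIs embed the CURIE-style identifiers under fixed bases
# so the round trip is exact.

OFN_BASE <- "http://example.org/cardphen/"
OFN_CLASS <- paste0(OFN_BASE, "id/")
OFN_REL <- paste0(OFN_BASE, "rel/")
OFN_IND <- paste0(OFN_BASE, "ind/")
OFN_NS_PROP <- paste0(OFN_BASE, "meta/namespace")

ofn_class_iri <- function(id) paste0("<", OFN_CLASS, id, ">")
ofn_rel_iri <- function(p) paste0("<", OFN_REL, p, ">")
ofn_ind_iri <- function(id) paste0("<", OFN_IND, id, ">")

ofn_render_expr <- function(expr) {
  switch(expr$type,
    class = ofn_class_iri(expr$id),
    nothing = "owl:Nothing",
    some = paste0("ObjectSomeValuesFrom(", ofn_rel_iri(expr$property), " ",
                  ofn_render_expr(expr$filler), ")"),
    all = paste0("ObjectAllValuesFrom(", ofn_rel_iri(expr$property), " ",
                 ofn_render_expr(expr$filler), ")"),
    not = paste0("ObjectComplementOf(", ofn_render_expr(expr$filler), ")"),
    one_of = paste0("ObjectOneOf(",
                    paste(vapply(expr$individuals, ofn_ind_iri,
                                 character(1L)), collapse = " "), ")"),
    and = {
      parts <- vapply(expr$args, ofn_render_expr, character(1L))
      keys <- vapply(expr$args, expr_key, character(1L))
      paste0("ObjectIntersectionOf(", paste(parts[order(keys)],
                                            collapse = " "), ")")
    },
    stop("cannot render expression type: ", expr$type)
  )
}

#' Write an ontology in OWL functional-style syntax (subset)
#'
#' Deterministic output: declarations, annotations and axioms are each
#' sorted, so writing the same ontology twice gives identical bytes.  Class
#' labels and namespaces travel as annotation assertions.
#'
#' @param ont a `phen_ontology`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_owl_functional <- function(ont, path) {
  cls <- class_ids(ont)
  decl <- c(
    if (length(cls)) {
      sort(paste0("Declaration(Class(",
                  vapply(cls, ofn_class_iri, character(1L)), "))"))
    },
    if (length(ont$individuals)) {
      sort(paste0("Declaration(NamedIndividual(",
                  vapply(ont$individuals, ofn_ind_iri, character(1L)), "))"))
    }
  )
  esc <- function(x) gsub('"', '\\\\"', x)
  ann <- if (length(cls)) {
    c(
      paste0("AnnotationAssertion(rdfs:label ", vapply(cls, ofn_class_iri,
                                                       character(1L)),
             ' "', esc(vapply(cls, function(i) class_label(ont, i),
                              character(1L))), '")'),
      paste0("AnnotationAssertion(<", OFN_NS_PROP, "> ",
             vapply(cls, ofn_class_iri, character(1L)),
             ' "', vapply(cls, function(i) class_namespace(ont, i),
                          character(1L)), '")')
    )
  } else character()
  edge_ax <- if (nrow(ont$edges)) {
    paste0("SubClassOf(", vapply(ont$edges$sub, ofn_class_iri, character(1L)),
           " ", vapply(ont$edges$super, ofn_class_iri, character(1L)), ")")
  } else character()
  logic_ax <- vapply(ont$axioms, function(ax) {
    head <- if (ax$strength == "equivalent") "EquivalentClasses(" else
      "SubClassOf("
    paste0(head, ofn_class_iri(ax$lhs), " ", ofn_render_expr(ax$rhs), ")")
  }, character(1L))
  syn_ax <- if (length(ont$synonyms)) {
    paste0("EquivalentClasses(", vapply(names(ont$synonyms), ofn_class_iri,
                                        character(1L)), " ",
           vapply(unname(ont$synonyms), ofn_class_iri, character(1L)), ")")
  } else character()
  out <- c(
    "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
    paste0("Ontology(<", OFN_BASE, "ontology>"),
    decl, sort(ann), sort(c(edge_ax, logic_ax, syn_ax)),
    ")"
  )
  writeLines(out, path)
  invisible(path)
}

ofn_tokenize <- function(text) {
  pattern <- '<[^>]*>|"(?:[^"\\\\]|\\\\.)*"|[()]|[^\\s()]+'
  m <- gregexpr(pattern, text, perl = TRUE)
  unlist(regmatches(text, m), use.names = FALSE)
}

# Parse the token stream into nested lists: list(head = "SubClassOf",
# args = list(...)); leaves are token strings.
ofn_parse_forms <- function(tokens) {
  pos <- 1L
  parse_one <- function() {
    tok <- tokens[[pos]]
    pos <<- pos + 1L
    if (pos <= length(tokens) && identical(tokens[[pos]], "(")) {
      pos <<- pos + 1L
      args <- list()
      while (!identical(tokens[[pos]], ")")) {
        args[[length(args) + 1L]] <- parse_one()
      }
      pos <<- pos + 1L
      return(list(head = tok, args = args))
    }
    tok
  }
  forms <- list()
  while (pos <= length(tokens)) forms[[length(forms) + 1L]] <- parse_one()
  forms
}

ofn_decode_iri <- function(tok) {
  if (!is.character(tok)) stop("expected an IRI token")
  inner <- sub("^<", "", sub(">$", "", tok))
  if (startsWith(inner, OFN_CLASS)) {
    list(kind = "class", id = substring(inner, nchar(OFN_CLASS) + 1L))
  } else if (startsWith(inner, OFN_REL)) {
    list(kind = "rel", id = substring(inner, nchar(OFN_REL) + 1L))
  } else if (startsWith(inner, OFN_IND)) {
    list(kind = "ind", id = substring(inner, nchar(OFN_IND) + 1L))
  } else {
    list(kind = "other", id = inner)
  }
}

ofn_to_expr <- function(form) {
  if (is.character(form)) {
    if (identical(form, "owl:Nothing")) return(ce_nothing())
    d <- ofn_decode_iri(form)
    if (d$kind != "class") stop("unexpected IRI in class position: ", form)
    return(ce_class(d$id))
  }
  switch(form$head,
    ObjectSomeValuesFrom = ce_some(ofn_decode_iri(form$args[[1L]])$id,
                                   ofn_to_expr(form$args[[2L]])),
    ObjectAllValuesFrom = ce_all(ofn_decode_iri(form$args[[1L]])$id,
                                 ofn_to_expr(form$args[[2L]])),
    ObjectComplementOf = ce_not(ofn_to_expr(form$args[[1L]])),
    ObjectIntersectionOf = ce_and(lapply(form$args, ofn_to_expr)),
    ObjectOneOf = ce_one_of(vapply(form$args, function(a)
      ofn_decode_iri(a)$id, character(1L))),
    stop("unsupported OWL construct: ", form$head)
  )
}

unquote_literal <- function(tok) {
  gsub('\\\\"', '"', sub('^"', "", sub('"$', "", tok)))
}

#' Read an ontology from OWL functional-style syntax (subset)
#'
#' Inverse of [write_owl_functional()] on the supported constructs:
#' declarations, label/namespace annotation assertions, named subclass
#' edges, subclass/equivalence axioms over the fragment's class
#' expressions, and named-to-named equivalences (merged).  Unsupported
#' constructs are an error in this strict reader.
#'
#' @param path file path.
#' @param config a [cardinality_config()].
#' @return a `phen_ontology`.
#' @export
read_owl_functional <- function(path, config = cardinality_config()) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  forms <- ofn_parse_forms(ofn_tokenize(text))
  forms <- Filter(function(f) !is.character(f) && f$head == "Ontology",
                  forms)
  if (!length(forms)) {
    warning("no Ontology() block found in ", path)
    return(ontology(basename(path)))
  }
  body <- Filter(Negate(is.character), forms[[1L]]$args)
  ont <- ontology(basename(path))
  labels <- character(); namespaces <- character()
  classes <- character(); individuals <- character()
  for (f in body) {
    if (f$head == "Declaration") {
      inner <- f$args[[1L]]
      d <- ofn_decode_iri(inner$args[[1L]])
      if (inner$head == "Class") classes <- c(classes, d$id)
      if (inner$head == "NamedIndividual") individuals <- c(individuals, d$id)
    } else if (f$head == "AnnotationAssertion") {
      prop <- f$args[[1L]]
      target <- ofn_decode_iri(f$args[[2L]])$id
      value <- unquote_literal(f$args[[3L]])
      if (identical(prop, "rdfs:label")) labels[[target]] <- value
      if (is.character(prop) && grepl("meta/namespace", prop)) {
        namespaces[[target]] <- value
      }
    }
  }
  for (id in sort(unique(classes))) {
    ns <- if (id %in% names(namespaces)) namespaces[[id]] else
      default_namespace_for_prefix(curie_prefix(id))
    ont <- add_class(ont, id,
                     label = if (id %in% names(labels)) labels[[id]] else id,
                     namespace = ns)
  }
  for (id in individuals) ont <- add_individual(ont, id)
  for (f in body) {
    if (f$head == "SubClassOf") {
      lhs <- f$args[[1L]]; rhs <- f$args[[2L]]
      if (is.character(lhs) && is.character(rhs)) {
        ont <- add_subclass(ont, ofn_decode_iri(lhs)$id,
                            ofn_decode_iri(rhs)$id)
      } else if (is.character(lhs)) {
        ont <- add_axiom(ont, subclass_axiom(ofn_decode_iri(lhs)$id,
                                             ofn_to_expr(rhs)))
      } else {
        stop("unsupported SubClassOf shape (complex left-hand side)")
      }
    } else if (f$head == "EquivalentClasses") {
      lhs <- f$args[[1L]]; rhs <- f$args[[2L]]
      if (is.character(lhs) && is.character(rhs)) {
        ont <- merge_equivalent(ont, ofn_decode_iri(lhs)$id,
                                ofn_decode_iri(rhs)$id)
      } else if (is.character(lhs)) {
        ont <- add_axiom(ont, equivalence_axiom(ofn_decode_iri(lhs)$id,
                                                ofn_to_expr(rhs)))
      } else {
        stop("unsupported EquivalentClasses shape")
      }
    } else if (!f$head %in% c("Declaration", "AnnotationAssertion")) {
      stop("unsupported construct in strict mode: ", f$head)
    }
  }
  canonicalize_eq_axioms(ont, config)
}
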