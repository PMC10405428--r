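# In-memory ontology: classes with namespaces, asserted is-a edges, logical
# axioms and synonym bookkeeping for merged equivalent classes.

NAMESPACES <- c("phenotype", "entity", "quality", "collection", "grouping")

#' Create an empty ontology
#'
#' The ontology holds declared classes (each with a namespace describing its
#' role: phenotype, entity, quality, collection or grouping), asserted
#' named-to-named is-a edges, logical axioms (subclass/equivalence between a
#' named class and a class expression), declared individuals and a synonym
#' table mapping merged identifiers to their canonical node.
#'
#' @param name ontology name, used in serialisation headers.
#' @return a `phen_ontology` object.
#' @export
ontology <- function(name = "ontology") {
  structure(list(
    name = name,
    classes = list(),
    edges = data.frame(sub = character(), super = character(),
                       stringsAsFactors = FALSE),
    axioms = list(),
    individuals = character(),
    synonyms = character()
  ), class = "phen_ontology")
}

#' Declare a class term
#'
#' @param id CURIE-style identifier containing exactly one colon.
#' @param label human-readable name.
#' @param namespace one of `"phenotype"`, `"entity"`, `"quality"`,
#'   `"collection"`, `"grouping"`.
#' @return a `class_term`.
#' @export
class_term <- function(id, label = id, namespace) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!nzchar(id) || lengths(regmatches(id, gregexpr(":", id, fixed = TRUE))) != 1L) {
    stop("class id must be non-empty and contain exactly one ':': ", id)
  }
  namespace <- match.arg(namespace, NAMESPACES)
  structure(list(id = id, label = label, namespace = namespace),
            class = "class_term")
}

#' Resolve an identifier to its canonical node
#'
#' Identifiers merged as equivalents resolve to the lexicographically smallest
#' member of their synonym group, so the canonical choice is independent of
#' merge order.
#'
#' @param ont a `phen_ontology`.
#' @param id class identifier(s).
#' @return canonical identifier(s).
#' @export
resolve_id <- function(ont, id) {
  hit <- match(id, names(ont$synonyms))
  out <- id
  out[!is.na(hit)] <- unname(ont$synonyms[hit[!is.na(hit)]])
  out
}

#' @rdname resolve_id
#' @export
has_class <- function(ont, id) resolve_id(ont, id) %in% names(ont$classes)

#' @rdname resolve_id
#' @export
class_namespace <- function(ont, id) {
  id <- resolve_id(ont, id)
  vapply(id, function(i) {
    if (!i %in% names(ont$classes)) stop("unknown class id: ", i)
    ont$classes[[i]]$namespace
  }, character(1L))
}

#' @rdname resolve_id
#' @export
class_label <- function(ont, id) {
  id <- resolve_id(ont, id)
  vapply(id, function(i) {
    if (!i %in% names(ont$classes)) stop("unknown class id: ", i)
    ont$classes[[i]]$label
  }, character(1L))
}

#' Add a class to an ontology
#'
#' @param ont a `phen_ontology`.
#' @param term a `class_term`, or an id string (then `label` and `namespace`
#'   are used to build the term).
#' @inheritParams class_term
#' @return the updated ontology.
#' @export
add_class <- function(ont, term, label = NULL, namespace = NULL) {
  if (!inherits(term, "class_term")) {
    term <- class_term(term, label = if (is.null(label)) term else label,
                       namespace = namespace)
  }
  if (has_class(ont, term$id) || term$id %in% names(ont$synonyms)) {
    stop("duplicate class id (malformed input ontology): ", term$id)
  }
  ont$classes[[term$id]] <- term
  ont
}

#' Assert a named-to-named is-a edge
#'
#' @param ont a `phen_ontology`.
#' @param sub,super declared class identifiers; asserts `sub` is-a `super`.
#' @return the updated ontology.
#' @export
add_subclass <- function(ont, sub, super) {
  sub <- resolve_id(ont, sub); super <- resolve_id(ont, super)
  for (i in c(sub, super)) {
    if (!has_class(ont, i)) stop("unknown class id: ", i)
  }
  if (sub == super) return(ont)
  key <- paste(sub, super)
  have <- paste(ont$edges$sub, ont$edges$super)
  if (!key %in% have) {
    ont$edges <- rbind(ont$edges,
                       data.frame(sub = sub, super = super,
                                  stringsAsFactors = FALSE))
  }
  ont
}

#' Add a logical axiom
#'
#' @param ont a `phen_ontology`.
#' @param ax an `axiom` (see [subclass_axiom()]); duplicates are ignored.
#' @return the updated ontology.
#' @export
add_axiom <- function(ont, ax) {
  stopifnot(inherits(ax, "axiom"))
  key <- axiom_key(ax)
  have <- vapply(ont$axioms, axiom_key, character(1L))
  if (!key %in% have) ont$axioms[[length(ont$axioms) + 1L]] <- ax
  ont
}

#' @rdname add_class
#' @param id individual identifier.
#' @export
add_individual <- function(ont, id) {
  ont$individuals <- sort(unique(c(ont$individuals, id)))
  ont
}

remap_expr <- function(expr, map) {
  switch(expr$type,
    class = {
      hit <- match(expr$id, names(map))
      if (!is.na(hit)) expr$id <- unname(map[hit])
      expr
    },
    some = , all = , not = { expr$filler <- remap_expr(expr$filler, map); expr },
    and = { expr$args <- lapply(expr$args, remap_expr, map = map); expr },
    expr
  )
}

#' Merge two equivalent classes into one canonical node
#'
#' The lexicographically smallest identifier of the synonym group becomes the
#' canonical node; the other identifiers are kept as synonyms and resolve to
#' it.  Edges and axioms are rewritten to the canonical identifier.  Merging
#' is used both for cross-ontology equivalence mappings and for mutual
#' subclass assertions; any other cycle in the is-a graph is an input error.
#'
#' @param ont a `phen_ontology`.
#' @param id_a,id_b declared class identifiers to merge.
#' @return the updated ontology.
#' @export
merge_equivalent <- function(ont, id_a, id_b) {
  a <- resolve_id(ont, id_a); b <- resolve_id(ont, id_b)
  for (i in c(a, b)) if (!has_class(ont, i)) stop("unknown class id: ", i)
  if (a == b) return(ont)
  keep <- min(a, b); drop <- max(a, b)
  map <- c(drop = keep); names(map) <- drop
  # retarget existing synonyms of the dropped node, then record it
  ont$synonyms[ont$synonyms == drop] <- keep
  ont$synonyms[[drop]] <- keep
  ont$classes[[drop]] <- NULL
  ont$edges$sub <- unname(ifelse(ont$edges$sub == drop, keep, ont$edges$sub))
  ont$edges$super <- unname(ifelse(ont$edges$super == drop, keep, ont$edges$super))
  ont$edges <- unique(ont$edges[ont$edges$sub != ont$edges$super, , drop = FALSE])
  rownames(ont$edges) <- NULL
  ont$axioms <- lapply(ont$axioms, function(ax) {
    if (ax$lhs == drop) ax$lhs <- keep
    ax$rhs <- remap_expr(ax$rhs, map)
    ax
  })
  keys <- vapply(ont$axioms, axiom_key, character(1L))
  ont$axioms <- ont$axioms[!duplicated(keys)]
  ont
}

#' List class identifiers, optionally by namespace
#'
#' @param ont a `phen_ontology`.
#' @param namespace optional namespace filter.
#' @return sorted character vector of canonical class ids.
#' @export
class_ids <- function(ont, namespace = NULL) {
  ids <- as.character(names(ont$classes))
  if (!is.null(namespace)) {
    ns <- vapply(ont$classes, `[[`, character(1L), "namespace")
    ids <- ids[ns %in% namespace]
  }
  sort(ids)
}

#' Axioms whose left-hand side is a given class
#'
#' @param ont a `phen_ontology`.
#' @param id class identifier.
#' @return list of axioms.
#' @export
axioms_for <- function(ont, id) {
  id <- resolve_id(ont, id)
  Filter(function(ax) ax$lhs == id, ont$axioms)
}

#' Drop all logical axioms defining a class
#'
#' Used by the rewrite step, which replaces (rather than augments) the
#' original entity-based definition of a cardinality phenotype.
#'
#' @param ont a `phen_ontology`.
#' @param id class identifier.
#' @return the updated ontology.
#' @export
drop_axioms_for <- function(ont, id) {
  id <- resolve_id(ont, id)
  ont$axioms <- Filter(function(ax) ax$lhs != id, ont$axioms)
  ont
}

#' Build the asserted subsumption graph of an ontology
#'
#' @param ont a `phen_ontology`.
#' @param namespace optional namespace filter; edges are restricted to nodes
#'   within the filtered set.
#' @return an (unclosed) `subsumption_graph`.
#' @export
subsumption_graph_of <- function(ont, namespace = NULL) {
  nodes <- class_ids(ont, namespace)
  e <- ont$edges[ont$edges$sub %in% nodes & ont$edges$super %in% nodes, ,
                 drop = FALSE]
  subsumption_graph(nodes, e)
}

#' @export
print.phen_ontology <- function(x, ...) {
  ns <- table(vapply(x$classes, `[[`, character(1L), "namespace"))
  cat("<phen_ontology> ", x$name, ": ", length(x$classes), " classes (",
      paste(names(ns), as.integer(ns), sep = ":", collapse = ", "),
      "), ", nrow(x$edges), " asserted edges, ", length(x$axioms),
      " axioms\n", sep = "")
  invisible(x)
}
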