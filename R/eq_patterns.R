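# Entity-quality (EQ) logical definitions: parsing the has_part pattern and
# detecting cardinality phenotypes.

#' EQ logical definition of a phenotype class
#'
#' Represents the standard phenotype definition pattern
#' `P (=|<=) has_part some (Q and characteristic_of some E
#' [and has_modifier some abnormal])`, where `Q` is a quality class and `E`
#' the affected entity (or, after rewriting, a collection class).
#'
#' @param phenotype_id,quality_id,entity_id class identifiers.
#' @param has_abnormal_modifier logical; whether the abnormal-modifier
#'   conjunct is present.
#' @param strength `"equivalent"` or `"subclass"`.
#' @return an `eq_definition`.
#' @export
eq_definition <- function(phenotype_id, quality_id, entity_id,
                          has_abnormal_modifier = TRUE,
                          strength = c("equivalent", "subclass")) {
  strength <- match.arg(strength)
  structure(list(phenotype_id = phenotype_id, quality_id = quality_id,
                 entity_id = entity_id,
                 has_abnormal_modifier = isTRUE(has_abnormal_modifier),
                 strength = strength),
            class = "eq_definition")
}

#' @export
print.eq_definition <- function(x, ...) {
  cat("<eq_definition> ", x$phenotype_id,
      if (x$strength == "equivalent") " = " else " <= ",
      "has_part some (", x$quality_id, " and characteristic_of some ",
      x$entity_id,
      if (x$has_abnormal_modifier) " and has_modifier some abnormal", ")\n",
      sep = "")
  invisible(x)
}

# Match the inner conjunction (quality and characteristic_of some E
# [and has_modifier some abnormal]).  Returns NULL on non-match.
match_inner_conjunction <- function(expr, config, allow_modifier = TRUE) {
  args <- if (expr$type == "and") expr$args else list(expr)
  quality <- NULL; entity <- NULL; modifier <- FALSE
  for (a in args) {
    if (a$type == "class") {
      if (!is.null(quality)) return(NULL)
      quality <- a$id
    } else if (a$type == "some" && a$property == "characteristic_of" &&
               a$filler$type == "class") {
      if (!is.null(entity)) return(NULL)
      entity <- a$filler$id
    } else if (allow_modifier && a$type == "some" &&
               a$property == "has_modifier" && a$filler$type == "class" &&
               a$filler$id == config$abnormal_id) {
      modifier <- TRUE
    } else {
      return(NULL)
    }
  }
  if (is.null(quality) || is.null(entity)) return(NULL)
  list(quality = quality, entity = entity, modifier = modifier)
}

# Structural EQ match; accepts the abnormal-modifier conjunct either inside
# the has_part filler or conjoined with the has_part restriction at the top
# level (phenotype ontologies use both nestings).  Returns
# list(quality, entity, modifier, nesting) or NULL.
match_eq_expr <- function(rhs, config) {
  if (rhs$type == "some" && rhs$property == "has_part") {
    m <- match_inner_conjunction(rhs$filler, config)
    if (!is.null(m)) return(c(m, list(nesting = "inside")))
    return(NULL)
  }
  if (rhs$type == "and" && length(rhs$args) == 2L) {
    is_mod <- vapply(rhs$args, function(a) {
      a$type == "some" && a$property == "has_modifier" &&
        a$filler$type == "class" && a$filler$id == config$abnormal_id
    }, logical(1L))
    if (sum(is_mod) == 1L) {
      core <- rhs$args[[which(!is_mod)]]
      if (core$type == "some" && core$property == "has_part") {
        m <- match_inner_conjunction(core$filler, config,
                                     allow_modifier = FALSE)
        if (!is.null(m)) {
          m$modifier <- TRUE
          return(c(m, list(nesting = "outside")))
        }
      }
    }
  }
  NULL
}

canonical_eq_rhs <- function(quality_id, entity_expr, modifier, config) {
  args <- list(ce_class(quality_id),
               ce_some("characteristic_of", entity_expr))
  if (modifier) {
    args <- c(args, list(ce_some("has_modifier", ce_class(config$abnormal_id))))
  }
  ce_some("has_part", ce_and(args))
}

#' Parse an EQ logical definition from an axiom
#'
#' Matches the pattern `has_part some (quality and characteristic_of some
#' entity [and has_modifier some abnormal])` on the right-hand side of a
#' subclass or equivalence axiom.  The abnormal-modifier conjunct may sit
#' inside the `has_part` filler or be conjoined outside it; both nestings are
#' accepted and recorded as `has_abnormal_modifier`.  Non-matching axioms
#' yield `NULL` and are left untouched by all downstream steps.
#'
#' @param ax an `axiom`.
#' @param ont optional `phen_ontology`; when given, a structural match whose
#'   quality or entity id is not a declared class is an error naming the
#'   dangling id.
#' @param config a [cardinality_config()].
#' @return an `eq_definition`, or `NULL` if the axiom does not match.
#' @export
parse_eq_definition <- function(ax, ont = NULL, config = cardinality_config()) {
  stopifnot(inherits(ax, "axiom"))
  m <- match_eq_expr(ax$rhs, config)
  if (is.null(m)) return(NULL)
  if (!is.null(ont)) {
    for (i in c(m$quality, m$entity)) {
      if (!has_class(ont, i)) {
        stop("EQ pattern references undeclared class: ", i)
      }
    }
  }
  eq_definition(ax$lhs, m$quality, m$entity,
                has_abnormal_modifier = m$modifier, strength = ax$strength)
}

#' Normalise EQ axioms to the modifier-inside nesting
#'
#' Rewrites every EQ axiom whose abnormal-modifier conjunct sits outside the
#' `has_part` filler into the canonical nesting with the modifier inside the
#' inner conjunction.  Applied on load so that classification and
#' serialisation operate on one form.
#'
#' @param ont a `phen_ontology`.
#' @param config a [cardinality_config()].
#' @return the updated ontology.
#' @export
canonicalize_eq_axioms <- function(ont, config = cardinality_config()) {
  ont$axioms <- lapply(ont$axioms, function(ax) {
    m <- match_eq_expr(ax$rhs, config)
    if (!is.null(m) && m$nesting == "outside") {
      ax$rhs <- canonical_eq_rhs(m$quality, ce_class(m$entity), m$modifier,
                                 config)
    }
    ax
  })
  keys <- vapply(ont$axioms, axiom_key, character(1L))
  ont$axioms <- ont$axioms[!duplicated(keys)]
  ont
}

#' Is an EQ definition a cardinality phenotype?
#'
#' True iff the definition's quality falls under the *amount* quality in the
#' quality-hierarchy closure (or is one of the configured absence qualities)
#' and the entity passes the entity prefix filter (by default: cell types).
#'
#' @param eqdef an `eq_definition`.
#' @param quality_graph the quality-hierarchy `subsumption_graph`.
#' @param config a [cardinality_config()].
#' @return logical.
#' @export
is_cardinality_phenotype <- function(eqdef, quality_graph,
                                     config = cardinality_config()) {
  quality_graph <- transitive_closure(quality_graph)
  if (!eqdef$quality_id %in% quality_graph$nodes) {
    stop("quality id not in quality hierarchy: ", eqdef$quality_id)
  }
  q_ok <- eqdef$quality_id %in% config$absence_ids ||
    (config$amount_root_id %in% quality_graph$nodes &&
       entails(quality_graph, eqdef$quality_id, config$amount_root_id))
  e_ok <- is.null(config$entity_prefixes) ||
    curie_prefix(eqdef$entity_id) %in% config$entity_prefixes
  q_ok && e_ok
}

eq_kind <- function(eqdef, config) {
  if (eqdef$quality_id %in% config$absence_ids) "absence" else "amount"
}

#' Detect all cardinality phenotype classes of an ontology
#'
#' Parses every axiom, keeps EQ definitions over entity-namespace classes
#' passing [is_cardinality_phenotype()], and returns them sorted by phenotype
#' id.  Classes whose EQ entity is already a collection class (i.e. already
#' rewritten) are never re-detected, which makes the rewrite idempotent.
#'
#' @param ont a `phen_ontology` whose quality hierarchy is loaded.
#' @param config a [cardinality_config()].
#' @return list of `eq_definition`s, sorted by phenotype id.
#' @export
detect_cardinality_phenotypes <- function(ont, config = cardinality_config()) {
  quality_graph <- transitive_closure(subsumption_graph_of(ont, "quality"))
  defs <- list()
  for (ax in ont$axioms) {
    eqdef <- parse_eq_definition(ax, ont = ont, config = config)
    if (is.null(eqdef)) next
    if (class_namespace(ont, eqdef$entity_id) != "entity") next
    if (!eqdef$quality_id %in% quality_graph$nodes) next
    if (is_cardinality_phenotype(eqdef, quality_graph, config)) {
      defs[[length(defs) + 1L]] <- eqdef
    }
  }
  ord <- order(vapply(defs, `[[`, character(1L), "phenotype_id"))
  defs[ord]
}

#' Tabulate EQ definitions
#'
#' @param defs list of `eq_definition`s.
#' @return data frame with one row per definition.
#' @export
eq_definition_table <- function(defs) {
  data.frame(
    phenotype_id = vapply(defs, `[[`, character(1L), "phenotype_id"),
    quality_id = vapply(defs, `[[`, character(1L), "quality_id"),
    entity_id = vapply(defs, `[[`, character(1L), "entity_id"),
    has_abnormal_modifier = vapply(defs, `[[`, logical(1L),
                                   "has_abnormal_modifier"),
    strength = vapply(defs, `[[`, character(1L), "strength"),
    stringsAsFactors = FALSE
  )
}
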