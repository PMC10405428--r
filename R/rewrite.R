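# Collection classes, rewritten cardinality-phenotype axioms, grouping
# classes and the materialised collection partonomy.

ensure_root_collection <- function(ont, config) {
  if (!has_class(ont, config$root_collection_id)) {
    ont <- add_class(ont, config$root_collection_id,
                     label = config$root_collection_label,
                     namespace = "collection")
  }
  ont
}

#' Create the collection class of an entity
#'
#' For an entity class `X`, declares the class `X-Collection` (collection
#' namespace) with three axioms: every member of the collection is an `X`
#' (`X-Collection <= has_member only X`), every `X` is a member of the
#' collection (`X <= member_of some X-Collection`), and the collection is a
#' nominal singleton (`X-Collection = { x-collection }`, with a fresh
#' individual used nowhere else), which makes it the one maximal collection
#' of `X`s within a body.  The collection is also asserted under the root
#' collection class.  Identifier generation is deterministic from the entity
#' id, and calling the function twice is a no-op.
#'
#' @param ont a `phen_ontology`.
#' @param entity_id a declared entity class.
#' @param config a [cardinality_config()].
#' @return the updated ontology.
#' @export
make_collection_class <- function(ont, entity_id, config = cardinality_config()) {
  entity_id <- resolve_id(ont, entity_id)
  if (!has_class(ont, entity_id)) stop("unknown entity class: ", entity_id)
  ont <- ensure_root_collection(ont, config)
  coll <- collection_id_for(entity_id, config)
  ind <- collection_individual_for(entity_id, config)
  if (!has_class(ont, coll)) {
    ont <- add_class(ont, coll,
                     label = paste0(class_label(ont, entity_id), "-Collection"),
                     namespace = "collection")
  }
  ont <- add_individual(ont, ind)
  ont <- add_axiom(ont, subclass_axiom(coll, ce_all("has_member",
                                                    ce_class(entity_id))))
  ont <- add_axiom(ont, subclass_axiom(entity_id,
                                       ce_some("member_of", ce_class(coll))))
  ont <- add_axiom(ont, equivalence_axiom(coll, ce_one_of(ind)))
  ont <- add_subclass(ont, coll, config$root_collection_id)
  ont
}

#' Tabulate the collection classes of an ontology
#'
#' Collections are recognised from their member-typing axiom
#' (`<= has_member only X`); the root collection class carries no such axiom
#' and is not listed.
#'
#' @param ont a `phen_ontology`.
#' @param config a [cardinality_config()].
#' @return data frame with columns `id`, `member_class_id`,
#'   `nominal_individual_id`, sorted by `id`.
#' @export
collection_classes <- function(ont, config = cardinality_config()) {
  rows <- list()
  for (ax in ont$axioms) {
    if (ax$strength == "subclass" && ax$rhs$type == "all" &&
        ax$rhs$property == "has_member" && ax$rhs$filler$type == "class" &&
        has_class(ont, ax$lhs) &&
        class_namespace(ont, ax$lhs) == "collection") {
      rows[[length(rows) + 1L]] <-
        data.frame(id = ax$lhs, member_class_id = ax$rhs$filler$id,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(), member_class_id = character(),
                      nominal_individual_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  nominal <- vapply(out$id, function(cid) {
    for (ax in axioms_for(ont, cid)) {
      if (ax$strength == "equivalent" && ax$rhs$type == "one_of") {
        return(ax$rhs$individuals[[1L]])
      }
    }
    NA_character_
  }, character(1L))
  out$nominal_individual_id <- unname(nominal)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Materialise the collection partonomy
#'
#' For every pair of entities `X`, `Y` with `X` is-a `Y` in the entity
#' closure (non-reflexive) and both having collection classes, asserts
#' `X-Collection <= part_of some Y-Collection`.  Entities pulled in as
#' ancestors of collection members but lacking a collection get one
#' auto-created (with a message).  Output order is deterministic.
#'
#' @param ont a `phen_ontology` that already has collection classes.
#' @param config a [cardinality_config()].
#' @return the updated ontology.
#' @export
materialize_partonomy <- function(ont, config = cardinality_config()) {
  colls <- collection_classes(ont, config)
  if (!nrow(colls)) return(ont)
  entity_closure <- transitive_closure(subsumption_graph_of(ont, "entity"))
  members <- sort(unique(colls$member_class_id))
  scope <- sort(unique(unlist(lapply(members, ancestors,
                                     graph = entity_closure))))
  auto <- setdiff(scope, members)
  if (length(auto)) {
    message("auto-creating collections for ancestor entities: ",
            paste(auto, collapse = ", "))
    for (x in auto) ont <- make_collection_class(ont, x, config)
  }
  for (x in scope) {
    for (y in sort(setdiff(intersect(ancestors(entity_closure, x), scope), x))) {
      ont <- add_axiom(ont, subclass_axiom(
        collection_id_for(x, config),
        ce_some("part_of", ce_class(collection_id_for(y, config)))))
    }
  }
  ont
}

#' Collection part-of axioms of an ontology
#'
#' @param ont a `phen_ontology`.
#' @return data frame with columns `part`, `whole` (collection ids).
#' @export
partonomy_axioms <- function(ont) {
  rows <- list()
  for (ax in ont$axioms) {
    if (ax$strength == "subclass" && ax$rhs$type == "some" &&
        ax$rhs$property == "part_of" && ax$rhs$filler$type == "class") {
      rows[[length(rows) + 1L]] <- data.frame(part = ax$lhs,
                                              whole = ax$rhs$filler$id,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(part = character(), whole = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$part, out$whole), , drop = FALSE]
}

#' Rewrite one cardinality phenotype over its collection
#'
#' Replaces the entity-based EQ definition of a cardinality phenotype with
#' its collection-based form.  Amount-kind phenotypes get one axiom with the
#' entity replaced by its collection class, preserving quality, modifier and
#' definition strength.  Absence-kind phenotypes get two definitions of the
#' same class: the empty-collection form
#' `has_part some (quality and characteristic_of some (X-Collection and
#' has_member only Nothing) [and has_modifier some abnormal])` and the
#' negative form `not (has_part some (quality and characteristic_of some X))`
#' (no modifier).  Declaring both on one class makes the two right-hand sides
#' definitionally equivalent.  The original definition is removed, not kept.
#'
#' @param ont a `phen_ontology` in which the entity's collection exists.
#' @param eqdef an `eq_definition` that is a cardinality phenotype.
#' @param config a [cardinality_config()].
#' @return the updated ontology.
#' @export
rewrite_phenotype <- function(ont, eqdef, config = cardinality_config()) {
  quality_graph <- subsumption_graph_of(ont, "quality")
  if (!is_cardinality_phenotype(eqdef, quality_graph, config)) {
    stop("not a cardinality phenotype: ", eqdef$phenotype_id)
  }
  coll <- collection_id_for(eqdef$entity_id, config)
  if (!has_class(ont, coll)) {
    stop("collection class missing for entity ", eqdef$entity_id,
         "; create it first")
  }
  make_ax <- if (eqdef$strength == "equivalent") equivalence_axiom else
    subclass_axiom
  ont <- drop_axioms_for(ont, eqdef$phenotype_id)
  if (eq_kind(eqdef, config) == "amount") {
    ont <- add_axiom(ont, make_ax(
      eqdef$phenotype_id,
      canonical_eq_rhs(eqdef$quality_id, ce_class(coll),
                       eqdef$has_abnormal_modifier, config)))
  } else {
    empty_coll <- ce_and(ce_class(coll),
                         ce_all("has_member", ce_nothing()))
    ont <- add_axiom(ont, make_ax(
      eqdef$phenotype_id,
      canonical_eq_rhs(config$quality_root_id, empty_coll,
                       eqdef$has_abnormal_modifier, config)))
    ont <- add_axiom(ont, make_ax(
      eqdef$phenotype_id,
      ce_not(ce_some("has_part",
                     ce_and(ce_class(config$quality_root_id),
                            ce_some("characteristic_of",
                                    ce_class(eqdef$entity_id)))))))
  }
  ont
}

#' Create grouping classes
#'
#' One by-collection grouping class per collection (`CXP`, subsuming every
#' abnormality of that collection: genus is the root quality) and one
#' by-quality grouping class per supplied quality (`CQ`, subsuming that
#' quality's phenotypes across all collections: the characteristic bearer is
#' the root collection class).  Grouping axioms are emitted as equivalences
#' so that classification places rewritten phenotypes under them.
#'
#' @param ont a `phen_ontology` with collections and the root collection.
#' @param qualities quality ids for the by-quality classes.
#' @param config a [cardinality_config()].
#' @return the updated ontology.
#' @export
make_grouping_classes <- function(ont, qualities,
                                  config = cardinality_config()) {
  ont <- ensure_root_collection(ont, config)
  colls <- collection_classes(ont, config)
  for (i in seq_len(nrow(colls))) {
    gid <- grouping_entity_id_for(colls$member_class_id[i], config)
    if (!has_class(ont, gid)) {
      ont <- add_class(ont, gid,
                       label = paste0("abnormality of collection of ",
                                      class_label(ont,
                                                  colls$member_class_id[i])),
                       namespace = "grouping")
    }
    ont <- add_axiom(ont, equivalence_axiom(
      gid, canonical_eq_rhs(config$quality_root_id, ce_class(colls$id[i]),
                            TRUE, config)))
    if (!is.null(config$phenotype_root_id) &&
        has_class(ont, config$phenotype_root_id)) {
      ont <- add_subclass(ont, gid, config$phenotype_root_id)
    }
  }
  for (q in sort(unique(qualities))) {
    gid <- grouping_quality_id_for(q, config)
    if (!has_class(ont, gid)) {
      qlab <- if (has_class(ont, q)) class_label(ont, q) else q
      ont <- add_class(ont, gid, label = paste(qlab, "cardinality"),
                       namespace = "grouping")
    }
    ont <- add_axiom(ont, equivalence_axiom(
      gid, canonical_eq_rhs(q, ce_class(config$root_collection_id), TRUE,
                            config)))
    if (!is.null(config$phenotype_root_id) &&
        has_class(ont, config$phenotype_root_id)) {
      ont <- add_subclass(ont, gid, config$phenotype_root_id)
    }
  }
  ont
}

# Number of phenotype classes currently defined over collections (amount
# form over a collection bearer, or dual absence forms).
n_rewritten_phenotypes <- function(ont, config) {
  meta <- class_meta(ont, config)
  n <- 0L
  if (!is.null(meta$pattern)) {
    p <- meta$pattern
    coll_bearer <- vapply(p$bearer, function(b) {
      has_class(ont, b) && class_namespace(ont, b) == "collection"
    }, logical(1L))
    pheno <- class_namespace(ont, p$id) == "phenotype"
    n <- n + sum(coll_bearer & pheno)
  }
  if (!is.null(meta$absence)) {
    n <- n + sum(class_namespace(ont, meta$absence$id) == "phenotype")
  }
  n
}

#' Rewrite an ontology's cardinality phenotypes over collections
#'
#' Pipeline composition: detect cardinality phenotypes, create one collection
#' class per affected entity, materialise the collection partonomy, replace
#' each detected definition with its collection-based form (dual definitions
#' for absences), and create the grouping classes (one per collection, one
#' per detected quality).  The result carries a provenance table mapping
#' every generated class to its source class and generation schema.
#' Deterministic given identical input, and a fixpoint: re-running on its own
#' output creates nothing new.
#'
#' @param ont a `phen_ontology` with entity and quality hierarchies loaded.
#' @param config a [cardinality_config()].
#' @return a `rewritten_ontology` (also a `phen_ontology`) with a
#'   `provenance` data frame and a `rewrite_summary` count vector.
#' @export
rewrite_ontology <- function(ont, config = cardinality_config()) {
  ont <- canonicalize_eq_axioms(ont, config)
  pre_classes <- class_ids(ont)
  detections <- detect_cardinality_phenotypes(ont, config)
  ont <- ensure_root_collection(ont, config)
  prov <- list()
  note <- function(generated, source, schema) {
    prov[[length(prov) + 1L]] <<- data.frame(generated_id = generated,
                                             source_id = source,
                                             schema = schema,
                                             stringsAsFactors = FALSE)
  }
  entities <- sort(unique(vapply(detections, `[[`, character(1L),
                                 "entity_id")))
  for (x in entities) {
    ont <- make_collection_class(ont, x, config)
    note(collection_id_for(x, config), x, "collection")
  }
  ont <- materialize_partonomy(ont, config)
  colls <- collection_classes(ont, config)
  for (x in setdiff(colls$member_class_id, entities)) {
    note(collection_id_for(x, config), x, "collection")
  }
  for (eqdef in detections) {
    ont <- rewrite_phenotype(ont, eqdef, config)
    note(eqdef$phenotype_id, eqdef$phenotype_id,
         paste0("rewritten_", eq_kind(eqdef, config)))
  }
  if (length(detections)) {
    qualities <- sort(unique(vapply(detections, `[[`, character(1L),
                                    "quality_id")))
    ont <- make_grouping_classes(ont, qualities, config)
    for (x in collection_classes(ont, config)$member_class_id) {
      note(grouping_entity_id_for(x, config), x, "grouping_by_collection")
    }
    for (q in qualities) {
      note(grouping_quality_id_for(q, config), q, "grouping_by_quality")
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(generated_id = character(), source_id = character(),
               schema = character(), stringsAsFactors = FALSE)
  prov <- prov[prov$generated_id %in% setdiff(class_ids(ont), pre_classes) |
                 grepl("^rewritten", prov$schema), , drop = FALSE]
  prov <- unique(prov[order(prov$generated_id, prov$schema), , drop = FALSE])
  rownames(prov) <- NULL
  ont$provenance <- prov
  ont$rewrite_summary <- c(
    collections = nrow(collection_classes(ont, config)),
    rewritten = n_rewritten_phenotypes(ont, config),
    grouping = length(class_ids(ont, "grouping")),
    partonomy = nrow(partonomy_axioms(ont))
  )
  class(ont) <- unique(c("rewritten_ontology", class(ont)))
  ont
}
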