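# Entailed subsumption among phenotype classes: pattern-specific inference
# rules for the original EQ semantics and the rewritten collection semantics,
# plus a naive structural-subsumption saturation oracle used to verify them.

key_set_of <- function(graph) transitive_closure(graph)$key_set

in_keys <- function(sub, super, keys) paste(sub, super) %in% keys

#' Classify phenotype classes under the original EQ semantics
#'
#' Entails `P1` is-a `P2` iff `quality(P1)` is-a `quality(P2)` and
#' `entity(P1)` is-a `entity(P2)` in the respective closures (monotonicity of
#' the shared existential-restriction pattern), provided `P2` is an
#' equivalence-strength definition (subclass-strength classes state necessary
#' conditions only, so they gain supers, never subs, from the pattern) and
#' `P2`'s abnormal-modifier conjunct, if present, is also present in `P1`.
#' Asserted is-a edges are kept and the result is transitively closed.
#'
#' @param eqdefs list of `eq_definition`s (all in the plain EQ pattern).
#' @param entity_closure,quality_closure closed `subsumption_graph`s.
#' @param asserted optional data frame of asserted `(sub, super)` edges.
#' @param nodes optional further node ids (undefined phenotype classes).
#' @return a closed `subsumption_graph` over the phenotype classes.
#' @export
classify_original <- function(eqdefs, entity_closure, quality_closure,
                              asserted = NULL, nodes = NULL) {
  entity_closure <- transitive_closure(entity_closure)
  quality_closure <- transitive_closure(quality_closure)
  d <- eq_definition_table(eqdefs)
  bad_e <- setdiff(d$entity_id, entity_closure$nodes)
  bad_q <- setdiff(d$quality_id, quality_closure$nodes)
  if (length(bad_e) || length(bad_q)) {
    stop("EQ definition references class outside the closures: ",
         paste(c(bad_e, bad_q), collapse = ", "))
  }
  rule_edges <- pattern_edges(
    quality = d$quality_id, bearer = d$entity_id, id = d$phenotype_id,
    modifier = d$has_abnormal_modifier, strength = d$strength,
    quality_keys = key_set_of(quality_closure),
    bearer_keys = key_set_of(entity_closure))
  all_nodes <- unique(c(d$phenotype_id, nodes,
                        if (!is.null(asserted)) unlist(asserted[, 1:2])))
  transitive_closure(subsumption_graph(
    all_nodes, rbind(rule_edges, normalize_edges(asserted))))
}

normalize_edges <- function(edges) {
  if (is.null(edges) || !nrow(edges)) {
    return(data.frame(sub = character(), super = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(sub = as.character(edges[[1L]]), super = as.character(edges[[2L]]),
             stringsAsFactors = FALSE)
}

# Vectorised one-step rule for the shared existential pattern: all ordered
# pairs (i, j) with quality_i <= quality_j and bearer_i <= bearer_j.
pattern_edges <- function(quality, bearer, id, modifier, strength,
                          quality_keys, bearer_keys) {
  n <- length(id)
  if (n < 2L) {
    return(data.frame(sub = character(), super = character(),
                      stringsAsFactors = FALSE))
  }
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  g <- g[g$i != g$j, , drop = FALSE]
  ok <- strength[g$j] == "equivalent" &
    (!modifier[g$j] | modifier[g$i]) &
    in_keys(quality[g$i], quality[g$j], quality_keys) &
    in_keys(bearer[g$i], bearer[g$j], bearer_keys)
  data.frame(sub = id[g$i][ok], super = id[g$j][ok], stringsAsFactors = FALSE)
}

# Recognise the definitional role of every phenotype/grouping class of a
# (possibly rewritten) ontology.  Returns:
#   pattern: rows for plain-EQ and collection-phenotype classes
#            (id, quality, bearer, modifier, strength)
#   absence: rows for dual-definition absence classes
#            (id, entity, coll, modifier, strength)
class_meta <- function(ont, config) {
  pattern <- list(); absence <- list()
  scope <- class_ids(ont, c("phenotype", "grouping"))
  for (id in scope) {
    axs <- axioms_for(ont, id)
    if (!length(axs)) next
    eq <- NULL; abs_row <- NULL
    for (ax in axs) {
      m <- match_eq_expr(ax$rhs, config)
      if (!is.null(m)) {
        eq <- data.frame(id = id, quality = m$quality, bearer = m$entity,
                         modifier = m$modifier, strength = ax$strength,
                         stringsAsFactors = FALSE)
        next
      }
      a <- match_absence_expr(ax$rhs, ont, config)
      if (!is.null(a)) {
        if (is.null(abs_row)) {
          abs_row <- data.frame(id = id, entity = NA_character_,
                                coll = NA_character_, modifier = FALSE,
                                strength = ax$strength,
                                stringsAsFactors = FALSE)
        }
        if (a$form == "empty") {
          abs_row$coll <- a$coll
          abs_row$modifier <- a$modifier
        } else {
          abs_row$entity <- a$entity
        }
        if (ax$strength == "equivalent") abs_row$strength <- "equivalent"
      }
    }
    if (!is.null(abs_row)) {
      absence[[length(absence) + 1L]] <- abs_row
    } else if (!is.null(eq)) {
      pattern[[length(pattern) + 1L]] <- eq
    }
  }
  list(
    pattern = if (length(pattern)) do.call(rbind, pattern) else NULL,
    absence = if (length(absence)) do.call(rbind, absence) else NULL,
    scope = scope
  )
}

# Absence forms: the empty-collection EQ (characteristic bearer is
# `X-Collection and has_member only Nothing`) or the negated parthood
# (`not (has_part some (quality and characteristic_of some X))`).
match_absence_expr <- function(rhs, ont, config) {
  if (rhs$type == "not" && rhs$filler$type == "some" &&
      rhs$filler$property == "has_part") {
    inner <- rhs$filler$filler
    if (inner$type == "and" && length(inner$args) == 2L) {
      cls <- Filter(function(a) a$type == "class", inner$args)
      chr <- Filter(function(a) a$type == "some" &&
                      a$property == "characteristic_of" &&
                      a$filler$type == "class", inner$args)
      if (length(cls) == 1L && length(chr) == 1L) {
        return(list(form = "negative", entity = chr[[1L]]$filler$id))
      }
    }
    return(NULL)
  }
  if (rhs$type != "some" || rhs$property != "has_part") return(NULL)
  args <- if (rhs$filler$type == "and") rhs$filler$args else list(rhs$filler)
  coll <- NULL; modifier <- FALSE; genus <- NULL
  for (a in args) {
    if (a$type == "class") genus <- a$id
    else if (a$type == "some" && a$property == "characteristic_of" &&
             a$filler$type == "and") {
      parts <- a$filler$args
      cid <- Filter(function(p) p$type == "class", parts)
      empt <- Filter(function(p) p$type == "all" &&
                       p$property == "has_member" &&
                       p$filler$type == "nothing", parts)
      if (length(cid) == 1L && length(empt) == 1L) coll <- cid[[1L]]$id
    } else if (a$type == "some" && a$property == "has_modifier" &&
               a$filler$type == "class" && a$filler$id == config$abnormal_id) {
      modifier <- TRUE
    }
  }
  if (is.null(coll) || is.null(genus)) return(NULL)
  list(form = "empty", coll = coll, modifier = modifier)
}

#' Classify a rewritten ontology under the collection semantics
#'
#' Computes the entailed subsumption graph over phenotype and grouping
#' classes from the emitted axiom schemata:
#' amount phenotypes of one collection are ordered by their qualities and are
#' incomparable across collections (the collections are nominal singletons);
#' absence classes are ordered by the *dual* of the entity order (via the
#' negated-parthood definition); every phenotype of a collection falls under
#' that collection's grouping class, and under a quality grouping class when
#' its quality fits (every collection being under the root collection);
#' untouched plain-EQ classes keep the original-semantics rule; asserted
#' is-a edges and transitivity apply throughout.  Only equivalence-strength
#' definitions can acquire inferred subclasses.
#'
#' @param ont a `phen_ontology`, normally the output of [rewrite_ontology()].
#' @param config a [cardinality_config()].
#' @return a closed `subsumption_graph` over phenotype and grouping classes.
#' @export
classify_revised <- function(ont, config = cardinality_config()) {
  meta <- class_meta(ont, config)
  quality_keys <- key_set_of(subsumption_graph_of(ont, "quality"))
  entity_clos <- transitive_closure(subsumption_graph_of(ont, "entity"))
  coll_clos <- transitive_closure(subsumption_graph_of(ont, "collection"))
  bearer_keys <- c(entity_clos$key_set, coll_clos$key_set)
  edges <- list()
  p <- meta$pattern
  if (!is.null(p)) {
    edges$pattern <- pattern_edges(p$quality, p$bearer, p$id, p$modifier,
                                   p$strength, quality_keys, bearer_keys)
  }
  b <- meta$absence
  if (!is.null(b)) {
    if (anyNA(b$entity) || anyNA(b$coll)) {
      stop("absence class lacking one of its dual definitions: ",
           paste(b$id[is.na(b$entity) | is.na(b$coll)], collapse = ", "))
    }
    # duality: absent_X <= absent_Y iff Y <= X among the entities
    if (nrow(b) >= 2L) {
      g <- expand.grid(i = seq_len(nrow(b)), j = seq_len(nrow(b)))
      g <- g[g$i != g$j, , drop = FALSE]
      ok <- b$strength[g$j] == "equivalent" &
        in_keys(b$entity[g$j], b$entity[g$i], entity_clos$key_set)
      edges$absence <- data.frame(sub = b$id[g$i][ok], super = b$id[g$j][ok],
                                  stringsAsFactors = FALSE)
    }
    # absence under grouping-style pattern classes via the empty-collection
    # form (genus is the root quality)
    if (!is.null(p)) {
      g <- expand.grid(i = seq_len(nrow(b)), j = seq_len(nrow(p)))
      ok <- p$strength[g$j] == "equivalent" &
        (!p$modifier[g$j] | b$modifier[g$i]) &
        in_keys(rep(config$quality_root_id, nrow(g)), p$quality[g$j],
                quality_keys) &
        in_keys(b$coll[g$i], p$bearer[g$j], bearer_keys)
      edges$absence_grouping <- data.frame(sub = b$id[g$i][ok],
                                           super = p$id[g$j][ok],
                                           stringsAsFactors = FALSE)
    }
  }
  asserted <- ont$edges[ont$edges$sub %in% meta$scope &
                          ont$edges$super %in% meta$scope, , drop = FALSE]
  transitive_closure(subsumption_graph(
    meta$scope, do.call(rbind, c(edges, list(asserted)))))
}

#' Classify an ontology in a given mode
#'
#' Convenience wrapper: `mode = "original"` parses the plain EQ definitions
#' and applies [classify_original()]; `mode = "revised"` applies
#' [classify_revised()] (the ontology should then be a rewritten one).
#'
#' @param ont a `phen_ontology`.
#' @param mode `"original"` or `"revised"`.
#' @param config a [cardinality_config()].
#' @return a closed `subsumption_graph`.
#' @export
classify <- function(ont, mode = c("original", "revised"),
                     config = cardinality_config()) {
  mode <- match.arg(mode)
  if (mode == "revised") return(classify_revised(ont, config))
  ont <- canonicalize_eq_axioms(ont, config)
  defs <- list()
  for (ax in ont$axioms) {
    eqdef <- parse_eq_definition(ax, ont = ont, config = config)
    if (!is.null(eqdef)) defs[[length(defs) + 1L]] <- eqdef
  }
  scope <- class_ids(ont, c("phenotype", "grouping"))
  asserted <- ont$edges[ont$edges$sub %in% scope & ont$edges$super %in% scope,
                        , drop = FALSE]
  classify_original(defs,
                    transitive_closure(subsumption_graph_of(ont, "entity")),
                    transitive_closure(subsumption_graph_of(ont, "quality")),
                    asserted = asserted, nodes = scope)
}

# Structural subsumption between class expressions of the emitted fragment,
# relative to the reflexive-transitive closure of all asserted named edges.
expr_subsumes <- function(e1, e2, keys) {
  if (e1$type == "nothing") return(TRUE)
  if (e2$type == "and") {
    return(all(vapply(e2$args, function(a) expr_subsumes(e1, a, keys),
                      logical(1L))))
  }
  if (e1$type == "and") {
    return(any(vapply(e1$args, function(a) expr_subsumes(a, e2, keys),
                      logical(1L))))
  }
  switch(e2$type,
    class = e1$type == "class" &&
      (e1$id == e2$id || paste(e1$id, e2$id) %in% keys),
    some = e1$type == "some" && e1$property == e2$property &&
      expr_subsumes(e1$filler, e2$filler, keys),
    all = e1$type == "all" && e1$property == e2$property &&
      expr_subsumes(e1$filler, e2$filler, keys),
    not = e1$type == "not" && expr_subsumes(e2$filler, e1$filler, keys),
    one_of = e1$type == "one_of" && all(e1$individuals %in% e2$individuals),
    FALSE
  )
}

#' Naive saturation oracle for the fragment entailments
#'
#' Reference implementation used to verify the optimised classifiers:
#' exhaustively iterates over all ordered pairs of phenotype/grouping
#' classes, deriving `P1` is-a `P2` whenever some definition of `P1`
#' structurally subsumes under some equivalence-strength definition of `P2`
#' (recursive structural subsumption over the expression trees, relative to
#' the closure of all asserted named edges), then closes under transitivity;
#' repeats to a fixpoint.  No indexing, no pattern metadata.  Intended for
#' small inputs.
#'
#' @param ont a `phen_ontology` (original or rewritten).
#' @param mode `"original"` or `"revised"`; informational, the axioms of
#'   `ont` determine the semantics.
#' @param config a [cardinality_config()].
#' @return a closed `subsumption_graph` over phenotype and grouping classes.
#' @export
naive_saturation_oracle <- function(ont, mode = c("original", "revised"),
                                    config = cardinality_config()) {
  match.arg(mode)
  ont <- canonicalize_eq_axioms(ont, config)
  scope <- class_ids(ont, c("phenotype", "grouping"))
  n <- length(scope)
  keys <- key_set_of(subsumption_graph(class_ids(ont), ont$edges))
  defs <- lapply(scope, function(id) axioms_for(ont, id))
  names(defs) <- scope
  E <- diag(TRUE, n)
  dimnames(E) <- list(scope, scope)
  asserted <- ont$edges[ont$edges$sub %in% scope & ont$edges$super %in% scope,
                        , drop = FALSE]
  for (k in seq_len(nrow(asserted))) {
    E[asserted$sub[k], asserted$super[k]] <- TRUE
  }
  repeat {
    before <- sum(E)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (E[i, j]) next
        for (axj in defs[[j]]) {
          if (axj$strength != "equivalent") next
          for (axi in defs[[i]]) {
            if (expr_subsumes(axi$rhs, axj$rhs, keys)) {
              E[i, j] <- TRUE
              break
            }
          }
          if (E[i, j]) break
        }
      }
    }
    repeat {
      E2 <- E | (E %*% E > 0)
      if (identical(E2, E)) break
      E <- E2
    }
    if (sum(E) == before) break
  }
  idx <- which(E, arr.ind = TRUE)
  edges <- data.frame(sub = scope[idx[, 1L]], super = scope[idx[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$sub, edges$super), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = scope, edges = edges, closed = TRUE,
                 key_set = paste(edges$sub, edges$super)),
            class = "subsumption_graph")
}
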