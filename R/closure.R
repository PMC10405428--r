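# Subsumption graphs and their reflexive-transitive closure.

#' Subsumption graph
#'
#' A set of class nodes and ordered `(sub, super)` edges meaning
#' `sub` is-a `super`.  [transitive_closure()] computes the smallest
#' reflexive-transitive superset of the edges; most consumers (ancestor
#' queries, entailment tests, information content) operate on the closed
#' graph.
#'
#' @param nodes character vector of class ids.
#' @param edges data frame with character columns `sub` and `super`; every
#'   endpoint must be a node.
#' @return a `subsumption_graph` (with `closed = FALSE`).
#' @export
subsumption_graph <- function(nodes, edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(sub = character(), super = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- unique(data.frame(sub = as.character(edges$sub),
                             super = as.character(edges$super),
                             stringsAsFactors = FALSE))
  nodes <- sort(unique(as.character(nodes)))
  missing <- setdiff(unique(c(edges$sub, edges$super)), nodes)
  if (length(missing)) stop("edge endpoint not in node set: ",
                            paste(missing, collapse = ", "))
  edges <- edges[order(edges$sub, edges$super), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, closed = FALSE),
            class = "subsumption_graph")
}

reach_sets <- function(nodes, edges) {
  adj <- split(edges$super, factor(edges$sub, levels = nodes))
  reach <- vector("list", length(nodes))
  names(reach) <- nodes
  for (n in nodes) {
    seen <- n
    frontier <- adj[[n]]
    while (length(frontier)) {
      frontier <- setdiff(unique(frontier), seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
      frontier <- unlist(adj[frontier], use.names = FALSE)
    }
    reach[[n]] <- seen
  }
  reach
}

#' Reflexive-transitive closure of a subsumption graph
#'
#' Computes the deductive closure of the is-a fragment: the smallest edge set
#' containing the input edges that is reflexive and transitive.  Idempotent.
#' Non-trivial cycles (mutually reachable distinct nodes) are an input error;
#' equivalent classes must be merged beforehand (see [merge_equivalent()]).
#'
#' @param graph a `subsumption_graph`.
#' @return the closed graph (`closed = TRUE`), edges sorted.
#' @export
transitive_closure <- function(graph) {
  stopifnot(inherits(graph, "subsumption_graph"))
  if (isTRUE(graph$closed)) return(graph)
  reach <- reach_sets(graph$nodes, graph$edges)
  for (n in graph$nodes) {
    for (m in setdiff(reach[[n]], n)) {
      if (n %in% reach[[m]]) {
        stop("unmerged cycle in subsumption graph: ", n, " <-> ", m)
      }
    }
  }
  sub <- rep(graph$nodes, lengths(reach))
  super <- as.character(unlist(reach, use.names = FALSE))
  edges <- data.frame(sub = sub, super = super, stringsAsFactors = FALSE)
  edges <- edges[order(edges$sub, edges$super), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = graph$nodes, edges = edges, closed = TRUE,
                 key_set = paste(edges$sub, edges$super)),
            class = "subsumption_graph")
}

#' Ancestors and descendants in the closed graph
#'
#' `ancestors()` returns every class `a` with `id` is-a `a` in the closure,
#' including `id` itself; `descendants()` is the converse.
#'
#' @param graph a `subsumption_graph` (closed or not; closed internally).
#' @param id a node identifier.
#' @return character vector of class ids.
#' @export
ancestors <- function(graph, id) {
  graph <- transitive_closure(graph)
  if (!id %in% graph$nodes) stop("unknown class id: ", id)
  graph$edges$super[graph$edges$sub == id]
}

#' @rdname ancestors
#' @export
descendants <- function(graph, id) {
  graph <- transitive_closure(graph)
  if (!id %in% graph$nodes) stop("unknown class id: ", id)
  graph$edges$sub[graph$edges$super == id]
}

#' Entailment test on a closed subsumption graph
#'
#' @param graph a `subsumption_graph`.
#' @param sub_id,super_id node identifiers.
#' @return `TRUE` iff `sub_id` is-a `super_id` is in the closure.
#' @export
entails <- function(graph, sub_id, super_id) {
  graph <- transitive_closure(graph)
  for (i in c(sub_id, super_id)) {
    if (!i %in% graph$nodes) stop("unknown class id: ", i)
  }
  paste(sub_id, super_id) %in% graph$key_set
}

#' @export
print.subsumption_graph <- function(x, ...) {
  cat("<subsumption_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      if (isTRUE(x$closed)) " closed edges\n" else " asserted edges\n",
      sep = "")
  invisible(x)
}
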