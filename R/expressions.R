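# Class expressions for the description-logic fragment used by the rewrite:
# named classes, existential and universal restrictions, intersection,
# complement, nominal enumerations and the bottom concept.  Expressions are
# plain nested lists tagged with a `type` field; axioms pair a named class
# with an expression under a strength ("subclass" or "equivalent").

#' Class-expression constructors
#'
#' Build the class expressions that collection-rewritten phenotype axioms are
#' made of.  `ce_class()` names a declared class, `ce_some()`/`ce_all()` are
#' existential and universal restrictions over a relation, `ce_and()` is
#' intersection, `ce_not()` complement, `ce_one_of()` a nominal enumeration of
#' individuals and `ce_nothing()` the bottom concept (the empty class).
#'
#' @param id class identifier (CURIE-style string).
#' @param property relation name, e.g. `"has_part"` or `"has_member"`.
#' @param filler a class expression.
#' @param ... class expressions to intersect.
#' @param individuals character vector of individual identifiers.
#' @return a `class_expr` object.
#' @examples
#' ce_some("has_part", ce_and(ce_class("PATO:0001997"),
#'                            ce_some("characteristic_of", ce_class("CL:0000084"))))
#' @export
ce_class <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(type = "class", id = id), class = "class_expr")
}

#' @rdname ce_class
#' @export
ce_some <- function(property, filler) {
  structure(list(type = "some", property = property, filler = filler),
            class = "class_expr")
}

#' @rdname ce_class
#' @export
ce_all <- function(property, filler) {
  structure(list(type = "all", property = property, filler = filler),
            class = "class_expr")
}

#' @rdname ce_class
#' @export
ce_and <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && is.null(args[[1L]]$type)) {
    args <- args[[1L]]
  }
  stopifnot(length(args) >= 2L)
  structure(list(type = "and", args = args), class = "class_expr")
}

#' @rdname ce_class
#' @export
ce_not <- function(filler) {
  structure(list(type = "not", filler = filler), class = "class_expr")
}

#' @rdname ce_class
#' @export
ce_one_of <- function(individuals) {
  stopifnot(is.character(individuals), length(individuals) >= 1L)
  structure(list(type = "one_of", individuals = sort(individuals)),
            class = "class_expr")
}

#' @rdname ce_class
#' @export
ce_nothing <- function() {
  structure(list(type = "nothing"), class = "class_expr")
}

#' Deterministic string key of a class expression
#'
#' Used for equality tests, axiom deduplication and sorted serialisation.
#' Intersection arguments are sorted, so logically identical intersections in
#' different orders map to the same key.
#'
#' @param expr a `class_expr`.
#' @return a single string.
#' @export
expr_key <- function(expr) {
  switch(expr$type,
    class   = expr$id,
    nothing = "owl:Nothing",
    some    = paste0("some(", expr$property, ",", expr_key(expr$filler), ")"),
    all     = paste0("all(", expr$property, ",", expr_key(expr$filler), ")"),
    not     = paste0("not(", expr_key(expr$filler), ")"),
    one_of  = paste0("oneOf(", paste(expr$individuals, collapse = ","), ")"),
    and     = paste0("and(",
                     paste(sort(vapply(expr$args, expr_key, character(1L))),
                           collapse = ","),
                     ")"),
    stop("unknown expression type: ", expr$type)
  )
}

expr_equal <- function(a, b) identical(expr_key(a), expr_key(b))

#' @export
print.class_expr <- function(x, ...) {
  cat(expr_key(x), "\n")
  invisible(x)
}

# Axioms -----------------------------------------------------------------

#' Construct a subclass or equivalence axiom
#'
#' Axioms relate a declared class (`lhs`) to a class expression (`rhs`).
#' Plain named-to-named subclass assertions are stored as graph edges, not
#' axioms; these constructors are for logical definitions.
#'
#' @param lhs class identifier.
#' @param rhs a `class_expr`.
#' @return an `axiom` object with fields `strength`, `lhs`, `rhs`.
#' @export
subclass_axiom <- function(lhs, rhs) {
  structure(list(strength = "subclass", lhs = lhs, rhs = rhs),
            class = "axiom")
}

#' @rdname subclass_axiom
#' @export
equivalence_axiom <- function(lhs, rhs) {
  structure(list(strength = "equivalent", lhs = lhs, rhs = rhs),
            class = "axiom")
}

axiom_key <- function(ax) {
  paste0(ax$strength, "|", ax$lhs, "|", expr_key(ax$rhs))
}

#' @export
print.axiom <- function(x, ...) {
  op <- if (x$strength == "equivalent") "EquivalentTo" else "SubClassOf"
  cat(x$lhs, op, expr_key(x$rhs), "\n")
  invisible(x)
}
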