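# Information content, Resnik pairwise similarity and best-match-average
# profile similarity over a phenotype hierarchy and an annotation corpus.

#' Annotation corpus
#'
#' Maps annotated entities (genes and diseases) to sets of phenotype class
#' ids.  Entities with empty profiles are dropped with a warning.
#'
#' @param annotations named list; each element a character vector of
#'   phenotype class ids.
#' @param kind named character vector (`"gene"` or `"disease"`) with the
#'   same names as `annotations`.
#' @return an `annotation_corpus`.
#' @export
annotation_corpus <- function(annotations, kind) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  kind <- kind[names(annotations)]
  stopifnot(all(kind %in% c("gene", "disease")))
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  empty <- lengths(annotations) == 0L
  if (any(empty)) {
    warning("dropping entities with empty annotation profiles: ",
            paste(names(annotations)[empty], collapse = ", "))
    annotations <- annotations[!empty]
    kind <- kind[!empty]
  }
  structure(list(annotations = annotations, kind = kind),
            class = "annotation_corpus")
}

#' Merge two annotation corpora
#'
#' @param a,b `annotation_corpus` objects with disjoint entity ids.
#' @return the union corpus.
#' @export
merge_corpora <- function(a, b) {
  stopifnot(!any(names(a$annotations) %in% names(b$annotations)))
  annotation_corpus(c(a$annotations, b$annotations), c(a$kind, b$kind))
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("<annotation_corpus> ", length(x$annotations), " entities (",
      sum(x$kind == "gene"), " genes, ", sum(x$kind == "disease"),
      " diseases), ", sum(lengths(x$annotations)), " annotations\n", sep = "")
  invisible(x)
}

#' Information content of phenotype classes
#'
#' Propagates every entity's annotation profile to all its ancestors in the
#' (closed) hierarchy, estimates `p(class)` as the fraction of annotated
#' entities whose propagated profile contains the class, and returns
#' `IC = -log2(p)` in bits for classes with `p > 0`.  Classes never used
#' have no entry (and are thereby excluded as MICA candidates).
#'
#' @param corpus an `annotation_corpus` over genes and diseases.
#' @param hierarchy a `subsumption_graph` of the phenotype classes.
#' @return an `ic_table`: list with `ic` (named numeric, bits) and
#'   `corpus_size`.
#' @export
compute_ic <- function(corpus, hierarchy) {
  stopifnot(inherits(corpus, "annotation_corpus"),
            length(corpus$annotations) > 0L)
  hierarchy <- transitive_closure(hierarchy)
  unknown <- setdiff(unique(unlist(corpus$annotations)), hierarchy$nodes)
  if (length(unknown)) {
    stop("annotation to unknown class: ", paste(unknown, collapse = ", "))
  }
  anc <- split(hierarchy$edges$super,
               factor(hierarchy$edges$sub, levels = hierarchy$nodes))
  propagated <- lapply(corpus$annotations, function(profile) {
    unique(unlist(anc[profile], use.names = FALSE))
  })
  counts <- table(unlist(propagated, use.names = FALSE))
  n <- length(corpus$annotations)
  ic <- -log2(as.numeric(counts) / n)
  names(ic) <- names(counts)
  structure(list(ic = ic, corpus_size = n), class = "ic_table")
}

#' Resnik similarity of two classes
#'
#' The information content of the most informative common ancestor (MICA):
#' the maximum IC over common ancestors of `a` and `b` that have an IC
#' entry; 0 when no common ancestor is annotated.
#'
#' @param a,b phenotype class ids.
#' @param ic an `ic_table` from [compute_ic()].
#' @param hierarchy the `subsumption_graph` used for `ic`.
#' @return non-negative numeric (bits).
#' @export
resnik <- function(a, b, ic, hierarchy) {
  hierarchy <- transitive_closure(hierarchy)
  common <- intersect(ancestors(hierarchy, a), ancestors(hierarchy, b))
  vals <- ic$ic[intersect(common, names(ic$ic))]
  if (!length(vals)) 0 else max(vals)
}

# Precompute, per annotation class, the IC-bearing ancestors; pairwise Resnik
# is then a max over a named-vector intersection.
ancestor_ic_index <- function(classes, ic, hierarchy) {
  hierarchy <- transitive_closure(hierarchy)
  lapply(stats::setNames(classes, classes), function(cl) {
    a <- intersect(ancestors(hierarchy, cl), names(ic$ic))
    ic$ic[a]
  })
}

resnik_from_index <- function(a, b, index) {
  va <- index[[a]]
  vals <- va[intersect(names(va), names(index[[b]]))]
  if (!length(vals)) 0 else max(vals)
}

#' Best-match-average similarity of two annotation profiles
#'
#' The two-sided best-match average: for each gene annotation the maximum
#' Resnik similarity over the disease annotations, summed and divided by
#' twice the gene profile size, plus the symmetric disease-side term divided
#' by twice the disease profile size.
#'
#' @param gene_profile,disease_profile non-empty character vectors of
#'   phenotype class ids.
#' @inheritParams resnik
#' @return non-negative numeric.
#' @export
bma <- function(gene_profile, disease_profile, ic, hierarchy) {
  if (!length(gene_profile) || !length(disease_profile)) {
    stop("best-match average requires non-empty profiles")
  }
  index <- ancestor_ic_index(unique(c(gene_profile, disease_profile)), ic,
                             hierarchy)
  bma_from_index(gene_profile, disease_profile, index)
}

bma_from_index <- function(gene_profile, disease_profile, index) {
  m <- outer(gene_profile, disease_profile,
             Vectorize(function(a, b) resnik_from_index(a, b, index)))
  m <- matrix(m, nrow = length(gene_profile))
  sum(apply(m, 1L, max)) / (2 * length(gene_profile)) +
    sum(apply(m, 2L, max)) / (2 * length(disease_profile))
}
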