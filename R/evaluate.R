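# Gene ranking per disease and pooled ROC AUC under original vs revised
# phenotype hierarchies.

#' Rank genes by similarity score
#'
#' Descending-score order; tied scores receive the average of the tied rank
#' positions.
#'
#' @param scores named numeric vector (names are gene ids); missing values
#'   are an error.
#' @return data frame with columns `gene`, `score`, `rank`, sorted by rank.
#' @export
rank_genes <- function(scores) {
  if (is.null(names(scores)) || anyNA(scores)) {
    stop("scores must be a complete named numeric vector")
  }
  r <- rank(-scores, ties.method = "average")
  out <- data.frame(gene = names(scores), score = unname(scores),
                    rank = unname(r), stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled ROC AUC from scores and labels
#'
#' The fraction of (positive, negative) score comparisons won by the
#' positive, ties counting one half -- the normalised Mann-Whitney rank-sum
#' statistic.
#'
#' @param score numeric vector of similarity scores.
#' @param label logical vector; `TRUE` for true gene-disease pairs.
#' @return numeric in `[0, 1]`.
#' @export
roc_auc <- function(score, label) {
  stopifnot(length(score) == length(label), is.logical(label))
  npos <- sum(label); nneg <- sum(!label)
  if (npos == 0L || nneg == 0L) {
    stop("ROC AUC needs at least one positive and one negative pair")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate gene-disease association recovery under a hierarchy mode
#'
#' Composes the full task: classify the ontology in the requested mode
#' (rewriting it first for `"revised"`), compute information content over
#' the union corpus of genes and diseases, score every gene-disease pair
#' with the best-match average, rank genes per disease and compute the
#' pooled ROC AUC over all pairs against the association truth (with the
#' per-disease macro average alongside).  With `cardinality_only = TRUE`,
#' profiles are first restricted to detected cardinality phenotype classes
#' and entities left with empty profiles are dropped.
#'
#' @param ont a `phen_ontology` (original, un-rewritten axioms).
#' @param genes,diseases `annotation_corpus` objects.
#' @param truth data frame of known associations with columns `gene`,
#'   `disease`.
#' @param mode `"original"` or `"revised"`.
#' @param config a [cardinality_config()].
#' @param cardinality_only restrict profiles to cardinality phenotypes.
#' @return a `phen_eval`: list with `mode`, `auc` (pooled), `macro_auc`,
#'   `per_disease` (data frame of true-gene ranks), `scores` matrix,
#'   `n_genes`, `n_diseases`.
#' @export
evaluate_associations <- function(ont, genes, diseases, truth,
                                  mode = c("original", "revised"),
                                  config = cardinality_config(),
                                  cardinality_only = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "disease") %in% names(truth)))
  if (cardinality_only) {
    keep <- vapply(detect_cardinality_phenotypes(ont, config), `[[`,
                   character(1L), "phenotype_id")
    restrict <- function(corpus) {
      pruned <- lapply(corpus$annotations, function(p) intersect(p, keep))
      annotation_corpus(pruned, corpus$kind)
    }
    genes <- restrict(genes)
    diseases <- restrict(diseases)
  }
  hierarchy <- if (mode == "revised") {
    classify_revised(if (inherits(ont, "rewritten_ontology")) ont else
      rewrite_ontology(ont, config), config)
  } else {
    classify(ont, "original", config)
  }
  corpus <- merge_corpora(genes, diseases)
  ic <- compute_ic(corpus, hierarchy)
  gene_ids <- sort(names(genes$annotations))
  disease_ids <- sort(names(diseases$annotations))
  index <- ancestor_ic_index(unique(unlist(corpus$annotations)), ic,
                             hierarchy)
  scores <- matrix(0, length(gene_ids), length(disease_ids),
                   dimnames = list(gene_ids, disease_ids))
  for (d in disease_ids) {
    dp <- diseases$annotations[[d]]
    for (g in gene_ids) {
      scores[g, d] <- bma_from_index(genes$annotations[[g]], dp, index)
    }
  }
  truth <- unique(truth[truth$gene %in% gene_ids &
                          truth$disease %in% disease_ids, c("gene", "disease")])
  pair_label <- matrix(FALSE, length(gene_ids), length(disease_ids),
                       dimnames = dimnames(scores))
  for (k in seq_len(nrow(truth))) {
    pair_label[truth$gene[k], truth$disease[k]] <- TRUE
  }
  auc <- roc_auc(as.vector(scores), as.vector(pair_label))
  per_disease <- list(); macro <- c()
  for (d in disease_ids) {
    ranks <- rank_genes(scores[, d])
    pos <- truth$gene[truth$disease == d]
    if (length(pos)) {
      per_disease[[d]] <- data.frame(
        disease = d, gene = pos,
        rank = ranks$rank[match(pos, ranks$gene)],
        stringsAsFactors = FALSE)
      if (length(pos) < length(gene_ids)) {
        macro <- c(macro, roc_auc(scores[, d], gene_ids %in% pos))
      }
    }
  }
  per_disease <- if (length(per_disease)) do.call(rbind, per_disease) else
    data.frame(disease = character(), gene = character(), rank = numeric(),
               stringsAsFactors = FALSE)
  rownames(per_disease) <- NULL
  structure(list(mode = mode, auc = auc,
                 macro_auc = if (length(macro)) mean(macro) else NA_real_,
                 per_disease = per_disease, scores = scores,
                 n_genes = length(gene_ids),
                 n_diseases = length(disease_ids)),
            class = "phen_eval")
}

#' @export
print.phen_eval <- function(x, ...) {
  cat("<phen_eval> mode=", x$mode, ": pooled ROC AUC = ",
      format(x$auc, digits = 4), " (macro ",
      format(x$macro_auc, digits = 4), ") over ", x$n_genes, " genes x ",
      x$n_diseases, " diseases\n", sep = "")
  invisible(x)
}
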