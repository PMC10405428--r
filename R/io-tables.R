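# Tab-separated readers for annotation corpora, association truth sets and
# cross-ontology equivalence mappings.  All three are simplified 2-column
# TSVs ('#' comments allowed); a one-line column extraction converts the
# multi-column model-organism report files into this shape.

read_tsv2 <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(what, " file ", path, ": expected 2 tab-separated columns at line ",
         keep[bad[1L]])
  }
  data.frame(a = trimws(vapply(parts, `[[`, character(1L), 1L)),
             b = trimws(vapply(parts, `[[`, character(1L), 2L)),
             stringsAsFactors = FALSE)
}

#' Read an annotation corpus from a 2-column TSV
#'
#' Columns: annotated entity id (gene or disease), phenotype class id.
#' Duplicates are dropped with a message.  When an ontology is supplied,
#' phenotype ids are resolved through its synonym table and unknown ids are
#' an error.
#'
#' @param path file path.
#' @param kind `"gene"` or `"disease"` for all entities in the file.
#' @param ont optional `phen_ontology` for validation.
#' @return an `annotation_corpus`.
#' @export
read_annotations <- function(path, kind = c("gene", "disease"), ont = NULL) {
  kind <- match.arg(kind)
  d <- read_tsv2(path, "annotation")
  ndup <- sum(duplicated(d))
  if (ndup) message("deduplicated ", ndup, " annotation(s) in ", path)
  d <- unique(d)
  if (!is.null(ont)) {
    d$b <- resolve_id(ont, d$b)
    unknown <- unique(d$b[!has_class(ont, d$b)])
    if (length(unknown)) {
      stop("annotation to unknown class: ", paste(unknown, collapse = ", "))
    }
  }
  annotations <- split(d$b, d$a)
  annotation_corpus(annotations,
                    stats::setNames(rep(kind, length(annotations)),
                                    names(annotations)))
}

#' Read a gene-disease association truth set from a 2-column TSV
#'
#' Columns: gene id, disease id.  Duplicates are dropped with a message.
#'
#' @param path file path.
#' @return data frame with columns `gene`, `disease`.
#' @export
read_associations <- function(path) {
  d <- read_tsv2(path, "association")
  ndup <- sum(duplicated(d))
  if (ndup) message("deduplicated ", ndup, " association(s) in ", path)
  d <- unique(d)
  data.frame(gene = d$a, disease = d$b, stringsAsFactors = FALSE)
}

#' Read a cross-ontology equivalence mapping from a 2-column TSV
#'
#' Columns: id_a, id_b, read as class equivalences.
#'
#' @param path file path.
#' @return data frame with columns `id_a`, `id_b`.
#' @export
read_mapping <- function(path) {
  d <- unique(read_tsv2(path, "mapping"))
  data.frame(id_a = d$a, id_b = d$b, stringsAsFactors = FALSE)
}

#' Merge equivalent classes from a mapping table
#'
#' Applies [merge_equivalent()] for every mapping pair.  Pairs naming
#' unknown classes are skipped with a warning (default) or are an error.
#'
#' @param ont a `phen_ontology`.
#' @param mapping data frame from [read_mapping()].
#' @param on_missing `"warn_skip"` or `"error"`.
#' @return the updated ontology.
#' @export
apply_mapping <- function(ont, mapping, on_missing = c("warn_skip", "error")) {
  on_missing <- match.arg(on_missing)
  for (k in seq_len(nrow(mapping))) {
    a <- mapping$id_a[k]; b <- mapping$id_b[k]
    if (!has_class(ont, a) || !has_class(ont, b)) {
      if (on_missing == "error") {
        stop("mapping names unknown class: ", a, " / ", b)
      }
      warning("skipping mapping with unknown class: ", a, " / ", b)
      next
    }
    ont <- merge_equivalent(ont, a, b)
  }
  ont
}

#' Write a similarity score table
#'
#' @param scores matrix from [evaluate_associations()] (`genes` x
#'   `diseases`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(scores, path) {
  d <- data.frame(gene = rep(rownames(scores), ncol(scores)),
                  disease = rep(colnames(scores), each = nrow(scores)),
                  bma = as.vector(scores), stringsAsFactors = FALSE)
  d <- d[order(d$gene, d$disease), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
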