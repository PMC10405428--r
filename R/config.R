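# Configuration for cardinality-phenotype detection and rewriting.

#' Cardinality-phenotype configuration
#'
#' Bundles the quality-ontology anchors and the identifier scheme used when
#' detecting cardinality phenotypes and generating collection, rewritten and
#' grouping classes.  The defaults use the PATO identifiers for the *amount*
#' branch: `amount` (PATO:0000070) as the root of the cardinality qualities,
#' `absent` (PATO:0000462) as the absence quality, `quality` (PATO:0000001)
#' as the root quality and `abnormal` (PATO:0000460) as the modifier.
#'
#' @param amount_root_id quality class id under which a quality must fall for
#'   a phenotype to count as a cardinality phenotype.
#' @param absence_ids quality ids read as "absence"; rewrites of these use
#'   the dual empty-collection / negated-parthood definitions.
#' @param quality_root_id root of the quality hierarchy; the genus of
#'   collection grouping classes and of the rewritten absence definitions.
#' @param abnormal_id the abnormal modifier class.
#' @param entity_prefixes CURIE prefixes of entities eligible for rewriting
#'   (default `"CL"`, i.e. cell types); `NULL` disables the filter.
#' @param root_collection_id,root_collection_label the single root collection
#'   class every generated collection is asserted under.
#' @param phenotype_root_id optional phenotype class under which generated
#'   grouping classes are asserted (so they share a root with the phenotype
#'   hierarchy, giving the root zero information content).
#' @param collection_prefix,grouping_entity_prefix,grouping_quality_prefix,individual_prefix
#'   CURIE prefixes of generated collection classes, by-collection grouping
#'   classes, by-quality grouping classes and nominal individuals.  Generated
#'   local identifiers are the source identifier with `:` replaced by `_`, so
#'   ids are deterministic and collision-free against input ontologies that
#'   do not use these prefixes.
#' @return a `cardinality_config` object.
#' @export
cardinality_config <- function(amount_root_id = "PATO:0000070",
                               absence_ids = "PATO:0000462",
                               quality_root_id = "PATO:0000001",
                               abnormal_id = "PATO:0000460",
                               entity_prefixes = "CL",
                               root_collection_id = "COLL:0000000",
                               root_collection_label = "collection of cells",
                               phenotype_root_id = NULL,
                               collection_prefix = "COLL",
                               grouping_entity_prefix = "GXP",
                               grouping_quality_prefix = "GQ",
                               individual_prefix = "IND") {
  structure(list(
    amount_root_id = amount_root_id,
    absence_ids = absence_ids,
    quality_root_id = quality_root_id,
    abnormal_id = abnormal_id,
    entity_prefixes = entity_prefixes,
    root_collection_id = root_collection_id,
    root_collection_label = root_collection_label,
    phenotype_root_id = phenotype_root_id,
    collection_prefix = collection_prefix,
    grouping_entity_prefix = grouping_entity_prefix,
    grouping_quality_prefix = grouping_quality_prefix,
    individual_prefix = individual_prefix
  ), class = "cardinality_config")
}

curie_prefix <- function(id) sub(":.*$", "", id)

mangle_id <- function(id) gsub(":", "_", id, fixed = TRUE)

collection_id_for <- function(entity_id, config) {
  paste0(config$collection_prefix, ":", mangle_id(entity_id))
}

collection_individual_for <- function(entity_id, config) {
  paste0(config$individual_prefix, ":", mangle_id(entity_id), "-collection")
}

grouping_entity_id_for <- function(entity_id, config) {
  paste0(config$grouping_entity_prefix, ":", mangle_id(entity_id))
}

grouping_quality_id_for <- function(quality_id, config) {
  paste0(config$grouping_quality_prefix, ":", mangle_id(quality_id))
}
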