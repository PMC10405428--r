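# Seeded generators for toy entity hierarchies, cardinality phenotype
# ontologies and annotated gene/disease corpora with planted associations and
# the sibling-subtype confound, so every other module is testable without
# external downloads.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

FIXTURE_QUALITY_LABELS <- c(
  "PATO:0000470" = "increased amount",
  "PATO:0001997" = "decreased amount",
  "PATO:0000462" = "absent"
)

#' Synthetic fixture specification
#'
#' Defines the study conditions of the synthetic benchmark: a rooted
#' entity tree (`branching` children per node down to `depth`), one
#' cardinality phenotype class per entity and quality, and annotated
#' gene/disease corpora in which each disease has one focus entity, its true
#' gene shares phenotypes of the same entity (or its direct parent), and
#' confounded decoy genes carry phenotypes of a *sibling* subtype of the
#' focus entity -- precisely the topology in which the original EQ semantics
#' links decoys to the disease through the shared parent phenotype while the
#' collection semantics does not.
#'
#' @param depth tree depth of the entity hierarchy (root is depth 0).
#' @param branching children per node; at least 2 so siblings exist.
#' @param qualities quality class ids; defaults to increased amount,
#'   decreased amount and absent.
#' @param n_genes,n_diseases corpus sizes (`n_genes >= n_diseases`; the
#'   first `n_diseases` genes are the planted true genes).
#' @param annotations_per_profile annotations drawn per profile.
#' @param confound_rate fraction of decoy genes annotated with
#'   sibling-subtype phenotypes (the rest get random profiles).
#' @param noise_rate per-annotation probability of replacement by a
#'   uniformly random phenotype class.
#' @param seed integer; all randomness flows from it.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(depth = 3, branching = 2,
                         qualities = names(FIXTURE_QUALITY_LABELS),
                         n_genes = 30, n_diseases = 10,
                         annotations_per_profile = 3,
                         confound_rate = 1, noise_rate = 0.1, seed = 1) {
  stopifnot(depth >= 1, branching >= 2, length(qualities) >= 1,
            n_genes >= n_diseases, n_diseases >= 1,
            annotations_per_profile >= 1,
            confound_rate >= 0, confound_rate <= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(depth = depth, branching = branching, qualities = qualities,
                 n_genes = n_genes, n_diseases = n_diseases,
                 annotations_per_profile = annotations_per_profile,
                 confound_rate = confound_rate, noise_rate = noise_rate,
                 seed = seed),
            class = "fixture_spec")
}

#' Configuration matching the synthetic fixtures
#'
#' @return a [cardinality_config()] with the fixture phenotype root set.
#' @export
fixture_config <- function() {
  cardinality_config(phenotype_root_id = "MP:0000000")
}

#' Generate a rooted entity tree ontology
#'
#' A full `branching`-ary tree of cell-type classes down to `depth`; labels
#' encode the tree position ("cell 1.2" is the second child of the first
#' child of the root).
#'
#' @param spec a `fixture_spec`.
#' @return a `phen_ontology` of entity classes.
#' @export
generate_entity_ontology <- function(spec) {
  ont <- ontology("synthetic-entities")
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("CL:%07d", counter)
  }
  root <- "CL:0000000"
  ont <- add_class(ont, root, label = "cell", namespace = "entity")
  frontier <- data.frame(id = root, path = "", d = 0L,
                         stringsAsFactors = FALSE)
  while (nrow(frontier)) {
    nxt <- list()
    for (k in seq_len(nrow(frontier))) {
      if (frontier$d[k] >= spec$depth) next
      for (b in seq_len(spec$branching)) {
        id <- next_id()
        path <- if (nzchar(frontier$path[k])) {
          paste0(frontier$path[k], ".", b)
        } else as.character(b)
        ont <- add_class(ont, id, label = paste("cell", path),
                         namespace = "entity")
        ont <- add_subclass(ont, id, frontier$id[k])
        nxt[[length(nxt) + 1L]] <- data.frame(id = id, path = path,
                                              d = frontier$d[k] + 1L,
                                              stringsAsFactors = FALSE)
      }
    }
    frontier <- if (length(nxt)) do.call(rbind, nxt) else frontier[0, ]
  }
  ont
}

#' Generate a cardinality phenotype ontology over an entity tree
#'
#' Adds a minimal quality hierarchy (root quality, *amount*, the chosen
#' qualities as children of *amount*, and the abnormal modifier), a
#' phenotype root class, and one equivalence-strength EQ definition per
#' (entity, quality) pair in the canonical pattern with the abnormal
#' modifier.  A `phenotype_index` attribute maps (entity, quality) to the
#' generated phenotype id.
#'
#' @param entity_ont output of [generate_entity_ontology()].
#' @param spec a `fixture_spec`.
#' @return a `phen_ontology` with EQ definitions.
#' @export
generate_phenotype_ontology <- function(entity_ont, spec) {
  config <- fixture_config()
  ont <- entity_ont
  ont$name <- "synthetic-phenotypes"
  ont <- add_class(ont, config$quality_root_id, label = "quality",
                   namespace = "quality")
  ont <- add_class(ont, config$amount_root_id, label = "amount",
                   namespace = "quality")
  ont <- add_subclass(ont, config$amount_root_id, config$quality_root_id)
  ont <- add_class(ont, config$abnormal_id, label = "abnormal",
                   namespace = "quality")
  ont <- add_subclass(ont, config$abnormal_id, config$quality_root_id)
  for (q in spec$qualities) {
    lab <- FIXTURE_QUALITY_LABELS[q]
    if (is.na(lab)) lab <- q
    ont <- add_class(ont, q, label = unname(lab), namespace = "quality")
    ont <- add_subclass(ont, q, config$amount_root_id)
  }
  ont <- add_class(ont, config$phenotype_root_id, label = "phenotype",
                   namespace = "phenotype")
  entities <- class_ids(ont, "entity")
  counter <- 0L
  rows <- list()
  for (e in entities) {
    for (q in spec$qualities) {
      counter <- counter + 1L
      pid <- sprintf("MP:%07d", counter)
      ont <- add_class(ont, pid,
                       label = paste(class_label(ont, q),
                                     class_label(ont, e)),
                       namespace = "phenotype")
      ont <- add_subclass(ont, pid, config$phenotype_root_id)
      ont <- add_axiom(ont, equivalence_axiom(
        pid, canonical_eq_rhs(q, ce_class(e), TRUE, config)))
      rows[[counter]] <- data.frame(entity = e, quality = q, phenotype = pid,
                                    stringsAsFactors = FALSE)
    }
  }
  attr(ont, "phenotype_index") <- do.call(rbind, rows)
  ont
}

#' Generate annotated gene/disease corpora with planted associations
#'
#' Each disease is assigned a non-root focus entity with at least one
#' sibling; its profile holds that entity's phenotypes across the spec's
#' qualities.  The matching true gene carries the same phenotypes, each
#' annotation drawn over the focus entity or (with probability 1/4) its
#' direct parent.  Each remaining gene is a decoy for one disease: with
#' probability `confound_rate` it carries the phenotypes of a *sibling* of
#' the focus entity (same qualities); otherwise a uniformly random profile.
#' Every annotation is finally replaced by a uniformly random phenotype
#' class with probability `noise_rate`.  All randomness flows from
#' `spec$seed`; identical specs give identical corpora.
#'
#' @param pheno_ont output of [generate_phenotype_ontology()].
#' @param spec a `fixture_spec`.
#' @return list with `genes` and `diseases` (`annotation_corpus`) and
#'   `truth` (data frame `gene`, `disease`).
#' @export
generate_annotated_corpus <- function(pheno_ont, spec) {
  idx <- attr(pheno_ont, "phenotype_index")
  if (is.null(idx)) {
    stop("phenotype ontology must come from generate_phenotype_ontology()")
  }
  if (spec$annotations_per_profile > nrow(idx)) {
    stop("spec demands more annotations per profile (",
         spec$annotations_per_profile, ") than phenotype classes available (",
         nrow(idx), ")")
  }
  ent_edges <- pheno_ont$edges[
    pheno_ont$edges$sub %in% class_ids(pheno_ont, "entity") &
      pheno_ont$edges$super %in% class_ids(pheno_ont, "entity"), ,
    drop = FALSE]
  parent <- stats::setNames(ent_edges$super, ent_edges$sub)
  siblings_of <- function(e) {
    sibs <- names(parent)[parent == parent[[e]]]
    setdiff(sibs, e)
  }
  eligible <- names(parent)[vapply(names(parent),
                                   function(e) length(siblings_of(e)) > 0L,
                                   logical(1L))]
  stopifnot(length(eligible) > 0L)
  pheno_for <- function(entities, qualities) {
    vapply(seq_along(entities), function(k) {
      idx$phenotype[idx$entity == entities[k] & idx$quality == qualities[k]]
    }, character(1L))
  }
  qs <- rep(spec$qualities, length.out = spec$annotations_per_profile)
  all_phenos <- idx$phenotype
  with_seed(spec$seed, {
    focus <- sample(eligible, spec$n_diseases,
                    replace = spec$n_diseases > length(eligible))
    add_noise <- function(profile) {
      hit <- stats::runif(length(profile)) < spec$noise_rate
      profile[hit] <- sample(all_phenos, sum(hit), replace = TRUE)
      profile
    }
    diseases <- lapply(seq_len(spec$n_diseases), function(i) {
      unique(add_noise(pheno_for(rep(focus[i], length(qs)), qs)))
    })
    names(diseases) <- sprintf("D:%04d", seq_len(spec$n_diseases))
    genes <- vector("list", spec$n_genes)
    names(genes) <- sprintf("G:%04d", seq_len(spec$n_genes))
    for (i in seq_len(spec$n_diseases)) {
      ents <- ifelse(stats::runif(length(qs)) < 0.25,
                     unname(parent[focus[i]]), focus[i])
      genes[[i]] <- unique(add_noise(pheno_for(ents, qs)))
    }
    decoys <- setdiff(seq_len(spec$n_genes), seq_len(spec$n_diseases))
    for (k in seq_along(decoys)) {
      i <- decoys[k]
      d <- ((k - 1L) %% spec$n_diseases) + 1L
      if (stats::runif(1L) < spec$confound_rate) {
        sib <- sample(siblings_of(focus[d]), 1L)
        genes[[i]] <- unique(add_noise(pheno_for(rep(sib, length(qs)), qs)))
      } else {
        genes[[i]] <- unique(add_noise(
          sample(all_phenos, spec$annotations_per_profile)))
      }
    }
    list(
      genes = annotation_corpus(genes,
                                stats::setNames(rep("gene", length(genes)),
                                                names(genes))),
      diseases = annotation_corpus(
        diseases, stats::setNames(rep("disease", length(diseases)),
                                  names(diseases))),
      truth = data.frame(gene = names(genes)[seq_len(spec$n_diseases)],
                         disease = names(diseases),
                         stringsAsFactors = FALSE)
    )
  })
}

#' The frozen two-cell-type mini fixture
#'
#' Loads the hand-written OBO fixture shipped with the package: a T cell /
#' NK T cell entity pair with decreased-number and absence phenotypes of
#' each, the minimal quality hierarchy and a phenotype root.  This is the
#' fixture on which the before/after entailment contrast is demonstrated.
#'
#' @return a `phen_ontology`.
#' @export
fig_fixture_ontology <- function() {
  path <- system.file("extdata", "tcell_mini.obo", package = "cardphen",
                      mustWork = TRUE)
  read_obo(path)
}

#' @rdname fig_fixture_ontology
#' @export
fig_fixture_config <- function() {
  cardinality_config(phenotype_root_id = "MP:0000001")
}
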