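# collection classes, partonomy materialisation, phenotype rewriting,
# grouping classes and the composed rewrite pipeline

test_that("a collection class carries its three axioms and is idempotent", {
  cfg <- chain_config()
  ont <- chain_fixture()
  ont <- make_collection_class(ont, "CL:0000002", cfg)
  colls <- collection_classes(ont, cfg)
  expect_equal(nrow(colls), 1L)
  expect_identical(colls$member_class_id, "CL:0000002")
  cid <- colls$id
  keys <- vapply(ont$axioms, cardphen:::axiom_key, character(1L))
  expect_true(any(grepl(paste0("subclass\\|", cid, "\\|all\\(has_member"),
                        keys)))
  expect_true(any(grepl("subclass\\|CL:0000002\\|some\\(member_of", keys)))
  expect_true(any(grepl(paste0("equivalent\\|", cid, "\\|oneOf"), keys)))
  # asserted under the root collection class
  expect_true(has_class(ont, cfg$root_collection_id))
  expect_true(paste(cid, cfg$root_collection_id) %in%
                paste(ont$edges$sub, ont$edges$super))
  again <- make_collection_class(ont, "CL:0000002", cfg)
  expect_identical(again$axioms, ont$axioms)
  expect_identical(class_ids(again), class_ids(ont))
})

test_that("distinct entities get distinct nominal individuals", {
  cfg <- chain_config()
  ont <- chain_fixture()
  ont <- make_collection_class(ont, "CL:0000002", cfg)
  ont <- make_collection_class(ont, "CL:0000003", cfg)
  colls <- collection_classes(ont, cfg)
  expect_equal(nrow(colls), 2L)
  expect_false(anyDuplicated(colls$nominal_individual_id) > 0L)
})

test_that("partonomy materialisation follows the non-reflexive closure", {
  cfg <- chain_config()
  ont <- chain_fixture()
  for (e in c("CL:0000001", "CL:0000002", "CL:0000003")) {
    ont <- make_collection_class(ont, e, cfg)
  }
  ont <- materialize_partonomy(ont, cfg)
  p <- partonomy_axioms(ont)
  expect_equal(nrow(p), 3L)  # NK->T, NK->lymphocyte, T->lymphocyte
  # single entity with no superclasses: nothing to assert
  o2 <- ontology()
  o2 <- add_class(o2, "CL:0000009", "solo", "entity")
  o2 <- make_collection_class(o2, "CL:0000009", chain_config())
  o2 <- materialize_partonomy(o2, chain_config())
  expect_equal(nrow(partonomy_axioms(o2)), 0L)
})

test_that("partonomy count equals the closure-pair count on random DAGs", {
  cfg <- cardinality_config()
  for (seed in c(3, 9)) {
    dag <- random_dag(10L, p = 0.2, seed = seed)
    ont <- ontology()
    for (n in dag$nodes) {
      ont <- add_class(ont, sub("^N", "CL", n), n, "entity")
    }
    for (k in seq_len(nrow(dag$edges))) {
      ont <- add_subclass(ont, sub("^N", "CL", dag$edges$sub[k]),
                          sub("^N", "CL", dag$edges$super[k]))
    }
    for (id in class_ids(ont, "entity")) {
      ont <- make_collection_class(ont, id, cfg)
    }
    ont <- materialize_partonomy(ont, cfg)
    clos <- transitive_closure(subsumption_graph_of(ont, "entity"))
    expect_equal(nrow(partonomy_axioms(ont)),
                 sum(clos$edges$sub != clos$edges$super))
  }
})

test_that("amount rewriting swaps the entity for its collection", {
  cfg <- chain_config()
  ont <- chain_fixture()
  ont <- make_collection_class(ont, "CL:0000002", cfg)
  eqdef <- eq_definition("MP:0000003", "PATO:0001997", "CL:0000002")
  ont2 <- rewrite_phenotype(ont, eqdef, cfg)
  axs <- axioms_for(ont2, "MP:0000003")
  expect_length(axs, 1L)
  d <- parse_eq_definition(axs[[1L]], config = cfg)
  expect_identical(d$entity_id, cardphen:::collection_id_for("CL:0000002",
                                                             cfg))
  expect_identical(d$quality_id, "PATO:0001997")
  expect_true(d$has_abnormal_modifier)
  expect_identical(d$strength, "equivalent")
})

test_that("absence rewriting attaches both dual forms to one class", {
  cfg <- chain_config()
  ont <- chain_fixture()
  ont <- make_collection_class(ont, "CL:0000002", cfg)
  eqdef <- eq_definition("MP:0000004", "PATO:0000462", "CL:0000002")
  ont2 <- rewrite_phenotype(ont, eqdef, cfg)
  axs <- axioms_for(ont2, "MP:0000004")
  expect_length(axs, 2L)
  forms <- vapply(axs, function(ax) {
    a <- cardphen:::match_absence_expr(ax$rhs, ont2, cfg)
    if (is.null(a)) "none" else a$form
  }, character(1L))
  expect_setequal(forms, c("empty", "negative"))
  expect_true(all(vapply(axs, `[[`, character(1L), "strength") ==
                    "equivalent"))
})

test_that("rewriting refuses non-cardinality input and missing collections", {
  cfg <- chain_config()
  ont <- mixed_ontology()
  split_def <- eq_definition("MP:0005170", "PATO:0001786", "UBERON:0001834")
  expect_error(rewrite_phenotype(ont, split_def, cfg), "not a cardinality")
  card_def <- eq_definition("MP:0005018", "PATO:0001997", "CL:0000084")
  expect_error(rewrite_phenotype(ont, card_def, cfg), "collection")
})

test_that("grouping classes count one per collection plus one per quality", {
  cfg <- chain_config()
  ont <- chain_fixture()
  for (e in c("CL:0000001", "CL:0000002", "CL:0000003")) {
    ont <- make_collection_class(ont, e, cfg)
  }
  ont <- make_grouping_classes(ont, c("PATO:0000470", "PATO:0001997"), cfg)
  g <- class_ids(ont, "grouping")
  expect_length(g, 5L)
  expect_length(grep("^GXP:", g), 3L)
  expect_length(grep("^GQ:", g), 2L)
  # degenerate input: no collections, only the by-quality classes over C
  o2 <- make_grouping_classes(ontology(), "PATO:0001997", cfg)
  expect_identical(class_ids(o2, "grouping"),
                   cardphen:::grouping_quality_id_for("PATO:0001997", cfg))
})

test_that("the composed rewrite yields the closed-form fixture counts", {
  cfg <- chain_config()
  ont <- chain_fixture()     # 3 entities in a chain x 3 qualities
  rw <- rewrite_ontology(ont, cfg)
  expect_equal(unname(rw$rewrite_summary["collections"]), 3)
  expect_equal(unname(rw$rewrite_summary["rewritten"]), 9)
  expect_equal(unname(rw$rewrite_summary["grouping"]), 6)  # 3 CXP + 3 CQ
  expect_equal(unname(rw$rewrite_summary["partonomy"]), 3)
  # generated ids never collide with input ids
  expect_equal(anyDuplicated(class_ids(rw)), 0L)
  # provenance covers every generated class
  gen <- setdiff(class_ids(rw), c(class_ids(ont), cfg$root_collection_id))
  expect_true(all(gen %in% rw$provenance$generated_id))
})

test_that("rewriting nothing adds only the root collection class", {
  cfg <- cardinality_config()
  ont <- ontology()
  ont <- add_quality_scaffold(ont, extra = "PATO:0001786")  # split
  ont <- add_class(ont, "UBERON:0001834", "upper lip", "entity")
  ont <- add_class(ont, "MP:0005170", "cleft upper lip", "phenotype")
  ont <- add_axiom(ont, eq_axiom("MP:0005170", "PATO:0001786",
                                 "UBERON:0001834"))
  rw <- rewrite_ontology(ont, cfg)
  expect_setequal(setdiff(class_ids(rw), class_ids(ont)),
                  cfg$root_collection_id)
  expect_identical(rw$axioms, ont$axioms)
})

test_that("rewriting is a fixpoint", {
  cfg <- chain_config()
  rw <- rewrite_ontology(chain_fixture(), cfg)
  rw2 <- rewrite_ontology(rw, cfg)
  expect_identical(class_ids(rw2), class_ids(rw))
  expect_identical(vapply(rw2$axioms, cardphen:::axiom_key, character(1L)),
                   vapply(rw$axioms, cardphen:::axiom_key, character(1L)))
  expect_identical(rw2$edges, rw$edges)
})
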