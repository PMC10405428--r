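# EQ definition parsing and cardinality-phenotype detection

test_that("the canonical EQ axiom parses with all components", {
  cfg <- cardinality_config()
  ax <- eq_axiom("MP:0005018", "PATO:0001997", "CL:0000084")
  d <- parse_eq_definition(ax, config = cfg)
  expect_s3_class(d, "eq_definition")
  expect_identical(d$phenotype_id, "MP:0005018")
  expect_identical(d$quality_id, "PATO:0001997")
  expect_identical(d$entity_id, "CL:0000084")
  expect_true(d$has_abnormal_modifier)
  expect_identical(d$strength, "equivalent")
})

test_that("absence definitions and subclass strength are recorded", {
  cfg <- cardinality_config()
  d <- parse_eq_definition(eq_axiom("MP:0008070", "PATO:0000462",
                                    "CL:0000084"), config = cfg)
  expect_identical(d$quality_id, "PATO:0000462")
  d2 <- parse_eq_definition(eq_axiom("MP:0000010", "PATO:0001997",
                                     "CL:0000084", strength = "subclass"),
                            config = cfg)
  expect_identical(d2$strength, "subclass")
})

test_that("non-matching axioms yield NULL and are left untouched", {
  cfg <- cardinality_config()
  ax <- subclass_axiom("MP:0000002",
                       ce_some("part_of", ce_class("CL:0000084")))
  expect_null(parse_eq_definition(ax, config = cfg))
  ax2 <- subclass_axiom("MP:0000002", ce_all("has_member",
                                             ce_class("CL:0000084")))
  expect_null(parse_eq_definition(ax2, config = cfg))
})

test_that("the modifier-outside nesting is accepted and canonicalized", {
  cfg <- cardinality_config()
  outside <- equivalence_axiom(
    "MP:0008070",
    ce_and(ce_some("has_part",
                   ce_and(ce_class("PATO:0000462"),
                          ce_some("characteristic_of",
                                  ce_class("CL:0000084")))),
           ce_some("has_modifier", ce_class("PATO:0000460"))))
  outside$lhs <- "MP:0008071"
  d <- parse_eq_definition(outside, config = cfg)
  expect_true(d$has_abnormal_modifier)
  ont <- mixed_ontology()
  ont <- add_class(ont, "MP:0008071", "absent NK T cells", "phenotype")
  ont <- add_axiom(ont, outside)
  ont <- canonicalize_eq_axioms(ont, cfg)
  ax <- axioms_for(ont, "MP:0008071")[[1L]]
  d2 <- parse_eq_definition(ax, config = cfg)
  expect_identical(cardphen:::match_eq_expr(ax$rhs, cfg)$nesting, "inside")
  expect_identical(unclass(d2), unclass(d))
})

test_that("a structural match with an undeclared class id is an error", {
  ont <- mixed_ontology()
  ax <- eq_axiom("MP:0005018", "PATO:0001997", "CL:7777777")
  expect_error(parse_eq_definition(ax, ont = ont, config = chain_config()),
               "CL:7777777")
})

test_that("cardinality test honours quality closure and entity filter", {
  ont <- mixed_ontology()
  qg <- subsumption_graph_of(ont, "quality")
  cfg <- cardinality_config()
  expect_true(is_cardinality_phenotype(
    eq_definition("MP:1", "PATO:0001997", "CL:0000084"), qg, cfg))
  # qualitative quality: split
  expect_false(is_cardinality_phenotype(
    eq_definition("MP:2", "PATO:0001786", "UBERON:0001834"), qg, cfg))
  # amount quality but the entity is no cell type under the default filter
  expect_false(is_cardinality_phenotype(
    eq_definition("MP:3", "PATO:0001997", "UBERON:0002412"), qg, cfg))
  # no filter: the vertebra phenotype counts
  expect_true(is_cardinality_phenotype(
    eq_definition("MP:3", "PATO:0001997", "UBERON:0002412"), qg,
    cardinality_config(entity_prefixes = NULL)))
  expect_error(is_cardinality_phenotype(
    eq_definition("MP:4", "PATO:9999999", "CL:0000084"), qg, cfg),
    "PATO:9999999")
})

test_that("detection returns exactly the per-class positives, sorted", {
  ont <- mixed_ontology()
  cfg <- cardinality_config()
  defs <- detect_cardinality_phenotypes(ont, cfg)
  got <- vapply(defs, `[[`, character(1L), "phenotype_id")
  expect_identical(got, c("MP:0005018", "MP:0008042", "MP:0008070"))
  # exhaustive cross-check against the per-class predicate
  qg <- subsumption_graph_of(ont, "quality")
  manual <- character()
  for (ax in ont$axioms) {
    d <- parse_eq_definition(ax, ont = ont, config = cfg)
    if (!is.null(d) && class_namespace(ont, d$entity_id) == "entity" &&
        is_cardinality_phenotype(d, qg, cfg)) {
      manual <- c(manual, d$phenotype_id)
    }
  }
  expect_identical(got, sort(manual))
  expect_length(detect_cardinality_phenotypes(ontology(), cfg), 0L)
})

test_that("detection is invariant under axiom order and saturates", {
  cfg <- cardinality_config()
  ont <- mixed_ontology()
  ont2 <- ont
  ont2$axioms <- rev(ont2$axioms)
  t1 <- eq_definition_table(detect_cardinality_phenotypes(ont, cfg))
  t2 <- eq_definition_table(detect_cardinality_phenotypes(ont2, cfg))
  expect_identical(t1, t2)
  # fixture where every phenotype is a cardinality phenotype
  ont3 <- chain_fixture()
  defs <- detect_cardinality_phenotypes(ont3, chain_config())
  expect_length(defs, 9L)
})
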