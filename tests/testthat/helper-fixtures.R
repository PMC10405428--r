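# Shared in-code fixtures and independent oracles for the test suite.

# Quality scaffold used by hand-built ontologies.
add_quality_scaffold <- function(ont, extra = character()) {
  ont <- add_class(ont, "PATO:0000001", "quality", "quality")
  ont <- add_class(ont, "PATO:0000070", "amount", "quality")
  ont <- add_subclass(ont, "PATO:0000070", "PATO:0000001")
  ont <- add_class(ont, "PATO:0000460", "abnormal", "quality")
  ont <- add_subclass(ont, "PATO:0000460", "PATO:0000001")
  for (q in c("PATO:0000470", "PATO:0001997", "PATO:0000462")) {
    ont <- add_class(ont, q, unname(cardphen:::FIXTURE_QUALITY_LABELS[q]),
                     "quality")
    ont <- add_subclass(ont, q, "PATO:0000070")
  }
  for (q in extra) {
    ont <- add_class(ont, q, q, "quality")
    ont <- add_subclass(ont, q, "PATO:0000001")
  }
  ont
}

eq_axiom <- function(pid, quality, entity, modifier = TRUE,
                     strength = "equivalent",
                     config = cardinality_config()) {
  rhs <- cardphen:::canonical_eq_rhs(quality, ce_class(entity), modifier,
                                     config)
  if (strength == "equivalent") equivalence_axiom(pid, rhs) else
    subclass_axiom(pid, rhs)
}

# Entity chain CL:0000003 (NKT) < CL:0000002 (T) < CL:0000001 (lymphocyte)
# with one phenotype per entity x quality.
chain_fixture <- function(qualities = c("PATO:0000470", "PATO:0001997",
                                        "PATO:0000462")) {
  ont <- ontology("chain")
  ont <- add_quality_scaffold(ont)
  ents <- c("CL:0000001", "CL:0000002", "CL:0000003")
  labs <- c("lymphocyte", "T cell", "NK T cell")
  for (i in seq_along(ents)) {
    ont <- add_class(ont, ents[i], labs[i], "entity")
  }
  ont <- add_subclass(ont, "CL:0000002", "CL:0000001")
  ont <- add_subclass(ont, "CL:0000003", "CL:0000002")
  ont <- add_class(ont, "MP:0000001", "phenotype root", "phenotype")
  k <- 1L
  for (e in ents) {
    for (q in qualities) {
      k <- k + 1L
      pid <- sprintf("MP:%07d", k)
      ont <- add_class(ont, pid, paste(q, e), "phenotype")
      ont <- add_subclass(ont, pid, "MP:0000001")
      ont <- add_axiom(ont, eq_axiom(pid, q, e))
    }
  }
  ont
}

chain_config <- function() cardinality_config(phenotype_root_id = "MP:0000001")

# Mixed ontology: 3 cardinality phenotypes plus a qualitative one ("split")
# and a filter-excluded one (vertebra is not a cell type).
mixed_ontology <- function() {
  ont <- ontology("mixed")
  ont <- add_quality_scaffold(ont, extra = "PATO:0001786")  # split
  ont <- add_class(ont, "CL:0000084", "T cell", "entity")
  ont <- add_class(ont, "CL:0000814", "mature NK T cell", "entity")
  ont <- add_subclass(ont, "CL:0000814", "CL:0000084")
  ont <- add_class(ont, "UBERON:0002412", "vertebra", "entity")
  ont <- add_class(ont, "UBERON:0001834", "upper lip", "entity")
  ont <- add_class(ont, "MP:0000001", "phenotype root", "phenotype")
  phenos <- list(
    list("MP:0005018", "PATO:0001997", "CL:0000084"),   # decreased T cell
    list("MP:0008070", "PATO:0000462", "CL:0000084"),   # absent T cells
    list("MP:0008042", "PATO:0000470", "CL:0000814"),   # increased NK T
    list("MP:0004645", "PATO:0001997", "UBERON:0002412"), # vertebrae number
    list("MP:0005170", "PATO:0001786", "UBERON:0001834")  # cleft upper lip
  )
  for (p in phenos) {
    ont <- add_class(ont, p[[1]], p[[1]], "phenotype")
    ont <- add_subclass(ont, p[[1]], "MP:0000001")
    ont <- add_axiom(ont, eq_axiom(p[[1]], p[[2]], p[[3]]))
  }
  ont
}

# Random DAG edges over n nodes (edges only from higher to lower index, so
# acyclic by construction).
random_dag <- function(n, p = 0.15, seed = 1) {
  cardphen:::with_seed(seed, {
    nodes <- sprintf("N:%03d", seq_len(n))
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    pairs <- pairs[pairs$i < pairs$j, ]
    keep <- stats::runif(nrow(pairs)) < p
    list(nodes = nodes,
         edges = data.frame(sub = nodes[pairs$j[keep]],
                            super = nodes[pairs$i[keep]],
                            stringsAsFactors = FALSE))
  })
}

# Brute-force reflexive reachability by per-node depth-first search.
brute_reachability <- function(nodes, edges) {
  out <- list()
  for (n in nodes) {
    stack <- n; seen <- character()
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      if (x %in% seen) next
      seen <- c(seen, x)
      stack <- c(stack, edges$super[edges$sub == x])
    }
    out[[length(out) + 1L]] <- data.frame(sub = n, super = seen,
                                          stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  sort(paste(d$sub, d$super))
}

# Seeded random fixture for oracle-equivalence tests.
random_fixture <- function(seed) {
  dims <- list(c(2L, 2L), c(2L, 3L), c(3L, 2L), c(2L, 2L),
               c(2L, 3L), c(3L, 2L), c(2L, 2L), c(3L, 3L))
  d <- dims[[(seed %% 8L) + 1L]]
  all_q <- c("PATO:0000470", "PATO:0001997", "PATO:0000462")
  qs <- all_q[seq_len(1L + (seed %% 3L))]
  spec <- fixture_spec(depth = d[1L], branching = d[2L], qualities = qs,
                       seed = seed)
  generate_phenotype_ontology(generate_entity_ontology(spec), spec)
}

graph_keys <- function(g) sort(transitive_closure(g)$key_set)
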