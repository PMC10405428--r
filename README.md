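# cardphen

Collection-based reformulation of cardinality phenotypes in phenotype
ontologies.

## The problem

Phenotype ontologies such as HP and MP formalise classes like *decreased
T cell number* with an entity–quality (EQ) definition

```
P  ≡  ∃has_part.(Q ⊓ ∃characteristic_of.E ⊓ ∃has_modifier.abnormal)
```

where `E` is a cell type and `Q` a PATO quality under *amount*.  Because
every NK T cell is a T cell, a standard reasoner then entails

```
'decreased NK T cell number'  ⊑  'decreased T cell number'
'absent NK T cells'           ⊑  'absent T cells'
```

Both inferences misstate the biology: losing one T-cell subtype does not
reduce (let alone abolish) the whole T-cell compartment, and for absence
the correct entailment runs the other way.  Tools that rank candidate
genes for rare diseases by ontology-based phenotype similarity inherit
these errors, because a decoy gene annotated to a *sibling* cell subtype
looks similar to a disease through the spurious shared parent class.

`cardphen` fixes this by rewriting cardinality phenotypes over *maximal
collections* of entities.  For each affected cell type `X` it creates a
collection class with three axioms

```
X-Collection ⊑ ∀has_member.X        X ⊑ ∃member_of.X-Collection
X-Collection ≡ { x-collection }                    (a fresh nominal)
```

asserts the collection partonomy `X-Collection ⊑ ∃part_of.Y-Collection`
for every entailed `X ⊑ Y`, replaces each amount phenotype's entity with
its collection, and gives each absence phenotype two equivalent
definitions — the empty collection
`∃has_part.(quality ⊓ ∃characteristic_of.(X-Collection ⊓ ∀has_member.⊥) ⊓ …)`
and the negated parthood
`¬∃has_part.(quality ⊓ ∃characteristic_of.X)` — plus grouping classes per
collection (CXP) and per quality (CQ).  After classification the subtype
inferences disappear, absence inverts (`absent T cells ⊑ absent NK T
cells`), and the grouping classes organise the revised hierarchy.

A fragment-specific classifier computes the entailed hierarchy for both
the original and the revised axioms (verified edge-for-edge against a
naive structural-subsumption saturation oracle), and the evaluation
module measures the downstream effect with Resnik similarity
(`sim(a,b) = IC(MICA(a,b))`, `IC = −log₂ p`), two-sided best-match-average
profile similarity, per-disease gene ranking and pooled ROC AUC.

## Worked example

```r
library(cardphen)

ont <- fig_fixture_ontology()          # frozen T cell / NK T cell fixture
cfg <- fig_fixture_config()

orig <- classify(ont, "original", cfg)
entails(orig, "MP:0008040", "MP:0005018")   # decreased NK < decreased T
#> [1] TRUE

rw <- rewrite_ontology(ont, cfg)
rw$rewrite_summary
#> collections   rewritten    grouping   partonomy
#>           3           4           5           3

revd <- classify_revised(rw, cfg)
entails(revd, "MP:0008040", "MP:0005018")   # defect removed
#> [1] FALSE
entails(revd, "MP:0008070", "MP:0008041")   # absent T < absent NK T
#> [1] TRUE
```

Three collection classes (T cell, NK T cell, and their lymphocyte
ancestor pulled in by the partonomy), four rewritten phenotype classes and
five grouping classes are generated; the problematic subtype entailment is
gone and absence is correctly inverted.

The synthetic gene–disease benchmark plants true associations that share
a disease's focus cell type while decoy genes carry phenotypes of a
*sibling* subtype — exactly the topology of the NK T cell confound:

```r
spec <- fixture_spec(seed = 11)        # 30 genes, 10 diseases, confounded
ph   <- generate_phenotype_ontology(generate_entity_ontology(spec), spec)
corp <- generate_annotated_corpus(ph, spec)
evaluate_associations(ph, corp$genes, corp$diseases, corp$truth,
                      "original", fixture_config())
#> <phen_eval> mode=original: pooled ROC AUC = 0.8526 (macro 0.8379) over 30 genes x 10 diseases
evaluate_associations(ph, corp$genes, corp$diseases, corp$truth,
                      "revised", fixture_config())
#> <phen_eval> mode=revised: pooled ROC AUC = 0.9474 (macro 0.9534) over 30 genes x 10 diseases
```

The revised hierarchy ranks the true genes higher because decoys no
longer reach the disease through the shared parent phenotype.

A thin command-line shell over the same functions lives at
`inst/cli/cardphen.R` (subcommands `detect`, `rewrite`, `classify`, `sim`,
`evaluate`, `simulate`); ontologies are exchanged as an OBO 1.4 subset or
an OWL 2 functional-style syntax subset (the latter with full fidelity
for nominals, negation and universal restrictions), and annotations,
associations and cross-ontology equivalence mappings as 2-column TSVs.

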