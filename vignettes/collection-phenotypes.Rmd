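---
title: "Cardinality phenotypes as phenotypes of collections: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardinality phenotypes as phenotypes of collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardphen)
```

## The model

Phenotype ontologies describe a phenotype class `P` with an entity–quality
(EQ) definition: `P` holds of an organism that has a part bearing quality
`Q` characteristic of entity `E`, optionally flagged abnormal,

$$P \sqsubseteq \exists has\_part.(Q \sqcap \exists characteristic\_of.E
  \sqcap \exists has\_modifier.abnormal).$$

When `Q` falls under the PATO *amount* branch (increased amount, decreased
amount, absent, …) the phenotype is about the **cardinality of a
collection** of entities of type `E` within one body — how many T cells
there are — not about any individual T cell.  Existential-restriction
monotonicity then produces entailments that are wrong for counts: a
decreased number of a *subtype* is classified under a decreased number of
the *supertype*, and absence of the subtype under absence of the
supertype, although for absence exactly the dual holds.

`cardphen` models the body-wide collection of all instances of `X`
directly.  A first-order reading would define `X-Collection(x)` as the
collection containing exactly the `X`s in a body; in the description-logic
fragment compatible with phenotype ontologies this is approximated by
three axioms per entity:

* `X-Collection ⊑ ∀has_member.X` — members are `X`s only;
* `X ⊑ ∃member_of.X-Collection` — every `X` belongs to it;
* `X-Collection ≡ {x-collection}` — a nominal singleton, with a fresh
  individual used nowhere else, so there is exactly one such collection
  per type.

The subtype/supertype relationship between collections is *parthood*, not
subsumption: a collection of T cells is part of the collection of
lymphocytes.  Because the nominal reading blocks the derivation of this
parthood inside the fragment, it is asserted directly:
`X-Collection ⊑ ∃part_of.Y-Collection` for every entailed `X ⊑ Y`
(reflexive pairs are skipped — parthood reflexivity carries no
information).  A single root collection class `C` ("collection of cells")
sits above every generated collection.

Detected cardinality phenotypes are then **rewritten**:

* *amount* kind — the entity is replaced by its collection, preserving the
  quality, the abnormal modifier and the definition strength;
* *absence* kind — the class receives two definitions, the empty
  collection (`… ∃characteristic_of.(X-Collection ⊓ ∀has_member.⊥) …`)
  and the negated parthood (`¬∃has_part.(quality ⊓
  ∃characteristic_of.X)`).  Declaring both on one class makes their
  right-hand sides definitionally equivalent: a quality of an empty
  collection of `X` is the same as not having any `X`-bearing part.  The
  negated form is what yields the inverted entailment `absent supertype ⊑
  absent subtype`.

The original entity-based definition is *replaced*, not kept: keeping it
would reinstate exactly the subtype inferences the rewrite removes.  A
configuration of the pipeline could retain them, but replacement is the
default and the tested behaviour.

Two families of **grouping classes** organise the result: one class per
collection (`CXP`, genus the root quality, subsuming every abnormality of
that collection, absences included) and one per quality occurring in the
detections (`CQ`, over the root collection `C`).  The printed grouping
schemata are subsumption axioms, but only full definitions make the
intended classifications derivable; the package therefore emits grouping
axioms (and rewritten equivalence-strength phenotypes) as equivalences,
preserving subclass strength only where the source definition had it.
One consequence worth noting: a `CQ` built over an absence quality
subsumes nothing after rewriting, because rewritten absences carry the
root-quality genus; absences are grouped by their `CXP` instead.  `CQ`
classes are still generated for absence qualities so that the
by-quality grouping family is complete over the detected qualities.

## Classification

Full OWL 2 DL reasoning is replaced by a rule set specific to the emitted
schemata; the axioms involve negation, universal restrictions and
nominals, but only in fixed positions, so a sound and (for this fragment)
complete rule set exists:

* shared-pattern rule — `P₁ ⊑ P₂` iff `Q₁ ⊑ Q₂` and the characteristic
  bearers are ordered (`E₁ ⊑ E₂` for plain EQ classes; identical
  collection, or any collection under the root `C`, for rewritten ones);
* absence duality — `absent_X ⊑ absent_Y` iff `Y ⊑ X` among the entities;
* absence-to-grouping — via the empty-collection form;
* asserted edges, reflexivity and transitivity throughout.

Only equivalence-strength definitions can acquire inferred subclasses;
subclass-strength definitions state necessary conditions and gain only
superclasses (the standard primitive-versus-defined reading).  A target
definition's abnormal-modifier conjunct must be matched by the source.
Collections of distinct entities are never comparable (their nominals are
distinct singletons), which is what removes the amount-phenotype defect;
whether collection parthood should induce `CXP(X) ⊑ CXP(Y)` needs role
chains outside the fragment and is deliberately excluded.

The optimised classifier works on pattern metadata tables.  It is
verified against `naive_saturation_oracle()`, an independent
implementation that performs recursive *structural subsumption* directly
on the expression trees of all axiom pairs and iterates to a fixpoint with
no indexing — slower, but with no shared code path.  The test suite
checks edge-for-edge equality on 50 seeded random fixtures per mode
(entity trees up to depth 3 and branching 3, one to three qualities;
the largest has 40 entities and 120 phenotype classes).

Both axiom nestings of the abnormal modifier occur in published
definitions (inside or outside the `has_part` filler).  The two differ
under strict DL semantics, but the ontologies use them interchangeably,
so the loader normalises to the modifier-inside form; the classifiers,
the oracle and the serialisers all operate on that canonical form.

## Similarity and evaluation

Information content is `IC(c) = −log₂ p(c)` in bits, with `p` the
fraction of annotated entities (genes **and** diseases pooled — the
probability is over "an entity" of either kind) whose profile, propagated
to all ancestors in the classified hierarchy, contains `c`.  Propagation
before counting is required for MICA-based similarity to be meaningful;
classes never used after propagation get no IC entry and are excluded as
MICA candidates rather than being assigned infinite IC, which would let
unannotated classes dominate.  Resnik similarity is the IC of the most
informative common ancestor; profile similarity is the literal two-sided
best-match average,

$$\mathrm{sim}(g,d) = \frac{\sum_i \max_j r_{ij}}{2g_n}
  + \frac{\sum_j \max_i r_{ij}}{2d_n},$$

with no further normalisation.  Each side of this formula is a
half-average, which halves scores of singleton profiles relative to plain
Resnik; the formula is implemented exactly as written because ranking is
scale-invariant.

Genes are ranked per disease by descending similarity with average ranks
for ties (unbiased AUC under ties).  The headline metric is the pooled
ROC AUC over all disease–gene pairs — the normalised Mann–Whitney
rank-sum statistic, equal to the fraction of (positive, negative) pair
comparisons won with ties counting one half — with the per-disease macro
average reported alongside.  Genes or diseases left without annotations
(e.g. after restricting to cardinality phenotypes) are dropped with a
warning, not scored zero.

## What the synthetic generator emulates

`fixture_spec()` fixes the study conditions: a full binary entity tree of
depth 3 (15 cell types), qualities {increased amount, decreased amount,
absent}, one equivalence-strength EQ definition per entity and quality,
30 genes, 10 diseases, 3 annotations per profile, `confound_rate = 1`,
`noise_rate = 0.1`.  Each disease receives a non-root focus cell type
with at least one sibling; its true gene shares the same phenotypes
(each annotation drawn over the focus entity, or its direct parent with
probability 1/4, emulating near-miss curation); every remaining gene is a
decoy that, with probability `confound_rate`, carries the phenotypes of a
*sibling* subtype — under the original semantics both profiles reach the
shared parent phenotype, under the collection semantics they share only
low-IC grouping classes.  Uniform annotation noise (the simplest null)
replaces each annotation with a random class at `noise_rate`.

This generator plants the confound topology and nothing else.  It does
not emulate the class-count distribution, annotation depth or redundancy
of real model-organism corpora, cross-ontology alignment noise, or
qualitative phenotypes mixed into profiles; passing benchmarks therefore
demonstrate that the rewrite removes the targeted inference defect and
that this *direction* of improvement survives noise — not the magnitude
of any real-data improvement.  Two further consequences of the model are
worth knowing.  First, with random decoys the no-confound limit is not
exactly AUC 1.0 in either mode: a decoy may by chance carry a phenotype
of an entity comparable to a disease's focus entity and tie with the true
pair (through the shared-parent MICA originally, through absence duality
after revision).  Second, at `confound_rate = 1` the original hierarchy
still performs well above chance, because exact matches outrank
parent-level matches; the revision's gain comes from pooled comparisons
across diseases.

## Numerical and interface choices

* Identifiers are opaque CURIE-style strings (exactly one colon); no IRI
  resolution.  Generated ids are deterministic: the source id with `:`
  mangled to `_` under fixed prefixes (`COLL:`, `GXP:`, `GQ:`, `IND:`),
  recorded in a provenance table.
* Equivalent classes (mapping files, named equivalence axioms) are merged
  into the lexicographically smallest id so the canonical node is
  independent of merge order; any other is-a cycle is an input error.
* All output is sorted: closures, axiom lists, serialisations.  Writing
  the same ontology twice is byte-identical.
* The OBO dialect covers hand-editable fixtures (classes, is-a edges,
  genus-differentia EQ equivalences); nominals, negation, universal
  restrictions and subclass-strength definitions require the OWL
  functional dialect, and the OBO writer drops them with a counted
  manifest.  The OWL export also preserves the option of checking the
  fragment entailments with an external OWL 2 DL reasoner; such a check
  must yield a superset of the fragment entailments.
* Default entity filter: CURIE prefix `CL` (cell types), configurable;
  collections of chemicals within cells ("stacked" collections) are out
  of scope.
* Benchmarks in tests and in `scripts/acceptance.R` use the default
  fixture scale (15 entities, 45 phenotype classes, 300 gene–disease
  pairs) over 20 seeds; oracle-equivalence checks use 50 random fixtures
  per mode at up to 40 entities.  These sizes make every property
  checkable exhaustively while the whole pipeline remains exact — nothing
  is approximated at larger scale.

## Known limitations

* The classifier is complete only for the emitted schemata; feeding it
  arbitrary OWL constructs is an error, not an approximation.
* Absence inversion relies on the negated-parthood definition; ontologies
  that model absence differently (e.g. lacks_part idioms) need mapping to
  the supported pattern first.
* Classes that are lexically about counts but have no logical definition
  are invisible to detection.
* Real-data evaluations (full MP/HP with model-organism annotation
  corpora) are supported through the TSV and ontology readers but are the
  user's task; the shipped tests are fixture-scale by design.
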