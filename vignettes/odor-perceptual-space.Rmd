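---
title: "Mapping odorant descriptors to perception profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping odorant descriptors to perception profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorspace)
```

## The problem

The smell of a product such as a wine is scored by trained panels on *odor
sensory attributes* (OSA) — "Cherry cooked", "Bell pepper", "Prune". Its
chemical stimulus, however, is a mixture of odorants, each of which is
annotated in reference databases with *odor descriptors* (OD) — "banana",
"ethereal-fruity". Between the two sits the working vocabulary of
flavorists: *odor qualities* (OQ) such as "Fruity" or "Smoky", broad
perceptual categories they combine mentally when constructing an odor.
There is no agreed mapping between these three vocabularies; flavor wheels
exist but are product- and database-specific.

`odorspace` fixes the three vocabularies and their relations in a formal
ontology and uses it to push quantitative descriptor information upward:
from database prose about single odorants, to OQ profiles, to the OSA
profiles a panel would use — for single odorants and, by weighted
summation, for multi-odorant products.

## The model

The ontology is a tuple \{C, R, P\}: classes C are the three layers OD, OQ
and OSA, each with one subclass per label ("is-a" relations R); properties
P are four object properties forming two inverse pairs,
`OD-part-of-OQ`/`OQ-including-OD` and `OQ-part-of-OSA`/`OSA-including-OQ`.
The cross-layer structure is equivalently held as two binary matrices: an
OD × OQ matrix from a check-all-that-apply (CATA) questionnaire, and an
OQ × OSA matrix from multi-expert elicitation.

Quantities attach to the OD layer. For odorant $M$ with per-source
descriptor sets $S_1(M), \dots, S_k(M)$, the aggregated descriptor set is
the union $\bigcup_i S_i(M)$ and the *intensity* of descriptor $d$ is its
citation count $c_M(d) = \#\{i : d \in S_i(M)\}$ — a dimensionless integer
between 1 and the number of sources. Intensities propagate linearly
through the binary links:

$$\mathrm{OQ}_M(q) = \sum_d c_M(d)\, A_{dq}, \qquad
  \mathrm{OSA}_M(s) = \sum_q \mathrm{OQ}_M(q)\, B_{qs},$$

with $A$ the OD × OQ and $B$ the OQ × OSA matrix. A product $W$ composed of
odorants $m$ with non-negative weights $w_m$ (e.g. GC-olfactometry
intensities) has profile $\sum_m w_m\, \mathrm{OSA}_m$.

Two modeling choices deserve emphasis. First, a descriptor ticked for
several qualities contributes its **full** count to each; the only
published worked rows are single-quality, and replication is the rule most
consistent with CATA semantics (a tick asserts membership, not a share).
Second, the whole propagation is **linear**: perceptual interactions in
odor mixtures — synergy, masking, configural perception — are real but are
deliberately outside this model; the linearity is also what makes the
engine exactly testable (see below).

## Worked example

```{r example}
fx <- wine_aroma_fixture()
corpus <- extract_corpus(fx$descriptions)
corpus[[1]]

ont <- odor_ontology(fx$od_oq, fx$oq_osa,
                     aliases = list(OQ = wine_oq_aliases()))
predict(ont, corpus[[1]], layer = "OQ")
predict(ont, corpus[[1]], layer = "OSA")
query_ontology(ont, "OQ-part-of-OSA", "Prune")
```

All nine citations of ethyl butanoate mass onto the single quality Fruity
(count 9 = 2 banana + 1 ethereal-fruity + 2 fruity + 3 pineapple + 1 ripe
fruit), and from there onto the four attributes the Fruity row of the
expert matrix links: Blackcurrant bud, Blackcurrant fresh, Prune and
Strawberry fresh.

## Tokenization

Database prose is reduced to descriptors by a rule-driven tokenizer
(`stop_rules()`), replacing what was historically a manual reading:

* **suffixes** ("like", "note") are dropped standalone and as hyphenated
  tails ("fruity-like" → "fruity");
* **stop words** — auxiliaries, connectives, and hedonic or intensity
  modifiers ("has", "powerful", "very", "odor") — are discarded: they
  carry no olfactory category;
* a **phrase lexicon** is consulted before word splitting so multi-word
  descriptors ("ripe fruit") survive whole; hyphenated compounds
  ("ethereal-fruity") are kept as single terms by default;
* terms are lower-cased; **no stemming or synonym merging is ever
  applied** — "leather" and "leathery" are distinct descriptors, because
  collapsing near-synonyms is precisely the judgement the ontology layer
  is meant to make explicit, not the tokenizer.

The default stop list is intentionally small and reviewable; any corpus
study should version its own rules file. Within one source a repeated term
counts once — citation counting happens across sources only, which is what
bounds every count by the number of databases.

## Label hygiene

Source tables are inconsistent spellers: the same quality appears as
"Lactony", "Lactoniy" and "Lactonic"; attributes appear both as "Cherry
cooked" and "CHERRY_COOKED". Every label entering a mapping or query is
resolved through a `label_registry()` — case-, underscore- and
whitespace-insensitive matching plus an explicit alias table — so variant
spellings link rather than silently dropping edges. Unresolvable labels
fail loudly with nearest-match suggestions.

## Fusion of expert knowledge

The OQ × OSA matrix is the set-union of per-expert elicitations: a cell is
1 when *any* expert listed that quality for that attribute. Union is
deliberately permissive (expert vocabularies differ more in coverage than
in contradiction) but information-lossy, so each fused link keeps its
provenance (`mapping_provenance()`): which experts contributed it. The
union is idempotent, order-invariant and monotone — adding an expert can
only add links — and those three properties are tested against a
brute-force logical-OR oracle.

The CATA OD × OQ matrix is a direct encoding of one flavorist's ticks;
descriptors with no tick become all-zero rows and simply contribute
nothing downstream (e.g. "buttery", "juicy" in the bundled example). The
bundled matrix carries the nine ethyl butanoate descriptor rows plus the
three further descriptor–quality links documented in the study's query and
visualization examples (almond → Almond; vanilla, tonka → Vanilla).

## The ontology as OWL

`export_owl()` writes the graph as an OWL 2 document — three top classes,
subclass axioms, the four properties declared as two `owl:inverseOf` pairs,
and one triple per assertion — in Turtle (default; line-oriented and
diff-friendly) or RDF/XML. Subclass IRIs are
`<base IRI><layer>_<URL-encoded label>`, with the verbatim label kept in
`rdfs:label`, so names with spaces round-trip. `import_owl()` reads both
dialects back and rejects documents missing any of the four properties.

The four query patterns are existential property fillers
("which OQ are part of the OSA *Prune*?"); they are answered directly on
the assertion set. No description-logic reasoner is involved: the patterns
need no inference, and evaluating them as indexed lookups gives identical
answers with no heavy dependency. Queries on an imported graph therefore
agree exactly with queries on the in-memory one, and both agree with the
row/column supports of the underlying matrices — an invariant the test
suite asserts label by label.

## Comparing product profiles

`to_proportions()` rescales a profile to shares of total intensity mass;
`compare_products()` tests, per attribute, whether the two products' shares
differ, using a two-proportion z-test with intensity masses treated as
counts (rounded half away from zero). The underlying attribute-wise
significance marks this mirrors are conventionally raw, so no
multiple-testing correction is applied by default; a Holm flag is
available. Two caveats are intrinsic and documented rather than hidden:
the choice of test is a package convention (the classic figures never
name one), and count-based tests are scale-dependent — doubling all
intensities at fixed shares can only shrink p-values, so compare products
measured on comparable intensity scales.

## Synthetic corpora and what the tests show

`generate_corpus()` builds a closed world in which every stage has an
exact, independently computed answer: planted per-source term sets are
decorated into prose using only default-stop-list tokens (so extraction is
exactly invertible), true mappings are Bernoulli-sampled, and true
profiles are computed by a brute-force double loop — never by the engine
under test. All arithmetic is integer, so pipeline recovery is asserted
with `identical()`, no tolerances.

Generator defaults mirror the reference study's shape — 49 odorants × 3
sources, 175 OD / 20 OQ / 15 OSA, 2 products — with per-source descriptor
counts of 2–8, link densities 0.05 (OD × OQ) and 0.10 (OQ × OSA) matching
the sparsity of the transcribed matrices, 10% hyphenated and 10% two-word
vocabulary to exercise the hardest tokenizer paths, and integer component
weights on a 1–5 GC-olfactometry-style scale. Property-style tests run the
engine against the double-loop oracle on ~1,750 random instances up to
10 × 10 (seeded), plus the linearity, scaling, path-equivalence and
mass-bound invariants.

What passing does **not** show: real database prose is messier than the
generator's templates (spelling noise, nested clauses, vocabulary far
beyond the stop list), real expert data contain genuine disagreement, and
real mixture perception is not linear. The synthetic results validate the
machinery, not the perceptual model.

## Numerical and degenerate-input conventions

* Label order is everywhere C-locale alphabetical, so outputs are
  byte-stable across locales.
* Profiles store explicit zeros over their full layer; an all-zero
  profile is valid everywhere except `to_proportions()`, which errors.
* Descriptors absent from the OD × OQ matrix are tolerated and reported
  (`unmapped` attribute) by default; a strict mode errors. Real corpora
  are open; the closed-world default would otherwise be a silent filter.
* Product weights default to 1 when omitted, reproducing plain summation.
* Intensities are integers at the descriptor layer but reals in the
  engine: product weighting introduces non-integers.
* Degenerate z-tests (pooled proportion 0 or 1) report p = 1: the shares
  are equal, there is nothing to detect.

## Known limitations

Linear propagation ignores mixture interactions by construction. The
tokenizer's stop list is a reviewable approximation of a manual practice,
not a model of it. The expert matrix fuses four experts by union with no
weighting or agreement statistics. The Turtle reader covers the subset
this package writes, not the full grammar. Odorant concentration enters
only through user-supplied product weights, not through the descriptor
layer itself.
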