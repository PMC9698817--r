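# odorspace

Ontology-based mapping from odorant descriptors to odor perception
profiles.

## The problem

A product's smell is scored by sensory panels on **odor sensory
attributes** (OSA: "Cherry cooked", "Bell pepper", "Prune"), but its
chemical stimulus is a mixture of odorants, each annotated in reference
databases with **odor descriptors** (OD: "banana", "ethereal-fruity").
Flavorists bridge the two with an intermediate vocabulary of **odor
qualities** (OQ: "Fruity", "Smoky"). These three vocabularies have no
agreed mapping. `odorspace` is for sensory and flavor informaticians who
want to fix the vocabularies and their relations in a formal ontology and
use it to predict, from database prose alone, the OQ and OSA profiles of
single odorants and of weighted odorant mixtures such as wines.

## The model

For odorant *M* with per-source descriptor sets *S₁(M), …, Sₖ(M)*, the
aggregated descriptor set is ⋃ᵢ Sᵢ(M) with intensity
*c_M(d) = #{i : d ∈ Sᵢ(M)}* (citation count). With *A* the binary OD × OQ
matrix (check-all-that-apply questionnaire) and *B* the binary OQ × OSA
matrix (union of multi-expert elicitations), intensities propagate
linearly:

    OQ_M(q)  = Σ_d c_M(d) · A[d,q]
    OSA_M(s) = Σ_q OQ_M(q) · B[q,s]
    OSA_W(s) = Σ_m w_m · OSA_m(s)        (product W, component weights w)

The same structure is held as an OWL 2 ontology — top classes OD/OQ/OSA,
one subclass per label, four object properties in two inverse pairs —
which can be serialized (Turtle, RDF/XML), re-imported, and queried with
the four existential patterns (e.g. `OQ-part-of-OSA` anchored at
"Prune"). Mixture perception is treated as linear; synergy and masking
are explicitly out of scope.

## Worked example

The package bundles a worked red-wine data set: three database
descriptions of ethyl butanoate, the CATA OD × OQ matrix and the
four-expert OQ × OSA matrix over 20 qualities and 15 wine attributes.

```r
library(odorspace)
fx <- wine_aroma_fixture()
corpus <- extract_corpus(fx$descriptions)
corpus[[1]]
#> <descriptor_set> Ethyl butanoate (CAS 105-54-4): 9 descriptor(s)
#>   [(banana, 2); (buttery, 1); (cognac, 1); (ethereal, 1); (ethereal-fruity, 1);
#>    (fruity, 2); (juicy, 2); (pineapple, 3); (ripe fruit, 1)]
```

"banana" is cited by 2 of the 3 sources, "pineapple" by all 3; modifiers
("powerful", "very diffusive") were discarded by the tokenizer.

```r
ont <- odor_ontology(fx$od_oq, fx$oq_osa,
                     aliases = list(OQ = wine_oq_aliases()))
predict(ont, corpus[[1]], layer = "OSA")
#> <odor_profile> layer OSA (15 labels)
#>   [(Bell pepper, 0); (Blackcurrant bud, 9); (Blackcurrant fresh, 9);
#>    (Cherry cooked, 0); (Cherry fresh, 0); (Cherry stone, 0); (Cut-grass, 0);
#>    (Leather, 0); (Prune, 9); (Smoky, 0); (Strawberry fresh, 9); (Toasty, 0);
#>    (Vanilla, 0); (Violet, 0); (Woody, 0)]
```

All nine citations land on the quality Fruity (2+1+2+3+1 = 9), and spread
to the four attributes linked to Fruity in the expert matrix. The
ontology answers the classic queries directly:

```r
query_ontology(ont, "OQ-part-of-OSA", "Prune")
#> [1] "Almond"  "Cooked"  "Fruity"  "Honey"   "Lactony"
```

`export_owl()`/`import_owl()` round-trip the graph; `compare_products()`
contrasts two product profiles attribute by attribute;
`generate_corpus()` builds synthetic corpora with exact ground truth. A
thin CLI over these functions ships in `inst/scripts/odorspace`. See the
vignette `vignettes/odor-perceptual-space.Rmd` for the model's
assumptions and design choices.

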