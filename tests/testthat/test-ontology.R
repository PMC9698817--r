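fx <- wine_aroma_fixture()
ont <- odor_ontology(fx$od_oq, fx$oq_osa,
                     aliases = list(OQ = wine_oq_aliases()))

test_that("the ontology holds every link with its inverse", {
  a <- ont$assertions
  has <- function(s, p, o) any(a$subject == s & a$property == p &
                                 a$object == o)
  expect_true(has("banana", "OD-part-of-OQ", "Fruity"))
  expect_true(has("Fruity", "OQ-including-OD", "banana"))
  expect_true(has("Vanilla", "OQ-part-of-OSA", "Blackcurrant bud"))
  expect_true(has("Blackcurrant bud", "OSA-including-OQ", "Vanilla"))
  # inverse closure holds for every assertion
  for (k in seq_len(nrow(a))) {
    inv <- switch(a$property[k],
                  "OD-part-of-OQ" = "OQ-including-OD",
                  "OQ-including-OD" = "OD-part-of-OQ",
                  "OQ-part-of-OSA" = "OSA-including-OQ",
                  "OSA-including-OQ" = "OQ-part-of-OSA")
    expect_true(has(a$object[k], inv, a$subject[k]))
  }
})

test_that("an empty ontology still has its three top classes", {
  e <- odor_ontology(
    binary_mapping(matrix(integer(0), 0, 0), layers = c("OD", "OQ")),
    binary_mapping(matrix(integer(0), 0, 0), layers = c("OQ", "OSA")))
  expect_identical(lengths(e$labels),
                   c(OD = 0L, OQ = 0L, OSA = 0L))
  expect_identical(nrow(e$assertions), 0L)
  f <- withr::local_tempfile(fileext = ".ttl")
  export_owl(e, f)
  txt <- paste(readLines(f), collapse = "\n")
  expect_identical(lengths(regmatches(txt, gregexpr("owl#Class", txt))), 3L)
  expect_identical(
    lengths(regmatches(txt, gregexpr("owl#ObjectProperty", txt))), 4L)
  expect_true(ontology_identical(import_owl(f), e))
})

test_that("mismatched quality layers are rejected at construction", {
  bad <- binary_mapping(matrix(0L, 1, 1, dimnames = list("x", "NotAnOQ")),
                        layers = c("OQ", "OSA"))
  expect_error(odor_ontology(fx$od_oq, bad), "same OQ labels")
})

test_that("the four query patterns answer from the assertion set", {
  expect_identical(query_ontology(ont, "OQ-including-OD", "almond"),
                   "Almond")
  expect_identical(query_ontology(ont, "OD-part-of-OQ", "Almond"),
                   "almond")
  expect_identical(query_ontology(ont, "OSA-including-OQ", "Almond"),
                   c("Cherry cooked", "Cherry fresh", "Cherry stone",
                     "Prune"))
  expect_identical(query_ontology(ont, "OQ-part-of-OSA", "Prune"),
                   c("Almond", "Cooked", "Fruity", "Honey", "Lactony"))
  # anchors resolve through the registries (variant spellings accepted)
  expect_identical(query_ontology(ont, "OQ-part-of-OSA", "PRUNE"),
                   query_ontology(ont, "OQ-part-of-OSA", "Prune"))
  expect_identical(query_ontology(ont, "OSA-including-OQ", "Lactonic"),
                   "Prune")
  # no links -> empty result, unknown anchor -> error
  expect_identical(query_ontology(ont, "OSA-including-OQ", "Violet"),
                   character(0))
  expect_error(query_ontology(ont, "OQ-part-of-OSA", "Pruen"), "nearest")
  expect_error(query_ontology(ont, "part-of", "Prune"), "unknown property")
})

test_that("query results equal matrix row/column supports everywhere", {
  g <- ont
  for (d in rownames(g$od_oq))
    expect_identical(query_ontology(g, "OQ-including-OD", d),
                     sort(colnames(g$od_oq)[g$od_oq[d, ] == 1L],
                          method = "radix"))
  for (q in colnames(g$od_oq))
    expect_identical(query_ontology(g, "OD-part-of-OQ", q),
                     sort(rownames(g$od_oq)[g$od_oq[, q] == 1L],
                          method = "radix"))
  for (s in colnames(g$oq_osa))
    expect_identical(query_ontology(g, "OQ-part-of-OSA", s),
                     sort(rownames(g$oq_osa)[g$oq_osa[, s] == 1L],
                          method = "radix"))
  # inverse symmetry on a random synthetic graph
  corpus <- generate_corpus(corpus_spec(n_odorants = 4, n_od = 15,
                                        n_oq = 6, n_osa = 4, seed = 11))
  g2 <- odor_ontology(corpus$od_oq, corpus$oq_osa)
  for (d in sample(rownames(g2$od_oq), 5)) {
    qs <- query_ontology(g2, "OQ-including-OD", d)
    back <- vapply(rownames(g2$oq_osa), function(q)
      d %in% query_ontology(g2, "OD-part-of-OQ", q), logical(1))
    expect_identical(qs, sort(names(back)[back], method = "radix"))
  }
})

test_that("OWL export/import round-trips in both dialects", {
  for (dialect in c("turtle", "rdfxml")) {
    f <- withr::local_tempfile(
      fileext = if (dialect == "turtle") ".ttl" else ".owl")
    export_owl(ont, f, dialect = dialect)
    back <- import_owl(f)
    expect_true(ontology_identical(back, ont))
    # the re-imported graph answers queries identically
    expect_identical(query_ontology(back, "OQ-including-OD", "almond"),
                     "Almond")
    expect_identical(query_ontology(back, "OQ-part-of-OSA", "Prune"),
                     query_ontology(ont, "OQ-part-of-OSA", "Prune"))
  }
  # explicit dialect selection matches auto-detection
  f <- withr::local_tempfile(fileext = ".ttl")
  export_owl(ont, f, dialect = "turtle")
  expect_true(ontology_identical(import_owl(f, dialect = "turtle"),
                                 import_owl(f)))
})

test_that("labels with spaces and hyphens survive IRI encoding", {
  corpus <- generate_corpus(corpus_spec(n_odorants = 3, n_od = 20,
                                        hyphen_frac = 0.3,
                                        phrase_frac = 0.3, seed = 21))
  g <- odor_ontology(corpus$od_oq, corpus$oq_osa)
  f <- withr::local_tempfile(fileext = ".ttl")
  export_owl(g, f)
  expect_true(ontology_identical(import_owl(f), g))
})

test_that("importing a document without the four properties fails", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "<http://example.org/odorspace> a owl:Ontology ."), f)
  expect_error(import_owl(f), "four object properties")
})

test_that("an independent RDF library parses both serializations identically", {
  f_ttl <- withr::local_tempfile(fileext = ".ttl")
  f_xml <- withr::local_tempfile(fileext = ".owl")
  export_owl(ont, f_ttl, dialect = "turtle")
  export_owl(ont, f_xml, dialect = "rdfxml")
  script <- paste(
    "import sys, rdflib",
    "a = rdflib.Graph(); a.parse(sys.argv[1], format='turtle')",
    "b = rdflib.Graph(); b.parse(sys.argv[2], format='xml')",
    "import rdflib.compare as c",
    "print(len(a), len(b), c.isomorphic(a, b))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(f_ttl),
                             shQuote(f_xml)), stdout = TRUE)
  parts <- strsplit(trimws(out[length(out)]), " ")[[1L]]
  n_triples <- nrow(odorspace:::ontology_triples(ont))
  expect_identical(as.integer(parts[1]), n_triples)
  expect_identical(as.integer(parts[2]), n_triples)
  expect_identical(parts[3], "True")
})

test_that("predict() dispatches over descriptor sets, corpora and products", {
  corpus <- extract_corpus(fx$descriptions)
  one <- predict(ont, corpus[[1L]], layer = "OQ")
  expect_identical(unname(one[["Fruity"]]), 9)
  many <- predict(ont, corpus, layer = "OSA")
  expect_identical(names(many), names(corpus))
  expect_identical(unname(many[[1L]][["Prune"]]), 9)
  comp <- product_composition("wine",
                              data.frame(odorant_id = names(corpus)[1],
                                         weight = 2))
  pw <- predict(ont, comp, corpus = corpus, layer = "OSA")
  expect_identical(unname(pw[["Prune"]]), 18)
  expect_error(predict(ont, comp, layer = "OSA"), "corpus")
  expect_error(predict(ont, 42), "newdata")
})
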