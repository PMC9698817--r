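test_that("label resolution canonicalizes spelling variants", {
  fx <- wine_aroma_fixture()
  expect_identical(resolve_label("CHERRY_COOKED", fx$registry_osa),
                   "Cherry cooked")
  expect_identical(resolve_label("Lactonic", fx$registry_oq), "Lactony")
  expect_identical(resolve_label("Lactoniy", fx$registry_oq), "Lactony")
  expect_identical(resolve_label("cut-GRASS", fx$registry_oq), "Cut-grass")
  expect_identical(resolve_label("Fruity", fx$registry_oq), "Fruity")
  expect_error(resolve_label("Frutti", fx$registry_oq), "nearest.*Fruity")
})

test_that("registries validate their labels and aliases", {
  expect_error(label_registry("OQ", c("A", "a")), "unique")
  expect_error(label_registry("OQ", "A", aliases = c(b = "B")),
               "not among canonical")
  expect_error(label_registry("OQ", c("A", "")), "non-empty")
})

test_that("expert fusion is the union of individual elicitations", {
  reg_oq <- label_registry("OQ", c("Almond", "Cooked", "Fruity", "Honey",
                                   "Lactony"),
                           aliases = wine_oq_aliases())
  reg_osa <- label_registry("OSA", c("Prune", "Cherry cooked"))
  long <- data.frame(
    expert_id = c("e1", "e1", "e2", "e3", "e3", "e4", "e4"),
    osa = c("Prune", "Prune", "Prune", "Prune", "PRUNE", "Prune",
            "Cherry cooked"),
    oq = c("Almond", "Cooked", "Fruity", "Honey", "Lactonic", "Almond",
           "Almond"))
  m <- fuse_expert_elicitations(long, reg_oq, reg_osa)
  expect_identical(rownames(m)[m[, "Prune"] == 1L],
                   c("Almond", "Cooked", "Fruity", "Honey", "Lactony"))
  # every 1 attributable to at least one expert
  idx <- which(unclass(m) == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    who <- mapping_provenance(m, rownames(m)[idx[k, 1]],
                              colnames(m)[idx[k, 2]])
    expect_gt(length(who), 0L)
  }
  expect_identical(mapping_provenance(m, "Almond", "Prune"), c("e1", "e4"))
  expect_error(fuse_expert_elicitations(
    data.frame(expert_id = "e1", osa = "Prune", oq = "Nonexistent"),
    reg_oq, reg_osa), "not found in OQ")
})

test_that("single-expert fusion reproduces that expert's responses", {
  reg_oq <- label_registry("OQ", c("Fruity", "Green"))
  reg_osa <- label_registry("OSA", c("Prune", "Smoky"))
  one <- list(list(expert_id = "e1",
                   responses = list(Prune = c("Fruity", "Green"),
                                    Smoky = "Green")))
  m <- fuse_expert_elicitations(one, reg_oq, reg_osa)
  expect_identical(unclass_mapping_for_test(m),
                   matrix(c(1L, 1L, 0L, 1L), 2, 2,
                          dimnames = list(c("Fruity", "Green"),
                                          c("Prune", "Smoky"))))
  expect_error(fuse_expert_elicitations(
    list(list(expert_id = "e1", responses = list(Prune = character(0)))),
    reg_oq, reg_osa), "at least one OQ")
})

test_that("fusion equals brute-force OR, is monotone and order-invariant", {
  set.seed(202)
  oq <- sprintf("Q%02d", 1:6)
  osa <- sprintf("S%02d", 1:4)
  reg_oq <- label_registry("OQ", oq)
  reg_osa <- label_registry("OSA", osa)
  for (i in 1:20) {
    n_exp <- sample(2:4, 1)
    mats <- lapply(seq_len(n_exp), function(e) {
      m <- matrix(rbinom(length(oq) * length(osa), 1, 0.3),
                  length(oq), length(osa), dimnames = list(oq, osa))
      # every OSA must be elicited by someone; force it for expert 1
      if (e == 1) m[cbind(sample(length(oq), length(osa), replace = TRUE),
                          seq_along(osa))] <- 1L
      m
    })
    longs <- lapply(seq_len(n_exp), function(e) {
      idx <- which(mats[[e]] == 1L, arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      data.frame(expert_id = paste0("e", e), osa = osa[idx[, 2]],
                 oq = oq[idx[, 1]])
    })
    long <- do.call(rbind, longs)
    fused <- fuse_expert_elicitations(long, reg_oq, reg_osa)
    want <- oracle_fuse_or(mats)
    expect_identical(unclass_mapping_for_test(fused),
                     want[rownames(fused), colnames(fused)])
    # permutation invariance
    perm <- fuse_expert_elicitations(long[sample(nrow(long)), ], reg_oq,
                                     reg_osa)
    expect_identical(unclass_mapping_for_test(perm),
                     unclass_mapping_for_test(fused))
    # monotonicity: adding one more expert never clears a link
    extra <- rbind(long, data.frame(expert_id = "e99", osa = osa[1],
                                    oq = oq[1]))
    grown <- fuse_expert_elicitations(extra, reg_oq, reg_osa)
    expect_true(all(unclass_mapping_for_test(grown)[rownames(fused),
                                                    colnames(fused)] >=
                      unclass_mapping_for_test(fused)))
  }
})

test_that("CATA responses become an OD x OQ matrix with all-zero rows kept", {
  fx <- wine_aroma_fixture()
  ticks <- data.frame(
    od_term = c("banana", "ethereal-fruity", "fruity", "pineapple",
                "ripe fruit", "almond", "tonka", "vanilla"),
    oq = c(rep("Fruity", 5), "Almond", "Vanilla", "Vanilla"))
  m <- build_cata_mapping(ticks, fx$registry_od, fx$registry_oq)
  expect_identical(unclass_mapping_for_test(m),
                   unclass_mapping_for_test(fx$od_oq))
  expect_identical(colnames(m)[m["banana", ] == 1L], "Fruity")
  expect_true(all(m["buttery", ] == 0L))

  empty <- build_cata_mapping(data.frame(od_term = character(0),
                                         oq = character(0)),
                              fx$registry_od, fx$registry_oq)
  expect_identical(dim(empty), c(12L, 20L))
  expect_true(all(empty == 0L))

  reg2 <- label_registry("OD", "apple")
  two <- build_cata_mapping(data.frame(od_term = "apple",
                                       oq = c("Fruity", "Fresh")),
                            reg2, fx$registry_oq)
  expect_identical(sum(two["apple", ]), 2L)
  expect_error(build_cata_mapping(
    data.frame(od_term = c("apple", "apple"), oq = c("Fruity", "Fruity")),
    reg2, fx$registry_oq), "duplicate CATA")
})

test_that("binary mappings round-trip bit-exactly through CSV", {
  fx <- wine_aroma_fixture()
  for (m in list(fx$od_oq, fx$oq_osa)) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_mapping_csv(m, f)
    back <- read_mapping_csv(f, layers = attr(m, "layers"))
    expect_identical(unclass_mapping_for_test(back),
                     unclass_mapping_for_test(m))
    expect_identical(attr(back, "layers"), attr(m, "layers"))
  }
})

test_that("mapping construction rejects non-binary or mislabeled input", {
  expect_error(binary_mapping(matrix(2L, 1, 1, dimnames = list("a", "b"))),
               "0 or 1")
  expect_error(binary_mapping(matrix(1L, 2, 1,
                                     dimnames = list(c("a", "a"), "b"))),
               "unique")
  m0 <- binary_mapping(matrix(integer(0), 0, 0), layers = c("OD", "OQ"))
  expect_identical(dim(m0), c(0L, 0L))
})
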