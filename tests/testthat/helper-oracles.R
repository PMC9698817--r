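# Independent oracles used to cross-check the implementation. Deliberately
# naive: explicit loops and textbook formulas, no shared code with R/.

# bipartite intensity propagation by double loop
oracle_propagate <- function(counts, m) {
  out <- stats::setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    acc <- 0
    for (t in names(counts)) {
      if (t %in% rownames(m)) acc <- acc + counts[[t]] * m[t, j]
    }
    out[j] <- acc
  }
  out
}

# multi-expert union by brute-force OR over individual response matrices
oracle_fuse_or <- function(expert_matrices) {
  out <- expert_matrices[[1L]]
  for (m in expert_matrices[-1L]) out <- out | m
  storage.mode(out) <- "integer"
  out
}

# textbook pooled two-proportion z-test, two-sided
oracle_two_prop_p <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  if (se == 0) return(1)
  2 * stats::pnorm(-abs((p1 - p2) / se))
}

# random binary mapping for property tests
random_mapping <- function(nr, nc, layers, density = 0.4,
                           rows = sprintf("%s%02d", tolower(layers[1]), seq_len(nr)),
                           cols = sprintf("%s%02d", layers[2], seq_len(nc))) {
  m <- matrix(rbinom(nr * nc, 1L, density), nr, nc,
              dimnames = list(rows, cols))
  binary_mapping(m, layers = layers)
}

profile_values_for_test <- function(p) stats::setNames(as.numeric(p), names(p))

# plain integer matrix view of a binary_mapping, for identical() comparisons
unclass_mapping_for_test <- function(m) {
  m <- unclass(m)
  attr(m, "layers") <- NULL
  attr(m, "provenance") <- NULL
  m
}

expect_profile_equal <- function(p, expected, tolerance = NULL) {
  vals <- stats::setNames(as.numeric(p), names(p))
  expected <- expected[names(vals)]
  if (is.null(tolerance)) expect_identical(vals, expected)
  else expect_equal(vals, expected, tolerance = tolerance)
}
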