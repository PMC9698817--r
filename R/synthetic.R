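#' Specification of a synthetic descriptor corpus
#'
#' Describes the shape of a generated corpus with exact ground truth. The
#' defaults mirror the reference wine study's shape: 49 odorants described
#' by 3 source databases with a vocabulary of 175 odor descriptors, 20 odor
#' qualities and 15 sensory attributes, and 2 products (wines) composed of
#' odorant subsets with integer GC-olfactometry-style weights on a 1-5
#' scale.
#'
#' @param n_odorants,n_sources,n_od,n_oq,n_osa Positive integers: corpus
#'   dimensions.
#' @param od_per_odorant Integer range (length 2): per-source descriptor
#'   count drawn uniformly from it; its maximum may not exceed `n_od`.
#' @param oq_link_prob,osa_link_prob Bernoulli link probabilities in
#'   (0, 1] for the true OD x OQ and OQ x OSA matrices. Defaults are chosen
#'   to match the sparsity of expert-derived matrices (a descriptor supports
#'   at most a couple of qualities; a quality feeds a handful of
#'   attributes).
#' @param hyphen_frac,phrase_frac Fractions of the vocabulary realized as
#'   hyphenated compounds ("tivo-kalo") and two-word phrases ("tivo kalo"),
#'   the hardest paths through the tokenizer.
#' @param n_products Number of product compositions to generate.
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_odorants = 49, n_sources = 3, n_od = 175,
                        n_oq = 20, n_osa = 15, od_per_odorant = c(2L, 8L),
                        oq_link_prob = 0.05, osa_link_prob = 0.10,
                        hyphen_frac = 0.10, phrase_frac = 0.10,
                        n_products = 2, seed = 1L) {
  ints <- c(n_odorants = n_odorants, n_sources = n_sources, n_od = n_od,
            n_oq = n_oq, n_osa = n_osa, n_products = n_products)
  if (any(ints < 1) || any(ints != as.integer(ints)))
    stop("corpus dimensions must be positive integers", call. = FALSE)
  od_per_odorant <- as.integer(od_per_odorant)
  if (length(od_per_odorant) != 2L || any(od_per_odorant < 1L) ||
      od_per_odorant[1L] > od_per_odorant[2L])
    stop("od_per_odorant must be an increasing positive integer range",
         call. = FALSE)
  if (od_per_odorant[2L] > n_od)
    stop("od_per_odorant exceeds the vocabulary size n_od", call. = FALSE)
  for (p in c(oq_link_prob, osa_link_prob))
    if (!is.numeric(p) || p <= 0 || p > 1)
      stop("link probabilities must lie in (0, 1]", call. = FALSE)
  if (hyphen_frac < 0 || phrase_frac < 0 || hyphen_frac + phrase_frac > 1)
    stop("hyphen_frac and phrase_frac must be non-negative and sum to <= 1",
         call. = FALSE)
  structure(
    list(n_odorants = as.integer(n_odorants),
         n_sources = as.integer(n_sources), n_od = as.integer(n_od),
         n_oq = as.integer(n_oq), n_osa = as.integer(n_osa),
         od_per_odorant = od_per_odorant, oq_link_prob = oq_link_prob,
         osa_link_prob = osa_link_prob, hyphen_frac = hyphen_frac,
         phrase_frac = phrase_frac, n_products = as.integer(n_products),
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat(sprintf(
    "<corpus_spec> %d odorants x %d sources; %d OD / %d OQ / %d OSA; seed %d\n",
    x$n_odorants, x$n_sources, x$n_od, x$n_oq, x$n_osa, x$seed))
  invisible(x)
}

# pseudo-word supply: 3-syllable tokens, disjoint from the default stop
# rules and unable to form the discard suffixes
synth_words <- function(n) {
  syl <- c("ba", "ce", "di", "fo", "gu", "ka", "lo", "mi", "nu", "pe",
           "ra", "su", "ti", "vo", "za", "bren", "dor", "fim", "gos", "lun")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    w <- vapply(seq_len(need * 2L), function(i)
      paste(sample(syl, 3L, replace = TRUE), collapse = ""), character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

# independent brute-force propagation: explicit double loop, used only to
# compute the generator's ground truth
propagate_oracle <- function(counts, mapping) {
  out <- stats::setNames(numeric(ncol(mapping)), colnames(mapping))
  for (q in colnames(mapping)) {
    acc <- 0
    for (t in names(counts)) {
      if (t %in% rownames(mapping))
        acc <- acc + counts[[t]] * unclass_mapping(mapping)[t, q]
    }
    out[q] <- acc
  }
  out
}

#' Generate a synthetic corpus with exact ground truth
#'
#' Plants per-source descriptor term sets for every odorant, decorates them
#' into free-text descriptions using only tokens from the default stop
#' rules (so extraction is exactly invertible), draws true binary OD x OQ
#' and OQ x OSA matrices, and computes the true OQ/OSA profiles of every
#' odorant and product with an independent brute-force double-loop — never
#' with the propagation engine the corpus is meant to test. All arithmetic
#' is in integers, so pipeline recovery can be asserted exactly.
#'
#' @param spec A [corpus_spec()].
#' @return A list:
#' \describe{
#'   \item{descriptions}{data frame (`odorant_id`, `source_id`, `text`).}
#'   \item{rules}{[stop_rules()] whose phrase lexicon covers the generated
#'     two-word descriptors.}
#'   \item{vocabulary}{character vector of all `n_od` descriptor terms.}
#'   \item{od_oq, oq_osa}{true [binary_mapping()]s.}
#'   \item{compositions}{list of [product_composition()]s.}
#'   \item{truth}{planted ground truth: `per_source_terms` (list of lists),
#'     `descriptor_sets`, `profiles_oq`, `profiles_osa`,
#'     `product_profiles_oq`, `product_profiles_osa`.}
#' }
#' @examples
#' corpus <- generate_corpus(corpus_spec(n_odorants = 5, n_od = 12, seed = 7))
#' sets <- extract_corpus(corpus$descriptions, corpus$rules, quiet = TRUE)
#' identical(sets, corpus$truth$descriptor_sets)
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n_hyph <- floor(spec$hyphen_frac * spec$n_od)
  n_phrase <- floor(spec$phrase_frac * spec$n_od)
  n_plain <- spec$n_od - n_hyph - n_phrase
  # constituent words are globally unique so phrases, hyphenated compounds
  # and plain terms cannot shadow each other inside one description
  words <- synth_words(n_plain + 2L * (n_hyph + n_phrase))
  plain <- words[seq_len(n_plain)]
  rest <- words[-seq_len(n_plain)]
  hyph <- if (n_hyph) paste(rest[seq_len(n_hyph)],
                            rest[n_hyph + seq_len(n_hyph)], sep = "-")
          else character(0)
  rest <- rest[-seq_len(2L * n_hyph)]
  phrases <- if (n_phrase) paste(rest[seq_len(n_phrase)],
                                 rest[n_phrase + seq_len(n_phrase)])
             else character(0)
  vocab <- sort_c(c(plain, hyph, phrases))
  rules <- stop_rules(phrases = phrases)

  odorants <- sprintf("odorant%03d", seq_len(spec$n_odorants))
  sources <- sprintf("source%02d", seq_len(spec$n_sources))
  per_source <- lapply(odorants, function(o) {
    sets <- lapply(sources, function(s) {
      kk <- seq(spec$od_per_odorant[1L], spec$od_per_odorant[2L])
      k <- if (length(kk) == 1L) kk else sample(kk, 1L)
      sample(vocab, k)
    })
    names(sets) <- sources
    sets
  })
  names(per_source) <- odorants

  decorate <- function(terms)
    paste0("Powerful, ", paste(terms, collapse = " and "),
           " odor, very diffusive")
  descriptions <- do.call(rbind, lapply(odorants, function(o) {
    data.frame(odorant_id = o, source_id = sources,
               text = vapply(per_source[[o]], decorate, character(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(descriptions) <- NULL

  # planted counted sets: term -> number of sources citing it
  descriptor_sets <- lapply(odorants, function(o) {
    tab <- table(unlist(per_source[[o]], use.names = FALSE))
    descriptor_set(o, stats::setNames(as.integer(tab), names(tab)))
  })
  names(descriptor_sets) <- odorants

  oq_labels <- sprintf("OQ%02d", seq_len(spec$n_oq))
  osa_labels <- sprintf("OSA%02d", seq_len(spec$n_osa))
  od_oq <- binary_mapping(
    matrix(stats::rbinom(spec$n_od * spec$n_oq, 1L, spec$oq_link_prob),
           spec$n_od, spec$n_oq, dimnames = list(vocab, oq_labels)),
    layers = c("OD", "OQ"))
  oq_osa <- binary_mapping(
    matrix(stats::rbinom(spec$n_oq * spec$n_osa, 1L, spec$osa_link_prob),
           spec$n_oq, spec$n_osa, dimnames = list(oq_labels, osa_labels)),
    layers = c("OQ", "OSA"))

  profiles_oq <- lapply(descriptor_sets, function(ds)
    odor_profile(propagate_oracle(as.list(ds), od_oq), layer = "OQ"))
  profiles_osa <- lapply(profiles_oq, function(p)
    odor_profile(propagate_oracle(as.list(profile_values(p)), oq_osa),
                 layer = "OSA"))

  compositions <- lapply(seq_len(spec$n_products), function(i) {
    k <- max(1L, ceiling(spec$n_odorants / 2))
    ids <- sort_c(sample(odorants, k))
    product_composition(sprintf("product%02d", i),
                        data.frame(odorant_id = ids,
                                   weight = sample(5L, k, replace = TRUE)))
  })
  names(compositions) <- vapply(compositions, `[[`, character(1),
                                "product_id")

  weighted_sum <- function(comp, profs) {
    template <- profs[[1L]]
    acc <- stats::setNames(numeric(length(template)), names(template))
    for (i in seq_len(nrow(comp$components))) {
      p <- profs[[comp$components$odorant_id[i]]]
      for (l in names(acc))
        acc[l] <- acc[l] + comp$components$weight[i] * p[[l]]
    }
    odor_profile(acc, layer = attr(template, "layer"))
  }
  product_profiles_oq <- lapply(compositions, weighted_sum, profs = profiles_oq)
  product_profiles_osa <- lapply(compositions, weighted_sum,
                                 profs = profiles_osa)

  list(spec = spec, descriptions = descriptions, rules = rules,
       vocabulary = vocab, od_oq = od_oq, oq_osa = oq_osa,
       compositions = compositions,
       truth = list(per_source_terms = per_source,
                    descriptor_sets = descriptor_sets,
                    profiles_oq = profiles_oq,
                    profiles_osa = profiles_osa,
                    product_profiles_oq = product_profiles_oq,
                    product_profiles_osa = product_profiles_osa))
}
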