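#' Tokenization rules for free-text odorant descriptions
#'
#' Reference databases describe an odorant's smell in free prose, e.g.
#' "Powerful, ethereal-fruity odor suggestive of banana and pineapple, and
#' very diffusive". Only some of those words carry olfactory information.
#' A `stop_rules` object holds the cleaning policy applied before descriptor
#' extraction:
#'
#' * `discard_suffixes` — tokens such as "like" or "note" that qualify a
#'   descriptor without adding one; they are dropped both as standalone
#'   tokens ("fruity note") and as hyphen-attached suffixes ("fruity-like").
#' * `discard_words` — auxiliaries, connectives and hedonic/intensity
#'   modifiers ("has", "powerful", "very") that are discarded outright.
#' * `phrases` — multi-word descriptors ("ripe fruit") consulted *before*
#'   word splitting so they survive as single terms.
#' * `keep_hyphenated` — whether hyphenated compounds ("ethereal-fruity")
#'   are preserved as one term (default) or split at the hyphen.
#'
#' The default lists cover the modifier vocabulary of the bundled worked
#' example; real corpora will want to extend them (the rules can be stored
#' as YAML/CSV alongside a project and reviewed like any other config).
#' No stemming or synonym merging is ever applied: "leather" and "leathery"
#' remain distinct descriptors by design.
#'
#' @param discard_suffixes,discard_words,phrases Character vectors, lower
#'   case.
#' @param keep_hyphenated Logical flag.
#' @return An object of class `stop_rules`.
#' @examples
#' rules <- stop_rules()
#' tokenize_description("Powerful, ethereal-fruity odor suggestive of banana", rules)
#' @export
stop_rules <- function(discard_suffixes = c("like", "note", "notes"),
                       discard_words = c(
                         "has", "have", "is", "was", "with", "a", "an", "the",
                         "and", "or", "of", "in", "to", "its", "this", "that",
                         "powerful", "strong", "weak", "mild", "very",
                         "slightly", "somewhat", "diffusive", "pleasant",
                         "unpleasant", "characteristic", "typical",
                         "odor", "odour", "smell", "aroma", "flavor",
                         "flavour", "taste", "suggestive", "reminiscent",
                         "resembling", "recalls"),
                       phrases = c("ripe fruit"),
                       keep_hyphenated = TRUE) {
  chk <- function(x, what) {
    x <- as.character(x)
    if (any(x != tolower(x)))
      stop(what, " entries must be lower case", call. = FALSE)
    unique(x[nzchar(x)])
  }
  structure(
    list(discard_suffixes = chk(discard_suffixes, "discard_suffixes"),
         discard_words = chk(discard_words, "discard_words"),
         phrases = chk(phrases, "phrases"),
         keep_hyphenated = isTRUE(keep_hyphenated)),
    class = "stop_rules"
  )
}

#' @export
print.stop_rules <- function(x, ...) {
  cat(sprintf(
    "<stop_rules> %d stop words, %d suffixes, %d phrases, hyphenated %s\n",
    length(x$discard_words), length(x$discard_suffixes), length(x$phrases),
    if (x$keep_hyphenated) "kept" else "split"))
  invisible(x)
}

#' Tokenize one free-text odorant description into odor descriptors
#'
#' Lower-cases the text, extracts registered multi-word phrases, splits the
#' remainder on punctuation and whitespace (internal hyphens are kept),
#' strips hyphen-attached discard suffixes, drops stop words, and
#' deduplicates within the description while preserving first-occurrence
#' order. A term repeated inside one source description counts once: citation
#' counting happens across sources, not within them.
#'
#' @param text A single character string; may be empty.
#' @param rules A [stop_rules()] object.
#' @return Character vector of normalized descriptor terms (possibly empty),
#'   deduplicated, in order of first occurrence.
#' @examples
#' tokenize_description(
#'   "Powerful, ethereal-fruity odor suggestive of banana and pineapple, and very diffusive")
#' # -> "ethereal-fruity" "banana" "pineapple"
#' @export
tokenize_description <- function(text, rules = stop_rules()) {
  stopifnot(inherits(rules, "stop_rules"))
  if (length(text) != 1L || is.na(text)) text <- ""
  x <- tolower(text)

  # phrase pass: record which registered multi-word terms occur, at the
  # position of their first occurrence, then blank them out
  found <- character(0)
  pos <- integer(0)
  for (ph in rules$phrases) {
    pat <- paste0("(?<![[:alnum:]-])", escape_regex(ph), "(?![[:alnum:]-])")
    m <- regexpr(pat, x, perl = TRUE)
    if (m > 0L) {
      found <- c(found, ph)
      pos <- c(pos, as.integer(m))
      x <- gsub(pat, " ", x, perl = TRUE)
    }
  }

  # word pass: split on anything but letters, digits and internal hyphens
  starts <- gregexpr("[[:alnum:]]+(-[[:alnum:]]+)*", x)[[1L]]
  toks <- if (starts[1L] == -1L) character(0) else
    regmatches(x, list(starts))[[1L]]
  tpos <- if (starts[1L] == -1L) integer(0) else as.integer(starts)

  if (length(toks)) {
    if (!rules$keep_hyphenated) {
      pieces <- strsplit(toks, "-", fixed = TRUE)
      tpos <- rep(tpos, lengths(pieces))
      toks <- unlist(pieces)
    } else if (length(rules$discard_suffixes)) {
      # "fruity-like" -> "fruity"
      suf <- paste0("-(", paste(escape_regex(rules$discard_suffixes),
                                collapse = "|"), ")$")
      toks <- gsub(suf, "", toks)
    }
    drop <- toks %in% c(rules$discard_words, rules$discard_suffixes) |
      !nzchar(toks)
    toks <- toks[!drop]
    tpos <- tpos[!drop]
  }

  terms <- c(found, toks)
  ord <- order(c(pos, tpos))
  unique(terms[ord])
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Counted descriptor set of one odorant
#'
#' A descriptor set pairs each odor descriptor cited for an odorant with its
#' intensity, defined as the number of source databases citing it. Counts are
#' therefore positive integers bounded by the number of sources.
#'
#' @param odorant_id Identifier of the odorant (name, optionally with CAS
#'   number).
#' @param counts Named integer vector (names = normalized descriptor terms,
#'   values >= 1). May be empty.
#' @return An object of class `descriptor_set`: a named integer vector in
#'   deterministic alphabetical term order, with an `odorant_id` attribute.
#' @export
descriptor_set <- function(odorant_id, counts = integer()) {
  if (!is.character(odorant_id) || length(odorant_id) != 1L ||
      !nzchar(odorant_id))
    stop("odorant_id must be a non-empty string", call. = FALSE)
  nm <- names(counts)
  counts <- stats::setNames(as.integer(counts), nm)
  if (length(counts)) {
    if (is.null(nm) || any(!nzchar(nm)))
      stop("counts must be named by descriptor term", call. = FALSE)
    if (anyDuplicated(nm))
      stop("duplicate descriptor terms in counts", call. = FALSE)
    if (any(nm != trimws(tolower(nm))))
      stop("descriptor terms must be lower case and trimmed", call. = FALSE)
    if (anyNA(counts) || any(counts < 1L))
      stop("every citation count must be a positive integer", call. = FALSE)
    counts <- counts[sort_c(nm)]
  }
  structure(counts, odorant_id = odorant_id, class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %s: %d descriptor(s)\n",
              attr(x, "odorant_id"), length(x)))
  if (length(x))
    cat(paste0("  [", paste(sprintf("(%s, %d)", names(x), as.integer(x)),
                            collapse = "; "), "]\n"))
  invisible(x)
}

#' Aggregate per-source descriptor term sets into a counted descriptor set
#'
#' Implements the union-with-citation-count aggregation: the descriptor set
#' of an odorant is the union of its per-source term sets, and the intensity
#' of each term is the number of sources citing it. Each per-source set must
#' already be deduplicated (as [tokenize_description()] guarantees);
#' within-source repeats would otherwise inflate counts beyond the number of
#' sources.
#'
#' @param odorant_id Odorant identifier.
#' @param per_source_terms List of character vectors, one per source. An
#'   empty list yields an empty descriptor set.
#' @return A [descriptor_set()].
#' @examples
#' aggregate_descriptor_sets("Ethyl butanoate (CAS 105-54-4)", list(
#'   c("ethereal-fruity", "banana", "pineapple"),
#'   c("ethereal", "fruity", "buttery", "pineapple", "banana", "ripe fruit", "juicy"),
#'   c("fruity", "juicy", "pineapple", "cognac")))
#' @export
aggregate_descriptor_sets <- function(odorant_id, per_source_terms) {
  stopifnot(is.list(per_source_terms))
  per_source_terms <- lapply(per_source_terms, function(s) {
    s <- as.character(s)
    if (anyDuplicated(s))
      stop("per-source term sets must be deduplicated", call. = FALSE)
    s
  })
  all_terms <- unlist(per_source_terms, use.names = FALSE)
  if (!length(all_terms)) return(descriptor_set(odorant_id))
  tab <- table(all_terms)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  descriptor_set(odorant_id, counts)
}

#' Extract a descriptor corpus from raw description records
#'
#' Batch driver: tokenizes every (odorant, source) description and aggregates
#' per odorant across sources. Odorants whose descriptions all tokenize to
#' nothing are retained with empty descriptor sets and reported via a
#' message, so a sparse corpus is visible rather than silently shrunk.
#'
#' @param records Data frame with columns `odorant_id`, `source_id`, `text`
#'   (an optional `cas` column is carried along but unused). One row per
#'   (odorant, source) pair; duplicated pairs are an error.
#' @param rules A [stop_rules()] object.
#' @param quiet Suppress the empty-odorant message.
#' @return Named list of [descriptor_set()]s, one per odorant, in
#'   alphabetical odorant order.
#' @export
extract_corpus <- function(records, rules = stop_rules(), quiet = FALSE) {
  records <- as.data.frame(records)
  need <- c("odorant_id", "source_id", "text")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) return(structure(list(), names = character(0)))
  if (any(!nzchar(records$odorant_id)) || anyNA(records$odorant_id))
    stop("odorant_id must be non-empty", call. = FALSE)
  key <- paste(records$odorant_id, records$source_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate record for odorant '%s' from source '%s'",
                 d$odorant_id, d$source_id), call. = FALSE)
  }
  ids <- sort_c(unique(records$odorant_id))
  out <- lapply(ids, function(id) {
    texts <- records$text[records$odorant_id == id]
    aggregate_descriptor_sets(id, lapply(texts, tokenize_description,
                                         rules = rules))
  })
  names(out) <- ids
  empty <- ids[vapply(out, length, integer(1)) == 0L]
  if (length(empty) && !quiet)
    message("odorant(s) with empty descriptor sets: ",
            paste(empty, collapse = ", "))
  out
}

#' Read raw description records from CSV
#'
#' Expected columns: `odorant_id`, `source_id`, `text` (optionally `cas`),
#' UTF-8 encoded.
#'
#' @param path CSV file path.
#' @return Data frame suitable for [extract_corpus()].
#' @export
read_descriptions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        encoding = "UTF-8")
  need <- c("odorant_id", "source_id", "text")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("description CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$text[is.na(df$text)] <- ""
  df
}

#' Write descriptor sets to long-format CSV
#'
#' One row per (odorant, descriptor) pair with columns `odorant_id`,
#' `od_term`, `count`; terms in alphabetical order within each odorant.
#'
#' @param sets Named list of [descriptor_set()]s (as from
#'   [extract_corpus()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_sets_csv <- function(sets, path) {
  rows <- lapply(sets, function(ds) {
    if (!length(ds)) return(NULL)
    data.frame(odorant_id = attr(ds, "odorant_id"), od_term = names(ds),
               count = as.integer(ds), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(odorant_id = character(0), od_term = character(0),
               count = integer(0)))))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read descriptor sets from long-format CSV
#'
#' Inverse of [write_descriptor_sets_csv()].
#'
#' @param path CSV path with columns `odorant_id`, `od_term`, `count`.
#' @return Named list of [descriptor_set()]s.
#' @export
read_descriptor_sets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("odorant_id", "od_term", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("descriptor CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- sort_c(unique(df$odorant_id))
  out <- lapply(ids, function(id) {
    sub <- df[df$odorant_id == id, , drop = FALSE]
    counts <- as.integer(sub$count)
    names(counts) <- sub$od_term
    descriptor_set(id, counts)
  })
  names(out) <- ids
  out
}
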