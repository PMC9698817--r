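#' Binary mapping between two layers of the perceptual space
#'
#' A 0/1 matrix linking the labels of one layer to the next: odor descriptors
#' to odor qualities (OD x OQ) or odor qualities to sensory attributes
#' (OQ x OSA). All-zero rows are legitimate — a descriptor such as "buttery"
#' may support no odor quality at all — and are preserved.
#'
#' @param entries Numeric/integer matrix of 0s and 1s.
#' @param row_labels,col_labels Label vectors; default to the dimnames of
#'   `entries`.
#' @param layers Length-2 character vector naming the row and column layers,
#'   e.g. `c("OD", "OQ")`.
#' @return An object of class `binary_mapping`: an integer matrix with
#'   dimnames and a `layers` attribute.
#' @export
binary_mapping <- function(entries, row_labels = rownames(entries),
                           col_labels = colnames(entries),
                           layers = c("OD", "OQ")) {
  entries <- as.matrix(entries)
  if (is.null(row_labels) && nrow(entries) == 0L) row_labels <- character(0)
  if (is.null(col_labels) && ncol(entries) == 0L) col_labels <- character(0)
  if (is.null(row_labels) || is.null(col_labels))
    stop("row and column labels are required", call. = FALSE)
  if (length(row_labels) != nrow(entries) ||
      length(col_labels) != ncol(entries))
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels))
    stop("mapping labels must be unique", call. = FALSE)
  storage.mode(entries) <- "integer"
  if (anyNA(entries) || !all(entries %in% c(0L, 1L)))
    stop("mapping entries must all be 0 or 1", call. = FALSE)
  dimnames(entries) <- list(as.character(row_labels),
                            as.character(col_labels))
  layers <- as.character(layers)
  if (length(layers) != 2L)
    stop("layers must name the row and column layer", call. = FALSE)
  structure(entries, layers = layers, class = c("binary_mapping", "matrix"))
}

#' @export
print.binary_mapping <- function(x, ...) {
  ly <- attr(x, "layers")
  cat(sprintf("<binary_mapping> %s x %s: %d x %d, %d link(s)\n",
              ly[1], ly[2], nrow(x), ncol(x), sum(x)))
  print(unclass_mapping(x), ...)
  invisible(x)
}

unclass_mapping <- function(m) {
  attr(m, "layers") <- NULL
  attr(m, "provenance") <- NULL
  class(m) <- NULL
  m
}

#' Fuse multi-expert elicitations into an OQ x OSA binary mapping
#'
#' Each expert, interviewed per sensory attribute, enumerates the odor
#' qualities needed to construct that attribute. The fused mapping is the
#' set union across experts: a cell is 1 exactly when at least one expert
#' listed that quality for that attribute. The union is information-lossy,
#' so the provenance of every link (which experts contributed it) is kept
#' alongside the matrix and can be queried with [mapping_provenance()].
#'
#' @param elicitations Data frame with columns `expert_id`, `osa`, `oq`,
#'   one row per (expert, attribute, quality) statement, or a list of
#'   per-expert lists (`expert_id`, `responses` = named list OSA -> character
#'   vector of OQ).
#' @param registry_oq,registry_osa [label_registry()] objects used to
#'   canonicalize the elicited labels; unknown labels are an error naming
#'   the label and layer.
#' @return A [binary_mapping()] with OQ rows and OSA columns covering the
#'   union of elicited labels (alphabetical), plus a `provenance` attribute.
#' @export
fuse_expert_elicitations <- function(elicitations, registry_oq,
                                     registry_osa) {
  if (is.data.frame(elicitations)) {
    need <- c("expert_id", "osa", "oq")
    miss <- setdiff(need, names(elicitations))
    if (length(miss))
      stop("elicitations is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    long <- elicitations[need]
  } else {
    rows <- lapply(elicitations, function(e) {
      if (is.null(e$expert_id) || is.null(e$responses))
        stop("each elicitation needs expert_id and responses", call. = FALSE)
      if (any(lengths(e$responses) == 0L))
        stop("every elicited OSA needs at least one OQ", call. = FALSE)
      data.frame(expert_id = e$expert_id,
                 osa = rep(names(e$responses), lengths(e$responses)),
                 oq = unlist(e$responses, use.names = FALSE),
                 stringsAsFactors = FALSE)
    })
    long <- do.call(rbind, rows)
  }
  if (is.null(long) || nrow(long) == 0L)
    stop("no elicitation statements supplied", call. = FALSE)
  long$oq <- resolve_labels(long$oq, registry_oq)
  long$osa <- resolve_labels(long$osa, registry_osa)

  oq <- sort_c(unique(long$oq))
  osa <- sort_c(unique(long$osa))
  m <- matrix(0L, length(oq), length(osa), dimnames = list(oq, osa))
  m[cbind(match(long$oq, oq), match(long$osa, osa))] <- 1L
  out <- binary_mapping(m, layers = c("OQ", "OSA"))
  prov <- unique(long[c("oq", "osa", "expert_id")])
  prov <- prov[order(prov$oq, prov$osa, prov$expert_id, method = "radix"), ]
  rownames(prov) <- NULL
  attr(out, "provenance") <- prov
  out
}

#' Which experts contributed a link?
#'
#' @param mapping A fused mapping from [fuse_expert_elicitations()].
#' @param oq,osa Canonical row and column labels.
#' @return Character vector of expert ids (empty if the cell is 0).
#' @export
mapping_provenance <- function(mapping, oq, osa) {
  prov <- attr(mapping, "provenance")
  if (is.null(prov))
    stop("mapping carries no provenance", call. = FALSE)
  sort_c(prov$expert_id[prov$oq == oq & prov$osa == osa])
}

#' Build the OD x OQ mapping from check-all-that-apply (CATA) responses
#'
#' For every descriptor in the corpus a flavorist ticks all odor qualities
#' it supports — none, one, or several. Each tick becomes a 1; descriptors
#' with no tick produce all-zero rows (they contribute to no quality but
#' stay part of the ontology's OD layer).
#'
#' @param responses Data frame with columns `od_term` and `oq`, one row per
#'   tick; descriptors absent from the data frame mean "none ticked". `oq`
#'   may be `NA`/empty to state "none" explicitly.
#' @param registry_od [label_registry()] of all descriptor terms; its label
#'   set defines the mapping's rows.
#' @param registry_oq [label_registry()] of the quality layer; defines the
#'   columns.
#' @return A [binary_mapping()] with OD rows (all registry labels,
#'   alphabetical) and OQ columns.
#' @export
build_cata_mapping <- function(responses, registry_od, registry_oq) {
  need <- c("od_term", "oq")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop("responses is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  responses <- as.data.frame(responses)[need]
  od <- registry_od$labels
  oq <- registry_oq$labels
  m <- matrix(0L, length(od), length(oq), dimnames = list(od, oq))
  ticked <- responses[!is.na(responses$oq) & nzchar(responses$oq), ,
                      drop = FALSE]
  if (nrow(ticked)) {
    ticked$od_term <- resolve_labels(ticked$od_term, registry_od)
    ticked$oq <- resolve_labels(ticked$oq, registry_oq)
    key <- paste(ticked$od_term, ticked$oq, sep = "\r")
    if (anyDuplicated(key)) {
      d <- ticked[duplicated(key), , drop = FALSE][1L, ]
      stop(sprintf("duplicate CATA response: '%s' ticked twice for '%s'",
                   d$od_term, d$oq), call. = FALSE)
    }
    m[cbind(match(ticked$od_term, od), match(ticked$oq, oq))] <- 1L
  }
  binary_mapping(m, layers = c("OD", "OQ"))
}

#' Write a binary mapping to CSV
#'
#' Header row = column labels, first column = row labels, cells 0/1; the
#' format round-trips bit-exactly through [read_mapping_csv()].
#'
#' @param mapping A [binary_mapping()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_csv <- function(mapping, path) {
  stopifnot(inherits(mapping, "binary_mapping"))
  ly <- attr(mapping, "layers")
  df <- as.data.frame(unclass_mapping(mapping), check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(mapping),
                                         stringsAsFactors = FALSE), ly[1]),
              df)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a binary mapping from CSV
#'
#' @param path CSV written by [write_mapping_csv()] (or hand-maintained in
#'   the same shape).
#' @param layers Row/column layer names, e.g. `c("OQ", "OSA")`; defaults to
#'   the first header cell and `"?"`.
#' @return A [binary_mapping()].
#' @export
read_mapping_csv <- function(path, layers = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (ncol(df) < 2L)
    stop("mapping CSV needs a label column and at least one data column",
         call. = FALSE)
  if (is.null(layers)) layers <- c(names(df)[1L], "?")
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  binary_mapping(m, layers = layers)
}
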