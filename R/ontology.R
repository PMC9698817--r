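#' The four object properties linking the ontology's layers
#'
#' Descriptors are parts of qualities, qualities parts of sensory
#' attributes; each "part-of" property has an "including" inverse. An
#' assertion is present exactly when its inverse is.
#'
#' @format Character vector of the four property names.
#' @export
ODOR_PROPERTIES <- c("OD-part-of-OQ", "OQ-including-OD",
                     "OQ-part-of-OSA", "OSA-including-OQ")

# property -> c(subject layer, object layer, inverse property)
property_info <- function(property) {
  switch(property,
    "OD-part-of-OQ"    = c("OD", "OQ", "OQ-including-OD"),
    "OQ-including-OD"  = c("OQ", "OD", "OD-part-of-OQ"),
    "OQ-part-of-OSA"   = c("OQ", "OSA", "OSA-including-OQ"),
    "OSA-including-OQ" = c("OSA", "OQ", "OQ-part-of-OSA"),
    stop("unknown property '", property, "'; expected one of: ",
         paste(ODOR_PROPERTIES, collapse = ", "), call. = FALSE)
  )
}

#' Build the odor perceptual space ontology
#'
#' Assembles the three-layer ontology as a formal structure \{C, R, P\}:
#' classes C are the three top classes OD, OQ and OSA with one subclass per
#' label ("is-a" relations R), and properties P are the four object
#' properties derived from the two binary mappings — every 1-entry of the
#' OD x OQ matrix becomes an `OD-part-of-OQ` assertion (plus its
#' `OQ-including-OD` inverse), and every 1-entry of the OQ x OSA matrix an
#' `OQ-part-of-OSA` assertion (plus inverse). Labels with all-zero rows or
#' columns still become subclasses: a descriptor supporting no quality is
#' part of the vocabulary even if it contributes to no profile.
#'
#' The returned object supports [predict()][predict.odor_ontology] (descriptor
#' sets or product compositions to OQ/OSA profiles), [query_ontology()],
#' [export_owl()], `print` and `summary`.
#'
#' @param od_oq A [binary_mapping()] with OD rows and OQ columns.
#' @param oq_osa A [binary_mapping()] with OQ rows and OSA columns; its row
#'   labels must equal `od_oq`'s column labels as a set.
#' @param aliases Optional named list (`OD`, `OQ`, `OSA`) of alias vectors
#'   passed to each layer's [label_registry()], used when resolving query
#'   anchors.
#' @param base_iri Base IRI for OWL serialization; must end in `#` or `/`.
#' @return An object of class `odor_ontology`.
#' @examples
#' fx <- wine_aroma_fixture()
#' ont <- odor_ontology(fx$od_oq, fx$oq_osa)
#' query_ontology(ont, "OQ-including-OD", "almond")
#' @export
odor_ontology <- function(od_oq, oq_osa, aliases = list(),
                          base_iri = "http://example.org/odorspace#") {
  stopifnot(inherits(od_oq, "binary_mapping"),
            inherits(oq_osa, "binary_mapping"))
  if (!setequal(colnames(od_oq), rownames(oq_osa)))
    stop("OD x OQ columns and OQ x OSA rows must carry the same OQ labels",
         call. = FALSE)
  if (!grepl("[#/]$", base_iri))
    stop("base_iri must end in '#' or '/'", call. = FALSE)
  labels <- list(OD = sort_c(rownames(od_oq)),
                 OQ = sort_c(colnames(od_oq)),
                 OSA = sort_c(colnames(oq_osa)))
  # cross-layer duplicates ("Smoky" is both an OQ and an OSA) are fine:
  # IRIs are layer-prefixed. Canonical row/col order:
  od_oq <- binary_mapping(unclass_mapping(od_oq)[labels$OD, labels$OQ,
                                                 drop = FALSE],
                          layers = c("OD", "OQ"))
  oq_osa <- binary_mapping(unclass_mapping(oq_osa)[labels$OQ, labels$OSA,
                                                   drop = FALSE],
                           layers = c("OQ", "OSA"))
  regs <- lapply(c(OD = "OD", OQ = "OQ", OSA = "OSA"), function(ly) {
    al <- aliases[[ly]]
    if (is.null(al)) al <- character()
    label_registry(ly, labels[[ly]], al)
  })
  structure(
    list(labels = labels, od_oq = od_oq, oq_osa = oq_osa,
         assertions = assertions_from_mappings(od_oq, oq_osa),
         registries = regs, base_iri = base_iri),
    class = "odor_ontology"
  )
}

assertions_from_mappings <- function(od_oq, oq_osa) {
  rows <- list()
  link <- function(m, fwd, inv) {
    idx <- which(unclass_mapping(m) == 1L, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    s <- rownames(m)[idx[, 1L]]
    o <- colnames(m)[idx[, 2L]]
    rbind(data.frame(subject = s, property = fwd, object = o,
                     stringsAsFactors = FALSE),
          data.frame(subject = o, property = inv, object = s,
                     stringsAsFactors = FALSE))
  }
  df <- rbind(link(od_oq, "OD-part-of-OQ", "OQ-including-OD"),
              link(oq_osa, "OQ-part-of-OSA", "OSA-including-OQ"))
  if (is.null(df))
    df <- data.frame(subject = character(0), property = character(0),
                     object = character(0), stringsAsFactors = FALSE)
  df <- df[order(df$property, df$subject, df$object, method = "radix"), ]
  rownames(df) <- NULL
  df
}

# rebuild an ontology from layer label sets + assertion triples (import path)
ontology_from_assertions <- function(labels, assertions, base_iri) {
  mk <- function(rows, cols, prop, layers) {
    m <- matrix(0L, length(rows), length(cols),
                dimnames = list(sort_c(rows), sort_c(cols)))
    sub <- assertions[assertions$property == prop, , drop = FALSE]
    if (nrow(sub)) {
      bad <- !(sub$subject %in% rownames(m)) | !(sub$object %in% colnames(m))
      if (any(bad))
        stop("assertion links a label missing from its layer: ",
             sub$subject[bad][1L], " -> ", sub$object[bad][1L],
             call. = FALSE)
      m[cbind(match(sub$subject, rownames(m)),
              match(sub$object, colnames(m)))] <- 1L
    }
    binary_mapping(m, layers = layers)
  }
  od_oq <- mk(labels$OD, labels$OQ, "OD-part-of-OQ", c("OD", "OQ"))
  oq_osa <- mk(labels$OQ, labels$OSA, "OQ-part-of-OSA", c("OQ", "OSA"))
  ont <- odor_ontology(od_oq, oq_osa, base_iri = base_iri)
  # verify inverse closure of the input triples against the rebuilt graph
  a <- assertions[order(assertions$property, assertions$subject,
                        assertions$object, method = "radix"), ]
  rownames(a) <- NULL
  if (!identical(a, ont$assertions))
    stop("assertion set is not closed under the inverse properties",
         call. = FALSE)
  ont
}

#' @export
print.odor_ontology <- function(x, ...) {
  cat(sprintf(
    "<odor_ontology> %d OD, %d OQ, %d OSA; %d OD-OQ and %d OQ-OSA link(s)\n",
    length(x$labels$OD), length(x$labels$OQ), length(x$labels$OSA),
    sum(x$od_oq), sum(x$oq_osa)))
  invisible(x)
}

#' @export
summary.odor_ontology <- function(object, ...) {
  x <- object
  res <- list(
    n_labels = vapply(x$labels, length, integer(1)),
    n_links = c(`OD-OQ` = sum(x$od_oq), `OQ-OSA` = sum(x$oq_osa)),
    density = c(`OD-OQ` = mean(unclass_mapping(x$od_oq)),
                `OQ-OSA` = mean(unclass_mapping(x$oq_osa))),
    unlinked_od = sort_c(rownames(x$od_oq)[rowSums(x$od_oq) == 0]),
    base_iri = x$base_iri)
  class(res) <- "summary.odor_ontology"
  res
}

#' @export
print.summary.odor_ontology <- function(x, ...) {
  cat("Odor perceptual space ontology\n")
  cat(sprintf("  labels: %d OD, %d OQ, %d OSA\n", x$n_labels["OD"],
              x$n_labels["OQ"], x$n_labels["OSA"]))
  cat(sprintf("  links:  %d OD-OQ (density %.3f), %d OQ-OSA (density %.3f)\n",
              x$n_links["OD-OQ"], x$density["OD-OQ"],
              x$n_links["OQ-OSA"], x$density["OQ-OSA"]))
  if (length(x$unlinked_od))
    cat("  descriptors supporting no quality: ",
        paste(x$unlinked_od, collapse = ", "), "\n", sep = "")
  cat("  base IRI: ", x$base_iri, "\n", sep = "")
  invisible(x)
}

#' Query the ontology along one object property
#'
#' Answers the four existential query patterns, e.g. "in which OQ is the OD
#' 'almond' included?" (`OQ-including-OD` anchored at `almond`) or "which OQ
#' are parts of the OSA 'Prune'?" (`OQ-part-of-OSA` anchored at `Prune`).
#' The anchor is the object of the property; returned are all subjects
#' linked to it, in alphabetical order. Anchors are resolved through the
#' layer's registry, so spelling variants and upper-case/underscore forms
#' are accepted.
#'
#' @param g An [odor_ontology()].
#' @param pattern One of `"OD-part-of-OQ"`, `"OQ-including-OD"`,
#'   `"OQ-part-of-OSA"`, `"OSA-including-OQ"`.
#' @param anchor Label anchoring the query (object side of the property).
#' @return Character vector of subject labels (possibly empty), sorted.
#' @export
query_ontology <- function(g, pattern, anchor) {
  stopifnot(inherits(g, "odor_ontology"))
  info <- property_info(pattern)
  anchor <- resolve_label(anchor, g$registries[[info[2L]]])
  a <- g$assertions
  sort_c(a$subject[a$property == pattern & a$object == anchor])
}

#' Predict OQ or OSA profiles from the ontology
#'
#' Propagates citation-count intensities through the ontology's mappings.
#' `newdata` may be:
#'
#' * a [descriptor_set()] — returns one profile;
#' * a list of descriptor sets (a corpus, as from [extract_corpus()]) —
#'   returns a named list of profiles;
#' * a [product_composition()] — per-component profiles are computed from
#'   `corpus` and combined as a weighted sum.
#'
#' @param object An [odor_ontology()].
#' @param newdata See above.
#' @param layer Target layer: `"OSA"` (default) or `"OQ"`.
#' @param corpus Named list of descriptor sets; required when `newdata` is a
#'   product composition.
#' @param unmapped Policy for descriptors absent from the OD layer, passed
#'   to [od_to_oq()].
#' @param ... Unused.
#' @return An [odor_profile()], or a named list of them.
#' @export
predict.odor_ontology <- function(object, newdata, layer = c("OSA", "OQ"),
                                  corpus = NULL,
                                  unmapped = c("report", "error"), ...) {
  layer <- match.arg(layer)
  unmapped <- match.arg(unmapped)
  one <- function(ds) {
    p <- od_to_oq(ds, object$od_oq, unmapped = unmapped)
    if (layer == "OQ") p else oq_to_osa(p, object$oq_osa)
  }
  if (inherits(newdata, "descriptor_set")) return(one(newdata))
  if (inherits(newdata, "product_composition")) {
    if (is.null(corpus))
      stop("predicting a product profile needs `corpus` (descriptor sets ",
           "of the component odorants)", call. = FALSE)
    ids <- newdata$components$odorant_id
    missing_ids <- setdiff(ids, names(corpus))
    if (length(missing_ids))
      stop("no descriptor set for component odorant(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    profs <- lapply(corpus[ids], one)
    if (!length(profs)) {
      # empty composition: all-zero profile over the target layer
      lab <- if (layer == "OQ") object$labels$OQ else object$labels$OSA
      return(odor_profile(stats::setNames(numeric(length(lab)), lab),
                          layer = layer))
    }
    return(product_profile(newdata, profs))
  }
  if (is.list(newdata) &&
      all(vapply(newdata, inherits, logical(1), "descriptor_set"))) {
    out <- lapply(newdata, one)
    names(out) <- vapply(newdata, attr, character(1), "odorant_id")
    return(out)
  }
  stop("newdata must be a descriptor_set, a list of them, or a ",
       "product_composition", call. = FALSE)
}

#' Do two ontologies carry the same classes and assertions?
#'
#' Structural identity: equal label sets per layer and equal assertion
#' sets. Base IRIs and alias tables are presentation details and are not
#' compared.
#'
#' @param a,b [odor_ontology()] objects.
#' @return Logical scalar.
#' @export
ontology_identical <- function(a, b) {
  stopifnot(inherits(a, "odor_ontology"), inherits(b, "odor_ontology"))
  identical(a$labels, b$labels) && identical(a$assertions, b$assertions)
}
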