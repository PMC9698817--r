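# OWL 2 serialization of the ontology.
#
# The graph is flattened to RDF triples: three top classes, one owl:Class
# subclass per label (with rdfs:label keeping the human-readable name,
# spaces included), the four object properties declared as two owl:inverseOf
# pairs, and one triple per property assertion. Subclass IRIs are
# base IRI + layer prefix + "_" + URL-encoded label, so IRIs stay ASCII
# while labels round-trip verbatim through the annotations.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"

label_iri <- function(base, layer, label) {
  paste0(base, layer, "_", utils::URLencode(label, reserved = TRUE))
}

ontology_triples <- function(g) {
  base <- g$base_iri
  tri <- function(s, p, o, literal = FALSE)
    data.frame(subject = s, predicate = p, object = o, literal = literal,
               stringsAsFactors = FALSE)
  out <- list(tri(sub("[#/]$", "", base), paste0(RDF_NS, "type"),
                  paste0(OWL_NS, "Ontology")))
  for (ly in c("OD", "OQ", "OSA")) {
    top <- paste0(base, ly)
    out <- c(out, list(
      tri(top, paste0(RDF_NS, "type"), paste0(OWL_NS, "Class")),
      tri(top, paste0(RDFS_NS, "label"), ly, literal = TRUE)))
    for (lab in g$labels[[ly]]) {
      iri <- label_iri(base, ly, lab)
      out <- c(out, list(
        tri(iri, paste0(RDF_NS, "type"), paste0(OWL_NS, "Class")),
        tri(iri, paste0(RDFS_NS, "subClassOf"), top),
        tri(iri, paste0(RDFS_NS, "label"), lab, literal = TRUE)))
    }
  }
  for (prop in ODOR_PROPERTIES) {
    info <- property_info(prop)
    iri <- paste0(base, prop)
    out <- c(out, list(
      tri(iri, paste0(RDF_NS, "type"), paste0(OWL_NS, "ObjectProperty")),
      tri(iri, paste0(RDFS_NS, "label"), prop, literal = TRUE),
      tri(iri, paste0(OWL_NS, "inverseOf"), paste0(base, info[3L]))))
  }
  a <- g$assertions
  if (nrow(a)) {
    info <- t(vapply(a$property, property_info, character(3)))
    out <- c(out, list(tri(
      label_iri(base, info[, 1L], a$subject),
      paste0(base, a$property),
      label_iri(base, info[, 2L], a$object))))
  }
  do.call(rbind, out)
}

#' Export the ontology as an OWL 2 document
#'
#' Writes the full graph — three top classes, one subclass axiom per label,
#' the four object properties as two inverse pairs, and all property
#' assertions — in Turtle (default, diff-friendly) or RDF/XML.
#' [import_owl()] reads either dialect back to an identical graph.
#'
#' @param g An [odor_ontology()].
#' @param path Output file path.
#' @param dialect `"turtle"` or `"rdfxml"`.
#' @return `path`, invisibly.
#' @export
export_owl <- function(g, path, dialect = c("turtle", "rdfxml")) {
  stopifnot(inherits(g, "odor_ontology"))
  dialect <- match.arg(dialect)
  triples <- ontology_triples(g)
  if (dialect == "turtle") write_turtle(triples, path)
  else write_rdfxml(triples, path, g$base_iri)
  invisible(path)
}

write_turtle <- function(triples, path) {
  esc <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
  fmt_o <- function(o, lit) ifelse(lit, paste0('"', esc(o), '"'),
                                   paste0("<", o, ">"))
  abbrev <- function(p) {
    p <- sub(RDF_NS, "rdf:", p, fixed = TRUE)
    p <- sub(RDFS_NS, "rdfs:", p, fixed = TRUE)
    p <- sub(OWL_NS, "owl:", p, fixed = TRUE)
    ifelse(grepl("^(rdf|rdfs|owl):", p), p, paste0("<", p, ">"))
  }
  lines <- c(
    paste0("@prefix rdf: <", RDF_NS, "> ."),
    paste0("@prefix rdfs: <", RDFS_NS, "> ."),
    paste0("@prefix owl: <", OWL_NS, "> ."),
    "")
  pred <- abbrev(triples$predicate)
  pred[pred == "rdf:type"] <- "a"
  for (s in unique(triples$subject)) {
    i <- which(triples$subject == s)
    body <- paste0("    ", pred[i],
                   " ", fmt_o(triples$object[i], triples$literal[i]),
                   c(rep(" ;", length(i) - 1L), " ."))
    lines <- c(lines, paste0("<", s, ">"), body, "")
  }
  writeLines(lines, path, useBytes = TRUE)
}

write_rdfxml <- function(triples, path, base) {
  doc <- xml2::xml_new_root("rdf:RDF",
    "xmlns:rdf" = RDF_NS, "xmlns:rdfs" = RDFS_NS, "xmlns:owl" = OWL_NS,
    "xmlns:os" = base)
  qn <- function(p) {
    if (startsWith(p, RDF_NS)) paste0("rdf:", sub(RDF_NS, "", p, fixed = TRUE))
    else if (startsWith(p, RDFS_NS)) paste0("rdfs:", sub(RDFS_NS, "", p, fixed = TRUE))
    else if (startsWith(p, OWL_NS)) paste0("owl:", sub(OWL_NS, "", p, fixed = TRUE))
    else paste0("os:", sub(base, "", p, fixed = TRUE))
  }
  type_p <- paste0(RDF_NS, "type")
  for (s in unique(triples$subject)) {
    rows <- triples[triples$subject == s, , drop = FALSE]
    ty <- rows$object[rows$predicate == type_p][1L]
    node <- xml2::xml_add_child(doc, qn(ty), "rdf:about" = s)
    rest <- rows[rows$predicate != type_p, , drop = FALSE]
    for (j in seq_len(nrow(rest))) {
      if (rest$literal[j])
        xml2::xml_add_child(node, qn(rest$predicate[j]), rest$object[j])
      else
        xml2::xml_add_child(node, qn(rest$predicate[j]),
                            "rdf:resource" = rest$object[j])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import an OWL 2 document written by [export_owl()]
#'
#' Reads Turtle or RDF/XML (auto-detected from content) back into an
#' [odor_ontology()]. The document must declare the three top classes and
#' all four object properties; a document missing any of the four
#' properties is rejected. Subclass labels are taken from `rdfs:label`
#' annotations, falling back to URL-decoding the IRI.
#'
#' The Turtle reader covers the triple subset this package emits (IRIs,
#' prefixed names, plain literals, predicate-object lists); it is not a
#' general Turtle parser.
#'
#' @param path OWL file path.
#' @param dialect `"auto"` (default), `"turtle"` or `"rdfxml"`.
#' @return An [odor_ontology()].
#' @export
import_owl <- function(path, dialect = c("auto", "turtle", "rdfxml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    head <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "\n")
    dialect <- if (grepl("<rdf:RDF|<\\?xml", head)) "rdfxml" else "turtle"
  }
  triples <- if (dialect == "turtle") read_turtle(path) else
    read_rdfxml(path)
  ontology_from_triples(triples)
}

ontology_from_triples <- function(triples) {
  type_p <- paste0(RDF_NS, "type")
  onts <- triples$subject[triples$predicate == type_p &
                            triples$object == paste0(OWL_NS, "Ontology")]
  props <- triples$subject[triples$predicate == type_p &
                             triples$object == paste0(OWL_NS, "ObjectProperty")]
  # the base IRI is recovered from the ontology header when present
  # (the header drops the trailing separator), else from a property IRI
  cands <- c(if (length(onts)) paste0(onts[1L], c("#", "/")),
             if (length(props))
               sub(paste0("(", paste(ODOR_PROPERTIES, collapse = "|"), ")$"),
                   "", props[1L]))
  base <- cands[1L]
  for (b in cands) {
    if (all(paste0(b, ODOR_PROPERTIES) %in% props)) { base <- b; break }
  }
  prop_iris <- paste0(base, ODOR_PROPERTIES)
  missing_p <- ODOR_PROPERTIES[!(prop_iris %in% props)]
  if (length(props) == 0L || length(missing_p))
    stop("OWL document does not declare the four object properties",
         if (length(missing_p)) paste0(" (missing: ",
                                       paste(missing_p, collapse = ", "), ")"),
         call. = FALSE)

  lab_of <- function(iris) {
    vapply(iris, function(i) {
      l <- triples$object[triples$subject == i &
                            triples$predicate == paste0(RDFS_NS, "label")]
      if (length(l)) l[1L] else
        utils::URLdecode(sub("^.*#(OD|OQ|OSA)_", "", i))
    }, character(1))
  }
  labels <- list()
  for (ly in c("OD", "OQ", "OSA")) {
    top <- paste0(base, ly)
    subs <- triples$subject[
      triples$predicate == paste0(RDFS_NS, "subClassOf") &
        triples$object == top]
    labels[[ly]] <- unname(lab_of(subs))
  }
  is_assert <- triples$predicate %in% prop_iris
  a <- triples[is_assert, , drop = FALSE]
  assertions <- data.frame(
    subject = unname(lab_of(a$subject)),
    property = sub(base, "", a$predicate, fixed = TRUE),
    object = unname(lab_of(a$object)),
    stringsAsFactors = FALSE)
  ontology_from_assertions(labels, assertions, base)
}

read_rdfxml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expand <- function(node) {
    # resolve "prefix:name" against the document's namespace table
    nm <- xml2::xml_name(node, ns)
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && parts[1L] %in% names(ns))
      paste0(ns[[parts[1L]]], parts[2L]) else nm
  }
  rows <- list()
  for (node in xml2::xml_children(doc)) {
    s <- xml2::xml_attr(node, "about")
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, predicate = paste0(RDF_NS, "type"),
      object = expand(node), literal = FALSE, stringsAsFactors = FALSE)
    for (child in xml2::xml_children(node)) {
      res <- xml2::xml_attr(child, "resource")
      if (is.na(res))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, predicate = expand(child),
          object = xml2::xml_text(child), literal = TRUE,
          stringsAsFactors = FALSE)
      else
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, predicate = expand(child), object = res,
          literal = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# minimal Turtle reader for the subset written by write_turtle(): @prefix
# directives, <IRI> and prefix:name terms, "literal" objects, 'a',
# ';' predicate lists and ',' object lists.
read_turtle <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  toks <- turtle_tokens(text)
  prefixes <- character()
  rows <- list()
  i <- 1L
  n <- length(toks)
  term <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    if (tok == "a") return(paste0(RDF_NS, "type"))
    parts <- strsplit(tok, ":", fixed = TRUE)[[1L]]
    pfx <- parts[1L]
    if (!pfx %in% names(prefixes))
      stop("undeclared Turtle prefix '", pfx, ":'", call. = FALSE)
    paste0(prefixes[[pfx]],
           if (length(parts) > 1L) paste(parts[-1L], collapse = ":") else "")
  }
  while (i <= n) {
    if (toks[i] == "@prefix") {
      pfx <- sub(":$", "", toks[i + 1L])
      prefixes[pfx] <- substr(toks[i + 2L], 2L, nchar(toks[i + 2L]) - 1L)
      if (toks[i + 3L] != ".")
        stop("malformed @prefix directive", call. = FALSE)
      i <- i + 4L
      next
    }
    s <- term(toks[i]); i <- i + 1L
    repeat {
      p <- term(toks[i]); i <- i + 1L
      repeat {
        o <- toks[i]; i <- i + 1L
        lit <- startsWith(o, '"')
        o <- if (lit) turtle_unescape(substr(o, 2L, nchar(o) - 1L)) else
          term(o)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, predicate = p, object = o, literal = lit,
          stringsAsFactors = FALSE)
        if (i > n || toks[i] != ",") break
        i <- i + 1L
      }
      if (i > n || toks[i] != ";") break
      i <- i + 1L
      # trailing ';' before '.' is legal
      if (i <= n && toks[i] == ".") break
    }
    if (i > n || toks[i] != ".")
      stop("expected '.' terminating a Turtle statement", call. = FALSE)
    i <- i + 1L
  }
  do.call(rbind, rows)
}

turtle_tokens <- function(text) {
  pat <- paste0(
    '"(\\\\.|[^"\\\\])*"',   # quoted literal
    "|<[^>]*>",              # IRI
    "|@prefix",
    "|[.;,]",
    "|[^\\s.;,\"<>][^\\s;,\"<>]*")  # bare term (prefixed name or 'a')
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character(0))
  toks <- regmatches(text, list(m))[[1L]]
  # a bare term may end in '.', e.g. 'rdf:type.' never emitted by us, but
  # guard: split a trailing '.' off non-IRI, non-literal tokens
  out <- character(0)
  for (t in toks) {
    if (!startsWith(t, "<") && !startsWith(t, '"') && nchar(t) > 1L &&
        endsWith(t, ".")) {
      out <- c(out, substr(t, 1L, nchar(t) - 1L), ".")
    } else out <- c(out, t)
  }
  out
}

turtle_unescape <- function(x) {
  x <- gsub('\\\\"', '"', x)
  gsub("\\\\\\\\", "\\\\", x)
}
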