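#' Label registry for one ontology layer
#'
#' A registry fixes the canonical spelling of every label in one layer of the
#' perceptual space (OD, OQ or OSA) and maps known spelling variants onto the
#' canonical forms. Source material is rarely consistent: the same odor
#' quality may appear as "Lactony", "Lactoniy" or "Lactonic" depending on the
#' table, and sensory attributes are sometimes printed in upper case with
#' underscores ("CHERRY_COOKED"). Exact string matching would silently drop
#' such links, so all label resolution in the package goes through a registry.
#'
#' Matching is case-insensitive and treats underscores and runs of whitespace
#' as a single space; after that normalization the alias table is consulted.
#'
#' @param layer One of `"OD"`, `"OQ"`, `"OSA"`.
#' @param labels Character vector of canonical labels, unique
#'   case-insensitively.
#' @param aliases Named character vector mapping variant spellings (names) to
#'   canonical labels (values); every value must occur in `labels`.
#' @return An object of class `label_registry`.
#' @examples
#' reg <- label_registry("OQ", c("Fruity", "Lactony"),
#'                       aliases = c(Lactonic = "Lactony"))
#' resolve_label("LACTONIC", reg)
#' @seealso [resolve_label()]
#' @export
label_registry <- function(layer = c("OD", "OQ", "OSA"), labels,
                           aliases = character()) {
  layer <- match.arg(layer)
  labels <- as.character(labels)
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("registry labels must be non-empty strings", call. = FALSE)
  if (anyDuplicated(tolower(labels)))
    stop("registry labels must be unique case-insensitively", call. = FALSE)
  aliases <- vapply(aliases, as.character, character(1))
  if (length(aliases) && (is.null(names(aliases)) || any(!nzchar(names(aliases)))))
    stop("aliases must be a named character vector", call. = FALSE)
  bad <- setdiff(aliases, labels)
  if (length(bad))
    stop("alias target(s) not among canonical labels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(layer = layer, labels = sort_c(labels), aliases = aliases),
    class = "label_registry"
  )
}

#' @export
print.label_registry <- function(x, ...) {
  cat(sprintf("<label_registry> layer %s: %d labels, %d aliases\n",
              x$layer, length(x$labels), length(x$aliases)))
  invisible(x)
}

# case-, underscore- and whitespace-insensitive key
normalize_label_key <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[_[:space:]]+", " ", x)
  x
}

#' Resolve a raw label to its canonical form
#'
#' Tries, in order: exact match, normalized match (case / underscore /
#' whitespace insensitive), then the registry's alias table (itself matched
#' on the normalized key). Unresolvable labels raise an error listing the
#' nearest canonical labels by edit distance.
#'
#' @param raw A single character string.
#' @param registry A [label_registry()].
#' @return The canonical label (length-1 character).
#' @examples
#' reg <- label_registry("OSA", c("Cherry cooked", "Prune"))
#' resolve_label("CHERRY_COOKED", reg)
#' @export
resolve_label <- function(raw, registry) {
  stopifnot(inherits(registry, "label_registry"))
  if (length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw)))
    stop("label to resolve must be a single non-empty string", call. = FALSE)
  labels <- registry$labels
  if (raw %in% labels) return(raw)
  key <- normalize_label_key(raw)
  hit <- which(normalize_label_key(labels) == key)
  if (length(hit) == 1L) return(labels[hit])
  if (length(registry$aliases)) {
    ak <- normalize_label_key(names(registry$aliases))
    hit <- which(ak == key)
    if (length(hit) == 1L) return(unname(registry$aliases[hit]))
  }
  d <- utils::adist(key, normalize_label_key(labels))[1L, ]
  near <- labels[order(d)][seq_len(min(3L, length(labels)))]
  stop(sprintf("label '%s' not found in %s registry; nearest: %s",
               raw, registry$layer, paste(near, collapse = ", ")),
       call. = FALSE)
}

#' Resolve a vector of labels
#' @param raw Character vector.
#' @param registry A [label_registry()].
#' @return Character vector of canonical labels.
#' @keywords internal
resolve_labels <- function(raw, registry) {
  vapply(raw, resolve_label, character(1), registry = registry,
         USE.NAMES = FALSE)
}

# locale-independent alphabetical order, used everywhere a deterministic
# label order is promised
sort_c <- function(x) {
  if (is.null(x)) x <- character(0)
  sort(x, method = "radix")
}
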