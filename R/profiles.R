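#' Intensity profile over one perceptual layer
#'
#' A non-negative intensity vector defined over the *full* label set of its
#' layer (explicit zeros), in deterministic alphabetical label order.
#' Intensities are dimensionless: for single odorants they are citation
#' sums, for products they are citation sums weighted by component
#' intensities and so need not be integers.
#'
#' @param values Named numeric vector; labels not in `values` are filled
#'   with 0 when `labels` is given.
#' @param layer `"OQ"` or `"OSA"`.
#' @param labels Full label set of the layer; defaults to `names(values)`.
#' @return An object of class `odor_profile`.
#' @export
odor_profile <- function(values, layer = c("OQ", "OSA"), labels = NULL) {
  layer <- match.arg(layer)
  values <- unlist(values)
  if (is.null(labels)) labels <- names(values)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("profile labels are required", call. = FALSE)
  labels <- sort_c(as.character(labels))
  if (anyDuplicated(labels))
    stop("profile labels must be unique", call. = FALSE)
  out <- stats::setNames(numeric(length(labels)), labels)
  if (length(values)) {
    if (is.null(names(values)))
      stop("values must be named by label", call. = FALSE)
    unknown <- setdiff(names(values), labels)
    if (length(unknown))
      stop("value label(s) outside the layer: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    out[names(values)] <- as.numeric(values)
  }
  if (anyNA(out) || any(out < 0))
    stop("profile intensities must be non-negative", call. = FALSE)
  structure(out, layer = layer, class = "odor_profile")
}

#' @export
print.odor_profile <- function(x, digits = 4, ...) {
  cat(sprintf("<odor_profile> layer %s (%d labels)\n", attr(x, "layer"),
              length(x)))
  v <- format(round(as.numeric(x), digits), trim = TRUE)
  cat(paste0("  [", paste(sprintf("(%s, %s)", names(x), v), collapse = "; "),
             "]\n"))
  invisible(x)
}

profile_values <- function(p) stats::setNames(as.numeric(p), names(p))

#' Propagate a descriptor set through the OD x OQ mapping
#'
#' The odor-quality intensity of an odorant is the citation-count mass of
#' its descriptors flowing along the binary links:
#' `value[q] = sum_d count[d] * entry[d, q]`. A descriptor ticked for
#' several qualities contributes its full count to each (no splitting).
#'
#' Descriptors absent from the mapping contribute nothing; by default they
#' are tolerated and reported in the result's `unmapped` attribute (a real
#' corpus is rarely closed), while `unmapped = "error"` makes the first
#' unmapped descriptor fatal.
#'
#' @param ds A [descriptor_set()].
#' @param mapping A [binary_mapping()] with OD rows and OQ columns.
#' @param unmapped `"report"` (default) or `"error"`.
#' @return An [odor_profile()] over the mapping's OQ labels, with attribute
#'   `unmapped` listing tolerated descriptors.
#' @examples
#' fx <- wine_aroma_fixture()
#' ds <- extract_corpus(fx$descriptions)[[1]]
#' od_to_oq(ds, fx$od_oq)
#' @export
od_to_oq <- function(ds, mapping, unmapped = c("report", "error")) {
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(ds, "descriptor_set"), inherits(mapping, "binary_mapping"))
  terms <- names(ds)
  missing_terms <- setdiff(terms, rownames(mapping))
  if (length(missing_terms) && unmapped == "error")
    stop("descriptor(s) not in the OD x OQ mapping: ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  known <- setdiff(terms, missing_terms)
  v <- numeric(ncol(mapping))
  if (length(known))
    v <- drop(as.numeric(ds[known]) %*%
                unclass_mapping(mapping)[known, , drop = FALSE])
  out <- odor_profile(stats::setNames(v, colnames(mapping)), layer = "OQ")
  attr(out, "unmapped") <- sort_c(missing_terms)
  out
}

#' Propagate an OQ profile through the OQ x OSA mapping
#'
#' `value[s] = sum_q p[q] * entry[q, s]`. The profile must be defined over
#' exactly the mapping's row labels.
#'
#' @param p An [odor_profile()] of layer OQ.
#' @param mapping A [binary_mapping()] with OQ rows and OSA columns.
#' @return An [odor_profile()] over the mapping's OSA labels.
#' @export
oq_to_osa <- function(p, mapping) {
  stopifnot(inherits(p, "odor_profile"), inherits(mapping, "binary_mapping"))
  if (!setequal(names(p), rownames(mapping)))
    stop("profile labels do not match the mapping's rows", call. = FALSE)
  v <- drop(as.numeric(p[rownames(mapping)]) %*% unclass_mapping(mapping))
  odor_profile(stats::setNames(v, colnames(mapping)), layer = "OSA")
}

#' Weighted composition of a multi-odorant product
#'
#' @param product_id Product identifier (e.g. a wine code).
#' @param components Data frame with columns `odorant_id` and `weight`
#'   (non-negative, e.g. GC-olfactometry intensities). Missing `weight`
#'   defaults to 1 for every component, reproducing unweighted summation.
#' @return An object of class `product_composition`.
#' @export
product_composition <- function(product_id, components) {
  if (!is.character(product_id) || length(product_id) != 1L ||
      !nzchar(product_id))
    stop("product_id must be a non-empty string", call. = FALSE)
  components <- as.data.frame(components)
  if (!"odorant_id" %in% names(components))
    stop("components needs an odorant_id column", call. = FALSE)
  if (!"weight" %in% names(components)) components$weight <- 1
  components <- components[c("odorant_id", "weight")]
  if (anyDuplicated(components$odorant_id))
    stop("component odorants must be unique within a product", call. = FALSE)
  components$weight <- as.numeric(components$weight)
  if (anyNA(components$weight) || any(components$weight < 0))
    stop("component weights must be non-negative", call. = FALSE)
  structure(list(product_id = product_id, components = components),
            class = "product_composition")
}

#' @export
print.product_composition <- function(x, ...) {
  cat(sprintf("<product_composition> %s: %d component(s)\n", x$product_id,
              nrow(x$components)))
  invisible(x)
}

#' Weighted-sum profile of a product
#'
#' The product's profile is the linear combination of its components'
#' profiles: `value[l] = sum_m weight(m) * profile_m[l]`. The linearity is a
#' deliberate modeling floor — perceptual interactions in mixtures (synergy,
#' masking, configural blending) are outside this model.
#'
#' @param comp A [product_composition()].
#' @param profiles Named list of [odor_profile()]s (same layer), keyed by
#'   odorant id; must cover every component.
#' @return An [odor_profile()] of the common layer. An empty composition
#'   yields an all-zero profile over the layer of the first profile in
#'   `profiles` (which must then be non-empty to define the label set).
#' @export
product_profile <- function(comp, profiles) {
  stopifnot(inherits(comp, "product_composition"))
  ids <- comp$components$odorant_id
  missing_ids <- setdiff(ids, names(profiles))
  if (length(missing_ids))
    stop("no profile for component odorant(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  if (!length(profiles))
    stop("profiles must contain at least one profile to define the layer",
         call. = FALSE)
  layers <- unique(vapply(profiles, attr, character(1), "layer"))
  if (length(layers) != 1L)
    stop("all profiles must share one layer", call. = FALSE)
  template <- profiles[[1L]]
  v <- stats::setNames(numeric(length(template)), names(template))
  for (i in seq_along(ids)) {
    p <- profiles[[ids[i]]]
    if (!identical(names(p), names(v)))
      stop("profile label sets differ across components", call. = FALSE)
    v <- v + comp$components$weight[i] * as.numeric(p)
  }
  odor_profile(v, layer = layers)
}

#' Write profiles to long-format CSV
#'
#' Columns `entity_id`, `layer`, `label`, `value`; labels in deterministic
#' alphabetical order.
#'
#' @param profiles Named list of [odor_profile()]s keyed by entity id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- mapply(function(p, id) {
    data.frame(entity_id = id, layer = attr(p, "layer"), label = names(p),
               value = as.numeric(p), stringsAsFactors = FALSE)
  }, profiles, names(profiles), SIMPLIFY = FALSE)
  df <- do.call(rbind, c(rows, list(
    data.frame(entity_id = character(0), layer = character(0),
               label = character(0), value = numeric(0)))))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read profiles from long-format CSV
#' @param path CSV written by [write_profiles_csv()].
#' @return Named list of [odor_profile()]s.
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("entity_id", "layer", "label", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- unique(df$entity_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$entity_id == id, , drop = FALSE]
    layer <- unique(sub$layer)
    if (length(layer) != 1L)
      stop("entity '", id, "' mixes layers", call. = FALSE)
    odor_profile(stats::setNames(sub$value, sub$label), layer = layer)
  })
  names(out) <- ids
  out
}
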