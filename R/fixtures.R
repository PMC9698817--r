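# Bundled worked example: the red-wine aroma vocabulary (20 odor qualities,
# 15 sensory attributes), the expert OQ x OSA matrix, the CATA OD x OQ
# matrix for the nine descriptors of ethyl butanoate, and the three source
# database descriptions of that odorant. Small enough to transcribe in code,
# which keeps it bit-stable and text-only.

wine_oq_labels <- function() c(
  "Almond", "Cooked", "Cut-grass", "Floral", "Fresh", "Fruity", "Green",
  "Honey", "Lactony", "Leather", "Peel", "Smoky", "Spicy", "Sulfurous",
  "Toasty", "Vanilla", "Vegetable", "Violet", "Wine-like", "Woody")

wine_osa_labels <- function() c(
  "Bell pepper", "Blackcurrant bud", "Blackcurrant fresh", "Cherry cooked",
  "Cherry fresh", "Cherry stone", "Cut-grass", "Leather", "Prune", "Smoky",
  "Strawberry fresh", "Toasty", "Vanilla", "Violet", "Woody")

#' Spelling aliases of the wine odor-quality layer
#'
#' The quality "Lactony" circulates under the variants "Lactonic" and
#' "Lactoniy"; this alias table maps both onto the canonical form.
#'
#' @return Named character vector (variant -> canonical).
#' @export
wine_oq_aliases <- function() c(Lactonic = "Lactony", Lactoniy = "Lactony")

wine_oq_osa_matrix <- function() {
  oq <- wine_oq_labels()
  osa <- wine_osa_labels()
  links <- list(
    Almond = c("Cherry cooked", "Cherry fresh", "Cherry stone", "Prune"),
    Cooked = c("Cherry cooked", "Cherry fresh", "Cherry stone", "Prune",
               "Strawberry fresh"),
    `Cut-grass` = "Cut-grass",
    Floral = c("Bell pepper", "Blackcurrant bud", "Blackcurrant fresh",
               "Cherry cooked", "Cherry fresh", "Cherry stone",
               "Strawberry fresh"),
    Fresh = c("Bell pepper", "Blackcurrant bud", "Blackcurrant fresh"),
    Fruity = c("Blackcurrant bud", "Blackcurrant fresh", "Prune",
               "Strawberry fresh"),
    Green = c("Bell pepper", "Blackcurrant bud", "Blackcurrant fresh",
              "Cherry cooked", "Cherry fresh", "Cherry stone",
              "Strawberry fresh"),
    Honey = "Prune",
    Lactony = "Prune",
    Leather = "Leather",
    Peel = c("Cherry cooked", "Cherry fresh", "Cherry stone"),
    Smoky = "Smoky",
    Spicy = c("Cherry cooked", "Cherry fresh", "Cherry stone"),
    Sulfurous = c("Bell pepper", "Blackcurrant bud", "Blackcurrant fresh"),
    Toasty = c("Bell pepper", "Toasty"),
    Vanilla = c("Blackcurrant bud", "Vanilla"),
    Vegetable = "Bell pepper",
    Violet = character(0),
    `Wine-like` = c("Blackcurrant bud", "Blackcurrant fresh"),
    Woody = "Woody")
  m <- matrix(0L, length(oq), length(osa), dimnames = list(oq, osa))
  for (q in names(links)) m[q, links[[q]]] <- 1L
  binary_mapping(m, layers = c("OQ", "OSA"))
}

wine_od_oq_matrix <- function() {
  # nine ethyl butanoate descriptors plus the three descriptors whose
  # quality links are documented in the study's query/visualization
  # examples: almond -> Almond, vanilla/tonka -> Vanilla
  od <- c("almond", "banana", "buttery", "cognac", "ethereal",
          "ethereal-fruity", "fruity", "juicy", "pineapple", "ripe fruit",
          "tonka", "vanilla")
  oq <- wine_oq_labels()
  m <- matrix(0L, length(od), length(oq), dimnames = list(od, oq))
  m[c("banana", "ethereal-fruity", "fruity", "pineapple", "ripe fruit"),
    "Fruity"] <- 1L
  m["almond", "Almond"] <- 1L
  m[c("tonka", "vanilla"), "Vanilla"] <- 1L
  binary_mapping(m, layers = c("OD", "OQ"))
}

ethyl_butanoate_descriptions <- function() {
  data.frame(
    odorant_id = "Ethyl butanoate (CAS 105-54-4)",
    source_id = c("Arctander", "Flavor-Base", "GoodScents"),
    text = c(
      "Powerful, ethereal-fruity odor suggestive of banana and pineapple, and very diffusive",
      "ethereal, fruity, buttery, pineapple, banana, ripe fruit, juicy",
      "fruity, juicy, pineapple, cognac"),
    stringsAsFactors = FALSE)
}

#' Bundled worked example: red-wine aroma ontology data
#'
#' A self-contained data set for the package's worked example, transcribed
#' from a published red-wine aroma study: the three source-database
#' descriptions of ethyl butanoate (CAS 105-54-4), the CATA OD x OQ matrix
#' over its nine descriptors and the 20 elicited odor qualities, the
#' four-expert OQ x OSA matrix over the 15 wine sensory attributes, and
#' label registries (with the known spelling variants of the quality layer
#' as aliases).
#'
#' Propagating the aggregated ethyl butanoate descriptor set through these
#' matrices gives the classic result: all citation mass (9) lands on the
#' quality Fruity, and from there on the attributes Blackcurrant bud,
#' Blackcurrant fresh, Prune and Strawberry fresh.
#'
#' @return A list with elements `descriptions` (data frame: `odorant_id`,
#'   `source_id`, `text`), `od_oq` and `oq_osa` ([binary_mapping()]s),
#'   `registry_od`, `registry_oq`, `registry_osa` ([label_registry()]s),
#'   and `rules` (the [stop_rules()] the descriptions were written for).
#' @examples
#' fx <- wine_aroma_fixture()
#' corpus <- extract_corpus(fx$descriptions, fx$rules)
#' ont <- odor_ontology(fx$od_oq, fx$oq_osa,
#'                      aliases = list(OQ = wine_oq_aliases()))
#' predict(ont, corpus[[1]], layer = "OQ")
#' @export
wine_aroma_fixture <- function() {
  od_oq <- wine_od_oq_matrix()
  list(
    descriptions = ethyl_butanoate_descriptions(),
    od_oq = od_oq,
    oq_osa = wine_oq_osa_matrix(),
    registry_od = label_registry("OD", rownames(od_oq)),
    registry_oq = label_registry("OQ", wine_oq_labels(),
                                 aliases = wine_oq_aliases()),
    registry_osa = label_registry("OSA", wine_osa_labels()),
    rules = stop_rules())
}
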