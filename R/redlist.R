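#' Red List category mapping
#'
#' National Red Lists score each species on an ordered rarity scale and an
#' ordered decline scale.  The pipeline reduces each scale to a binary:
#' a species is "rare" when its category is at or above the rarity threshold
#' category, and "declining" when its decline category is at or above the
#' decline threshold.  The published thresholds are the category "rare"
#' (and higher) for rarity and "moderately declining" (and higher) for
#' decline; category systems differ slightly between species groups, so the
#' ordered lists are configurable.
#'
#' @param rarity_categories character vector of rarity categories, ordered
#'   from least to most rare.
#' @param rarity_threshold the category at which a species counts as rare.
#' @param decline_categories character vector of decline categories, ordered
#'   from least to most declining.
#' @param decline_threshold the category at which a species counts as
#'   declining.
#'
#' @return An object of class `redlist_mapping`.
#' @export
#' @examples
#' m <- redlist_mapping()
#' map_redlist("rare", m, "rarity")                 # 1
#' map_redlist("moderately declining", m, "decline") # 1
redlist_mapping <- function(
    rarity_categories = c("common", "rather rare", "rare",
                          "very rare", "extremely rare"),
    rarity_threshold = "rare",
    decline_categories = c("stable or increasing", "slightly declining",
                           "moderately declining", "strongly declining",
                           "very strongly declining"),
    decline_threshold = "moderately declining") {
  check_axis <- function(categories, threshold, axis) {
    if (anyDuplicated(categories)) stopf("duplicate %s categories", axis)
    if (!threshold %in% categories) {
      stopf("%s threshold '%s' is not among the ordered categories",
            axis, threshold)
    }
  }
  check_axis(rarity_categories, rarity_threshold, "rarity")
  check_axis(decline_categories, decline_threshold, "decline")
  structure(
    list(rarity = list(categories = rarity_categories,
                       threshold = rarity_threshold),
         decline = list(categories = decline_categories,
                        threshold = decline_threshold)),
    class = "redlist_mapping"
  )
}

#' Map a Red List category to a binary label
#'
#' Monotone by construction: every category at or above the axis threshold
#' maps to 1, every category below it to 0.
#'
#' @param category a category label present in the mapping's ordered list.
#' @param mapping a [redlist_mapping()].
#' @param axis `"rarity"` or `"decline"`.
#' @return integer 0 or 1 (vectorised over `category`).
#' @export
map_redlist <- function(category, mapping, axis = c("rarity", "decline")) {
  axis <- match.arg(axis)
  ax <- mapping[[axis]]
  pos <- match(category, ax$categories)
  if (anyNA(pos)) {
    stopf("unknown %s category: '%s'", axis, category[which(is.na(pos))[1]])
  }
  as.integer(pos >= match(ax$threshold, ax$categories))
}
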