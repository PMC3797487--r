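#' Attribute metadata
#'
#' An `attribute_spec` describes one categorical predictor ("attribute") of a
#' species table: its measurement kind, the number of category levels, the
#' availability tier at which it becomes knowable for unassessed species, and
#' a free-text note on how it was derived.
#'
#' Attributes have between 2 and 10 category levels; most trait attributes in
#' practice are binary or five-level ordinals.  Availability tiers are nested:
#' everything knowable for poorly known species is also knowable for
#' well-known species, and everything knowable for well-known species is also
#' knowable for species evaluated for a Red List.  Distribution-derived
#' attributes (preference, specialization, commonness) live in the
#' `"evaluated"` tier because they require systematic occupancy data.
#'
#' @param name attribute identifier (single string).
#' @param kind one of `"binary"`, `"ordinal"`, `"nominal"`.
#' @param n_categories integer number of levels, between 2 and 10.
#'   Binary attributes must have exactly 2.
#' @param tier lowest availability tier at which the attribute is knowable:
#'   one of `"poorly_known"`, `"well_known"`, `"evaluated"`.
#' @param derivation free-text provenance, e.g. `"raw"`, `"dummy"`, `"phi"`,
#'   `"specialization"`, `"commonness"`.
#'
#' @return An object of class `attribute_spec`.
#' @export
#' @examples
#' attribute_spec("body_size", "ordinal", 5, "poorly_known")
attribute_spec <- function(name, kind = c("binary", "ordinal", "nominal"),
                           n_categories = 2L,
                           tier = c("poorly_known", "well_known", "evaluated"),
                           derivation = "raw") {
  kind <- match.arg(kind)
  tier <- match.arg(tier)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("attribute name must be a non-empty string")
  }
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L || n_categories > 10L) {
    stopf("attribute '%s': n_categories must be between 2 and 10, got %s",
          name, n_categories)
  }
  if (kind == "binary" && n_categories != 2L) {
    stopf("attribute '%s': binary attributes have exactly 2 categories", name)
  }
  structure(
    list(name = name, kind = kind, n_categories = n_categories,
         tier = tier, derivation = derivation),
    class = "attribute_spec"
  )
}

#' @export
print.attribute_spec <- function(x, ...) {
  cat(sprintf("attribute '%s': %s, %d categories, tier %s (%s)\n",
              x$name, x$kind, x$n_categories, x$tier, x$derivation))
  invisible(x)
}

# Tier order used for nesting comparisons (lowest availability first).
TIER_LEVELS <- c("poorly_known", "well_known", "evaluated")

tier_rank <- function(tier) match(tier, TIER_LEVELS)
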