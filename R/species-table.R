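#' Species-by-attribute table
#'
#' The central data container of the pipeline: one row per species, one
#' column per categorical attribute, plus taxonomic labels and the two binary
#' Red List response axes (rarity and decline).  Attribute values are stored
#' as small integer codes `1..k` (with `NA` marking a genuinely missing
#' value); ordinal attributes carry their level order in the codes, nominal
#' attributes treat codes as unordered labels.
#'
#' The taxonomic `group` labels form a hierarchy supplied as parent links
#' (e.g. `c(birds = "vertebrates", vertebrates = "animals")`): an indicator
#' group is a subset of its higher taxonomic group, which is a subset of a
#' kingdom.  The hierarchy is given, never inferred.
#'
#' @param data data.frame of integer attribute codes (`NA` = missing), one
#'   column per attribute, in the same order as `specs`.
#' @param specs list of [attribute_spec()] objects, one per column of `data`.
#' @param species_id character vector of unique species identifiers.
#' @param group character vector of finest taxonomic group labels.
#' @param kingdom character vector (or single value) of kingdom labels.
#' @param rarity,decline optional binary (0/1) label vectors; `NA` allowed.
#' @param hierarchy named character vector of parent links
#'   (`child = "parent"`); groups without an entry are roots.
#'
#' @return An object of class `species_table`.
#' @export
species_table <- function(data, specs, species_id,
                          group = rep("all", nrow(data)),
                          kingdom = rep("all", nrow(data)),
                          rarity = NULL, decline = NULL,
                          hierarchy = character()) {
  data <- as.data.frame(data)
  if (length(specs) != ncol(data)) {
    stopf("got %d attribute specs for %d columns", length(specs), ncol(data))
  }
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stopf("duplicate attribute names in specs")
  names(data) <- nm
  names(specs) <- nm
  n <- nrow(data)
  if (length(kingdom) == 1L) kingdom <- rep(kingdom, n)
  if (length(species_id) != n || anyDuplicated(species_id)) {
    stopf("species_id must be unique and match the number of rows (%d)", n)
  }
  if (length(group) != n || length(kingdom) != n) {
    stopf("group and kingdom labels must have one entry per species")
  }
  for (j in seq_along(specs)) {
    v <- data[[j]]
    bad <- !is.na(v) & !(v %in% seq_len(specs[[j]]$n_categories))
    if (any(bad)) {
      stopf("species '%s': value %s outside the %d categories of attribute '%s'",
            species_id[which(bad)[1]], v[which(bad)[1]],
            specs[[j]]$n_categories, nm[j])
    }
    data[[j]] <- as.integer(v)
  }
  check_label <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) != n) stopf("%s labels must have one entry per species", what)
    if (!is_binary01(x)) stopf("%s labels must be binary 0/1", what)
    as.integer(x)
  }
  structure(
    list(data = data, specs = specs,
         species_id = as.character(species_id),
         group = as.character(group), kingdom = as.character(kingdom),
         rarity = check_label(rarity, "rarity"),
         decline = check_label(decline, "decline"),
         hierarchy = hierarchy),
    class = "species_table"
  )
}

#' @export
print.species_table <- function(x, ...) {
  cat(sprintf("species_table: %d species x %d attributes (%d missing cells)\n",
              nrow(x$data), ncol(x$data), sum(is.na(x$data))))
  cat(sprintf("  groups: %s\n", paste(unique(x$group), collapse = ", ")))
  if (!is.null(x$rarity)) {
    cat(sprintf("  rarity prevalence:  %.3f\n", mean(x$rarity, na.rm = TRUE)))
  }
  if (!is.null(x$decline)) {
    cat(sprintf("  decline prevalence: %.3f\n", mean(x$decline, na.rm = TRUE)))
  }
  invisible(x)
}

#' Number of species / attributes in a table
#' @param table a [species_table()].
#' @return integer count.
#' @export
n_species <- function(table) nrow(table$data)

#' @rdname n_species
#' @export
n_attributes <- function(table) ncol(table$data)

#' Labels for one response axis
#'
#' @param table a [species_table()].
#' @param axis `"rarity"` or `"decline"`.
#' @return integer 0/1 vector (possibly with `NA`).
#' @export
axis_labels <- function(table, axis = c("rarity", "decline")) {
  axis <- match.arg(axis)
  lab <- table[[axis]]
  if (is.null(lab)) stopf("table carries no %s labels", axis)
  lab
}

#' Subset a species table
#'
#' @param table a [species_table()].
#' @param rows integer or logical row index (species).
#' @param cols character vector of attribute names, or `NULL` for all.
#' @return A [species_table()].
#' @export
subset_species <- function(table, rows = seq_len(n_species(table)),
                           cols = NULL) {
  if (is.null(cols)) cols <- names(table$data)
  missing_cols <- setdiff(cols, names(table$data))
  if (length(missing_cols)) {
    stopf("unknown attributes: %s", paste(missing_cols, collapse = ", "))
  }
  species_table(
    data = table$data[rows, cols, drop = FALSE],
    specs = table$specs[cols],
    species_id = table$species_id[rows],
    group = table$group[rows],
    kingdom = table$kingdom[rows],
    rarity = if (!is.null(table$rarity)) table$rarity[rows],
    decline = if (!is.null(table$decline)) table$decline[rows],
    hierarchy = table$hierarchy
  )
}

# All ancestor labels of a group (including itself) under the parent links.
group_ancestry <- function(group, hierarchy) {
  chain <- group
  while (group %in% names(hierarchy)) {
    group <- unname(hierarchy[[group]])
    if (group %in% chain) stopf("cycle in group hierarchy at '%s'", group)
    chain <- c(chain, group)
  }
  chain
}

#' Species belonging to a (possibly higher) taxonomic group
#'
#' Membership follows the parent links of the table's hierarchy: a species
#' whose finest group is `"birds"` belongs to `"vertebrates"` if the
#' hierarchy links birds to vertebrates.  Kingdom labels also match.
#'
#' @param table a [species_table()].
#' @param label a group or kingdom label.
#' @return logical vector over species.
#' @export
group_members <- function(table, label) {
  in_chain <- vapply(
    table$group,
    function(g) label %in% group_ancestry(g, table$hierarchy),
    logical(1)
  )
  unname(in_chain | table$kingdom == label)
}

#' Select the attribute columns available at a given tier
#'
#' Returns the column subset whose availability tier is at or below the
#' requested tier, honouring the nesting poorly_known < well_known <
#' evaluated.  For the rarity axis the commonness attribute (historic
#' grid-cell occupancy) is always excluded, whatever the tier, because
#' commonness is essentially the quantity that defines rarity.
#'
#' @param table a [species_table()].
#' @param tier `"poorly_known"`, `"well_known"` or `"evaluated"`.
#' @param axis `"rarity"` or `"decline"`; controls the commonness exclusion.
#' @return A [species_table()] with the selected columns.
#' @export
select_tier <- function(table, tier = c("poorly_known", "well_known", "evaluated"),
                        axis = c("decline", "rarity")) {
  tier <- match.arg(tier)
  axis <- match.arg(axis)
  keep <- vapply(table$specs, function(s) {
    ok <- tier_rank(s$tier) <= tier_rank(tier)
    if (axis == "rarity" && identical(s$derivation, "commonness")) ok <- FALSE
    ok
  }, logical(1))
  subset_species(table, cols = names(table$specs)[keep])
}
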