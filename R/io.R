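#' Read and write species tables
#'
#' The on-disk format is a plain CSV/TSV with a header row and one species
#' per row: columns `species_id`, `kingdom`, `group`, optionally `rarity`
#' and `decline`, then one column per attribute holding integer category
#' codes `1..k`.  Missing cells use a configurable token (default `"NA"`).
#' Attribute metadata (kind, category count, tier, derivation) and the
#' group hierarchy live in a companion YAML file so that the table itself
#' stays a flat matrix.
#'
#' @param path path to the CSV (`.csv`) or TSV (`.tsv`/`.txt`) table.
#' @param metadata_path path to the YAML attribute metadata.
#' @param missing token encoding a missing cell (default `"NA"`).
#' @return [read_species_table()] returns a [species_table()];
#'   the writers return their input invisibly.
#' @export
read_species_table <- function(path, metadata_path, missing = "NA") {
  meta <- read_attribute_metadata(metadata_path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = missing, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  fixed <- c("species_id", "kingdom", "group")
  if (!all(fixed %in% names(raw))) {
    stopf("table must have columns %s", paste(fixed, collapse = ", "))
  }
  if (anyDuplicated(raw$species_id)) {
    stopf("duplicate species_id: '%s'",
          raw$species_id[anyDuplicated(raw$species_id)])
  }
  attr_cols <- setdiff(names(raw), c(fixed, "rarity", "decline"))
  unknown <- setdiff(attr_cols, names(meta$specs))
  if (length(unknown)) {
    stopf("attributes present in the table but not in the metadata: %s",
          paste(unknown, collapse = ", "))
  }
  specs <- meta$specs[attr_cols]
  tbl <- species_table(
    data = raw[attr_cols],
    specs = specs,
    species_id = raw$species_id,
    group = raw$group,
    kingdom = raw$kingdom,
    rarity = if ("rarity" %in% names(raw)) raw$rarity,
    decline = if ("decline" %in% names(raw)) raw$decline,
    hierarchy = meta$hierarchy
  )
  message(sprintf("read %d species x %d attributes from %s",
                  n_species(tbl), n_attributes(tbl), path))
  tbl
}

#' @rdname read_species_table
#' @param table a [species_table()] to write.
#' @export
write_species_table <- function(table, path, metadata_path, missing = "NA") {
  out <- data.frame(species_id = table$species_id,
                    kingdom = table$kingdom,
                    group = table$group,
                    stringsAsFactors = FALSE)
  if (!is.null(table$rarity)) out$rarity <- table$rarity
  if (!is.null(table$decline)) out$decline <- table$decline
  out <- cbind(out, table$data)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, na = missing,
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  write_attribute_metadata(table$specs, table$hierarchy, metadata_path)
  invisible(table)
}

#' Read attribute metadata from YAML
#'
#' @param path YAML file with an `attributes` list (fields `name`, `kind`,
#'   `n_categories`, `tier`, `derivation`) and an optional `hierarchy` map
#'   of `child: parent` group links.
#' @return list with elements `specs` (named list of [attribute_spec()])
#'   and `hierarchy` (named character vector).
#' @export
read_attribute_metadata <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$attributes)) stopf("metadata file has no 'attributes' entry")
  specs <- lapply(y$attributes, function(a) {
    attribute_spec(name = a$name, kind = a$kind,
                   n_categories = a$n_categories, tier = a$tier,
                   derivation = if (is.null(a$derivation)) "raw" else a$derivation)
  })
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  hierarchy <- unlist(y$hierarchy %||% list())
  list(specs = specs, hierarchy = hierarchy)
}

#' @rdname read_attribute_metadata
#' @param specs named list of [attribute_spec()].
#' @param hierarchy named character vector of parent links.
#' @export
write_attribute_metadata <- function(specs, hierarchy, path) {
  y <- list(
    attributes = lapply(unname(specs), function(s) {
      list(name = s$name, kind = s$kind, n_categories = s$n_categories,
           tier = s$tier, derivation = s$derivation)
    }),
    hierarchy = as.list(hierarchy)
  )
  yaml::write_yaml(y, path)
  invisible(specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
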