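# Forest engine: grow classification forests on a species table, expose
# out-of-bag predictions, vote fractions and permutation importance.
# The trees themselves come from the randomForest package (Breiman-Cutler
# CART forests with Gini splits, bootstrap size n, node size 1,
# mtry = floor(sqrt(p)) by default).

# Model frame for randomForest: nominal attributes as factors over the full
# declared category set (so transfer predictions never meet unseen levels),
# binary/ordinal attributes as integer levels.
forest_frame <- function(table) {
  out <- lapply(names(table$data), function(nm) {
    s <- table$specs[[nm]]
    v <- table$data[[nm]]
    if (s$kind == "nominal") {
      factor(v, levels = seq_len(s$n_categories))
    } else {
      as.numeric(v)
    }
  })
  names(out) <- names(table$data)
  as.data.frame(out, check.names = FALSE)
}

#' Grow a random forest on a species table
#'
#' Grows `n_trees` classification trees, each on a bootstrap sample of all
#' species drawn with replacement, testing `mtry` randomly chosen attributes
#' at each node and splitting on the largest Gini impurity decrease; trees
#' are grown to purity.  Each species is classified out-of-bag (OOB) by the
#' majority vote of the trees whose bootstrap sample excluded it; vote ties
#' are broken toward the negative class (not rare / not declining), which is
#' the conservative and deterministic choice.
#'
#' Permutation importance is computed during fitting: for every attribute,
#' its OOB values are permuted tree by tree and the drop in OOB correct
#' classification is averaged over trees (raw mean decrease in accuracy,
#' not normalized by its standard error).
#'
#' @param table a complete [species_table()] (impute first).
#' @param labels binary 0/1 vector over species; both classes must occur.
#' @param n_trees number of trees (default 10000).
#' @param seed integer seed; identical inputs and seed reproduce the model.
#' @param mtry attributes tested per node; default `floor(sqrt(p))`.
#' @return An object of class `forest_model` with elements `rf` (the fitted
#'   randomForest), `oob_prediction`, `oob_vote_fraction` (fraction of OOB
#'   trees voting for the positive class), `labels`, `n_trees`, `mtry`,
#'   `seed` and `specs`.
#' @export
grow_forest <- function(table, labels, n_trees = 10000L, seed = 1L,
                        mtry = NULL) {
  if (anyNA(table$data)) stopf("table has missing cells: impute first")
  if (anyNA(labels) || length(labels) != n_species(table)) {
    stopf("labels must be a complete vector over all species")
  }
  if (!is_binary01(labels)) stopf("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) {
    stopf("labels are single-class; a classification forest needs both")
  }
  x <- forest_frame(table)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  y <- factor(labels, levels = c(0, 1))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                                   importance = TRUE)
  vote_pos <- rf$votes[, "1"]  # OOB vote fractions, normalized
  oob_pred <- ifelse(is.nan(vote_pos), NA_integer_,
                     as.integer(vote_pos > 0.5))  # tie -> negative class
  structure(
    list(rf = rf, oob_prediction = oob_pred, oob_vote_fraction = vote_pos,
         labels = as.integer(labels), n_trees = n_trees, mtry = mtry,
         seed = seed, specs = table$specs),
    class = "forest_model"
  )
}

#' @export
print.forest_model <- function(x, ...) {
  ok <- mean(x$oob_prediction == x$labels, na.rm = TRUE)
  cat(sprintf("forest_model: %d trees, mtry %d, %d species, %d attributes\n",
              x$n_trees, x$mtry, length(x$labels), length(x$specs)))
  cat(sprintf("  OOB correct classification: %.2f%%\n", 100 * ok))
  invisible(x)
}

#' Classify species with a fitted forest
#'
#' Majority vote over all trees of the forest; vote ties go to the negative
#' class.  The new table must carry the model's attribute set (used e.g. to
#' transfer an indicator-group forest to its higher taxonomic group).
#'
#' @param object a [grow_forest()] model.
#' @param table a complete [species_table()] with the model's attributes.
#' @param ... unused.
#' @return list with `prediction` (integer 0/1 per species) and
#'   `vote_fraction` (fraction of trees voting positive).
#' @export
predict.forest_model <- function(object, table, ...) {
  want <- names(object$specs)
  if (!all(want %in% names(table$data))) {
    stopf("table lacks model attributes: %s",
          paste(setdiff(want, names(table$data)), collapse = ", "))
  }
  if (anyNA(table$data[want])) stopf("table has missing cells: impute first")
  x <- forest_frame(subset_species(table, cols = want))
  votes <- predict(object$rf, x, type = "vote")  # normalized over all trees
  vote_pos <- votes[, "1"]
  list(prediction = as.integer(vote_pos > 0.5), vote_fraction = vote_pos)
}

#' Permutation importance ranking
#'
#' Extracts the raw permutation importance (mean decrease in OOB correct
#' classification when the attribute's values are permuted) from a fitted
#' forest, ranked decreasingly.  Ties are broken by attribute name order so
#' that top-10 lists are deterministic.  An attribute the forest never
#' splits on has importance exactly 0.
#'
#' @param model a [grow_forest()] model.
#' @param top_k how many attributes the `top` element lists (default 10).
#' @return An object of class `importance_ranking`: data.frame with columns
#'   `attribute`, `importance`, `rank`, plus attribute `top` (character
#'   vector of the `top_k` first names).
#' @export
permutation_importance <- function(model, top_k = 10L) {
  imp <- randomForest::importance(model$rf, type = 1, scale = FALSE)[, 1]
  ord <- order(-imp, names(imp))
  out <- data.frame(attribute = names(imp)[ord],
                    importance = unname(imp[ord]),
                    rank = seq_along(imp),
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", "data.frame")
  attr(out, "top") <- utils::head(out$attribute, top_k)
  out
}

#' Top attributes of an importance ranking
#' @param ranking a [permutation_importance()] result.
#' @return character vector of attribute names.
#' @export
top_attributes <- function(ranking) attr(ranking, "top")
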