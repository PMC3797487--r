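#' Proximity-based imputation of missing attribute values
#'
#' Replaces every missing cell with a value borrowed from proximate species,
#' where proximity between two species is the fraction of trees of a random
#' forest in which they land in the same terminal node (the Breiman-Cutler
#' scheme).  The procedure is:
#'
#' 1. initialise each missing cell with the attribute's modal category
#'    (binary/nominal) or median level (ordinal) among non-missing species;
#' 2. grow a forest of `n_trees` classification trees on the current
#'    completed table, with the binary labels as the response, and compute
#'    the all-case proximity matrix;
#' 3. for each originally missing cell, replace the current value by the
#'    category with the largest proximity-weighted vote among species whose
#'    cell was actually observed (binary/nominal), or by the
#'    proximity-weighted mean level rounded to the nearest level (ordinal);
#' 4. repeat from step 2 for `n_iter` iterations.
#'
#' Originally observed cells are never altered, and imputed values always
#' stay within the attribute's declared category set.
#'
#' @param table a [species_table()]; may contain missing cells.
#' @param labels binary 0/1 vector over all species (no `NA`): the response
#'   the imputation forests are grown on, so imputation is label-aware (set
#'   `supervised = FALSE` for unsupervised proximities from a label-free
#'   forest).
#' @param n_trees trees per imputation forest (default 1000).
#' @param n_iter number of imputation iterations (default 10).
#' @param seed integer master seed; iteration `i` uses `seed + i`.
#' @param supervised grow the proximity forests on the labels (default) or
#'   unsupervised.
#' @param return_proximity also return the final proximity matrix.
#' @return A complete [species_table()].  With `return_proximity = TRUE`, a
#'   list with elements `table` and `proximity`.
#' @export
impute_proximity <- function(table, labels, n_trees = 1000L, n_iter = 10L,
                             seed = 1L, supervised = TRUE,
                             return_proximity = FALSE) {
  if (n_species(table) == 0L) stopf("empty species table")
  if (anyNA(labels) || length(labels) != n_species(table)) {
    stopf("labels must be a complete binary vector over all species")
  }
  if (!is_binary01(labels)) stopf("labels must be binary 0/1")
  miss <- is.na(as.matrix(table$data))
  if (!any(miss)) {
    # nothing to do; no forests grown
    if (return_proximity) return(list(table = table, proximity = NULL))
    return(table)
  }
  no_obs <- colSums(!miss) == 0L
  if (any(no_obs)) {
    stopf("attribute '%s' has no observed values to impute from",
          names(table$data)[which(no_obs)[1]])
  }

  data <- table$data
  specs <- table$specs
  # -- initialisation: mode (binary/nominal) or median level (ordinal)
  for (j in seq_along(data)) {
    mj <- miss[, j]
    if (!any(mj)) next
    obs <- data[[j]][!mj]
    init <- if (specs[[j]]$kind == "ordinal") {
      as.integer(round_half_up(stats::median(obs)))
    } else {
      as.integer(which.max(tabulate(obs, nbins = specs[[j]]$n_categories)))
    }
    data[[j]][mj] <- init
  }

  prox <- NULL
  y <- factor(labels, levels = c(0, 1))
  for (it in seq_len(n_iter)) {
    work <- table
    work$data <- data
    x <- forest_frame(work)
    set.seed(derive_seed(seed + it, "impute"))
    rf <- if (supervised) {
      randomForest::randomForest(x, y, ntree = n_trees, proximity = TRUE)
    } else {
      randomForest::randomForest(x, ntree = n_trees, proximity = TRUE)
    }
    prox <- rf$proximity
    for (j in seq_along(data)) {
      mj <- which(miss[, j])
      if (!length(mj)) next
      donors <- which(!miss[, j])
      v_d <- data[[j]][donors]
      for (i in mj) {
        w <- prox[i, donors]
        if (all(w == 0)) next  # no proximate donor: keep current value
        if (specs[[j]]$kind == "ordinal") {
          data[[j]][i] <- min(max(
            as.integer(round_half_up(sum(w * v_d) / sum(w))), 1L),
            specs[[j]]$n_categories)
        } else {
          votes <- vapply(seq_len(specs[[j]]$n_categories),
                          function(k) sum(w[v_d == k]), numeric(1))
          data[[j]][i] <- which.max(votes)  # ties -> lowest category code
        }
      }
    }
  }
  table$data <- data
  if (return_proximity) list(table = table, proximity = prox) else table
}
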