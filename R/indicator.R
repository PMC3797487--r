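#' Indicator-group transfer analysis
#'
#' Measures how well a forest fitted on a well-studied indicator group
#' (e.g. birds) classifies decline in its enclosing higher taxonomic group
#' (e.g. all vertebrates).  Per replicate: the higher-group table is imputed
#' (label-aware), a forest is grown on the indicator rows only, evaluated
#' out-of-bag on the indicator group, then applied to the higher-group rows;
#' the actual transfer correct classification is compared with the expected
#' one obtained by re-projecting the indicator's exact OOB error rates onto
#' the higher group's prevalence ([expected_correct()]).  Replication (with
#' re-imputation) quantifies the random parts of the procedure; the 95%
#' confidence intervals are Student-t intervals over the replicates.
#'
#' The transfer analysis is restricted to the decline axis: decline is the
#' conservation-relevant signal an indicator group is meant to carry.
#'
#' By default the indicator's own rows are included among the classified
#' higher-group rows, mirroring the design of classifying the whole sample
#' of the higher group; note that those rows are classified by a forest
#' that was trained on them, which is optimistic.  Set
#' `include_indicator = FALSE` for a strictly out-of-sample transfer.
#'
#' @param table a [species_table()] with decline labels and a hierarchy in
#'   which `indicator` is nested inside `higher`.
#' @param indicator indicator group label.
#' @param higher higher taxonomic group label.
#' @param axis response axis; only `"decline"` is supported.
#' @param n_replicates number of independent replicates (default 10).
#' @param seed master seed; replicate r uses deterministic seed `seed + r`.
#' @param n_trees trees of the main forests (default 10000).
#' @param impute_trees,impute_iter imputation forest size and iterations
#'   (defaults 1000 and 10).
#' @param include_indicator include the indicator rows among the classified
#'   higher-group rows (default `TRUE`).
#' @param compute_overlap also grow a full higher-group forest per replicate
#'   and record the overlap of the two top-10 importance lists.
#' @param ci_method `"t"` (Student-t, default) or `"normal"` for the
#'   replicate confidence intervals.
#' @return An object of class `indicator_result`: list with `indicator`,
#'   `higher`, `replicates` (data.frame of per-replicate seeds, indicator
#'   OOB %, actual transfer %, expected %, Type I/II, overlap),
#'   `actual_mean`, `actual_ci`, `expected_mean`, `expected_ci`,
#'   `importance_overlap` (mean), and `top_indicator` / `top_higher` (last
#'   replicate's top-10 lists).
#' @export
run_indicator <- function(table, indicator, higher, axis = "decline",
                          n_replicates = 10L, seed = 1L, n_trees = 10000L,
                          impute_trees = 1000L, impute_iter = 10L,
                          include_indicator = TRUE, compute_overlap = TRUE,
                          ci_method = c("t", "normal")) {
  if (!identical(axis, "decline")) {
    stopf("the transfer analysis is defined for the decline axis only")
  }
  ci_method <- match.arg(ci_method)
  in_h <- group_members(table, higher)
  in_i <- group_members(table, indicator)
  if (!any(in_i)) stopf("no species in indicator group '%s'", indicator)
  if (any(in_i & !in_h)) {
    stopf("indicator group '%s' is not nested inside '%s'", indicator, higher)
  }
  tbl_h <- subset_species(table, in_h)
  idx_i <- group_members(tbl_h, indicator)
  labels_h <- axis_labels(tbl_h, "decline")
  if (anyNA(labels_h)) stopf("decline labels missing for some species")
  if (length(unique(labels_h[idx_i])) < 2L) {
    stopf("indicator group has a single decline class")
  }
  prev_h <- mean(labels_h)
  n_h <- length(labels_h)

  reps <- vector("list", n_replicates)
  top_i <- top_h <- NULL
  for (r in seq_len(n_replicates)) {
    seed_r <- seed + r
    tbl_c <- impute_proximity(tbl_h, labels_h, n_trees = impute_trees,
                              n_iter = impute_iter, seed = seed_r)
    fit_i <- grow_forest(subset_species(tbl_c, idx_i), labels_h[idx_i],
                         n_trees = n_trees, seed = derive_seed(seed_r, "ind"))
    rep_i <- report_from_confusion(
      confusion_from_labels(labels_h[idx_i], fit_i$oob_prediction))
    pred <- predict(fit_i, tbl_c)
    eval_rows <- if (include_indicator) rep(TRUE, n_h) else !idx_i
    rep_t <- report_from_confusion(
      confusion_from_labels(labels_h[eval_rows], pred$prediction[eval_rows]))
    exp_pct <- expected_correct(rep_i$counts, sum(eval_rows),
                                mean(labels_h[eval_rows]))
    top_i <- top_attributes(permutation_importance(fit_i))
    overlap <- NA_integer_
    if (compute_overlap) {
      fit_h <- grow_forest(tbl_c, labels_h, n_trees = n_trees,
                           seed = derive_seed(seed_r, "high"))
      top_h <- top_attributes(permutation_importance(fit_h))
      overlap <- importance_overlap(top_i, top_h)
    }
    reps[[r]] <- data.frame(
      replicate = r, seed = seed_r,
      indicator_correct = rep_i$correct_percent,
      actual = rep_t$correct_percent,
      expected = exp_pct,
      type1 = rep_t$type1, type2 = rep_t$type2,
      chi_square_p = rep_t$chi_square_p,
      overlap = overlap
    )
  }
  reps <- do.call(rbind, reps)
  structure(
    list(indicator = indicator, higher = higher,
         n_higher = n_h, prevalence_higher = prev_h,
         n_indicator = sum(idx_i),
         prevalence_indicator = mean(labels_h[idx_i]),
         replicates = reps,
         actual_mean = mean(reps$actual),
         actual_ci = replicate_ci(reps$actual, method = ci_method),
         expected_mean = mean(reps$expected),
         expected_ci = replicate_ci(reps$expected, method = ci_method),
         importance_overlap = mean(reps$overlap),
         top_indicator = top_i, top_higher = top_h),
    class = "indicator_result"
  )
}

#' @export
print.indicator_result <- function(x, ...) {
  cat(sprintf("indicator transfer: %s -> %s (decline)\n", x$indicator, x$higher))
  cat(sprintf("  indicator: n = %d, prevalence %.2f; higher: n = %d, prevalence %.2f\n",
              x$n_indicator, x$prevalence_indicator, x$n_higher,
              x$prevalence_higher))
  cat(sprintf("  expected correct: %.2f%% [%.2f, %.2f]\n",
              x$expected_mean, x$expected_ci["lo"], x$expected_ci["hi"]))
  cat(sprintf("  actual correct:   %.2f%% [%.2f, %.2f]  (%d replicates)\n",
              x$actual_mean, x$actual_ci["lo"], x$actual_ci["hi"],
              nrow(x$replicates)))
  if (!is.na(x$importance_overlap)) {
    cat(sprintf("  mean top-10 importance overlap: %.1f / 10\n",
                x$importance_overlap))
  }
  invisible(x)
}

#' Overlap of two top-importance lists
#'
#' @param top_a,top_b character vectors of distinct attribute names (the
#'   top-10 lists of two forests).
#' @return integer size of the intersection.
#' @export
importance_overlap <- function(top_a, top_b) {
  if (anyDuplicated(top_a) || anyDuplicated(top_b)) {
    stopf("duplicate names in a top-importance list")
  }
  length(intersect(top_a, top_b))
}

#' Plot expected vs. actual transfer performance
#'
#' Bar pairs of expected and actual correct classification per indicator
#' analysis, with 95% replicate confidence intervals as error bars.
#'
#' @param results a list of [run_indicator()] results (or a single one).
#' @param ... passed to [graphics::barplot()].
#' @export
plot_indicator <- function(results, ...) {
  if (inherits(results, "indicator_result")) results <- list(results)
  vals <- vapply(results, function(r) c(r$expected_mean, r$actual_mean),
                 numeric(2))
  labs <- vapply(results, function(r)
    sprintf("%s\n-> %s", r$indicator, r$higher), character(1))
  mids <- graphics::barplot(vals, beside = TRUE, names.arg = labs,
                            ylim = c(0, 100),
                            legend.text = c("expected", "actual"),
                            ylab = "correct classification (%)", ...)
  for (i in seq_along(results)) {
    r <- results[[i]]
    ci <- rbind(r$expected_ci, r$actual_ci)
    graphics::arrows(mids[, i], ci[, "lo"], mids[, i], ci[, "hi"],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(mids)
}
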