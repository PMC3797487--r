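#' Confusion counts for a binary Red List classification
#'
#' The positive class is "rare" (rarity axis) or "declining" (decline axis).
#' Derived rates follow conservation usage: the probability of a Type I
#' error is the false-positive rate `FP / (FP + TN)` (a common or stable
#' species classified as threatened), the probability of a Type II error is
#' the false-negative rate `FN / (TP + FN)` (a threatened species classified
#' as common or stable).
#'
#' @param tp,fp,fn,tn non-negative integer counts; their sum must be > 0.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stopf("empty confusion matrix")
  structure(setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(true = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Confusion counts from observed and predicted labels
#' @param truth,prediction binary 0/1 vectors of equal length.
#' @return A [confusion_counts()].
#' @export
confusion_from_labels <- function(truth, prediction) {
  keep <- !is.na(truth) & !is.na(prediction)
  truth <- truth[keep]; prediction <- prediction[keep]
  confusion_counts(tp = sum(truth == 1 & prediction == 1),
                   fp = sum(truth == 0 & prediction == 1),
                   fn = sum(truth == 1 & prediction == 0),
                   tn = sum(truth == 0 & prediction == 0))
}

#' Classification report (correct %, error probabilities, chi-square)
#'
#' Summarises a confusion matrix the way Red List classification results
#' are reported: the correct classification percentage
#' `C = 100 (TP + TN) / n`, the prevalence `p = (TP + FN) / n`, the Type I
#' and Type II error probabilities, and the Pearson chi-square test of the
#' classification against a random one.  The identity
#' `C / 100 = (1 - p)(1 - alpha) + p (1 - beta)` holds exactly.
#'
#' @param counts a [confusion_counts()].
#' @return An object of class `classification_report`: list with `n`,
#'   `correct_percent`, `type1`, `type2`, `prevalence`, `chi_square`,
#'   `chi_square_p` and `counts`.
#' @export
report_from_confusion <- function(counts) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (counts$fp + counts$tn == 0) {
    stopf("no true negatives or false positives: Type I rate undefined")
  }
  if (counts$tp + counts$fn == 0) {
    stopf("no true positives or false negatives: Type II rate undefined")
  }
  chi <- chi_square_vs_random(counts)
  structure(
    list(n = n,
         correct_percent = 100 * (counts$tp + counts$tn) / n,
         type1 = counts$fp / (counts$fp + counts$tn),
         type2 = counts$fn / (counts$tp + counts$fn),
         prevalence = (counts$tp + counts$fn) / n,
         chi_square = chi$statistic,
         chi_square_p = chi$p_value,
         counts = counts),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "n = %d  correct = %.2f%%  P(chi-square) = %.3g  Type I = %.3f  Type II = %.3f\n",
    x$n, x$correct_percent, x$chi_square_p, x$type1, x$type2))
  invisible(x)
}

#' Reconstruct integer confusion counts from a printed summary
#'
#' Published classification tables report only `n`, the prevalence and the
#' Type I/II error probabilities, all rounded.  Because the underlying
#' counts are integers, the full confusion matrix can usually be recovered:
#' positives = `n * prevalence` rounded half-up, `FP` and `FN` from the
#' rounded rates applied to the class sizes.  If the recomputed exact rates
#' disagree with the printed ones by more than 0.01, the summary is flagged
#' as inconsistent.
#'
#' @param n total number of species.
#' @param prevalence printed prevalence (0 < p < 1).
#' @param type1,type2 printed error probabilities in \[0, 1\].
#' @return A [confusion_counts()] with attribute `consistent` (logical).
#' @export
confusion_from_summary <- function(n, prevalence, type1, type2) {
  if (prevalence <= 0 || prevalence >= 1) {
    stopf("prevalence must lie strictly between 0 and 1")
  }
  if (type1 < 0 || type1 > 1 || type2 < 0 || type2 > 1) {
    stopf("error probabilities must lie in [0, 1]")
  }
  pos <- round_half_up(prevalence * n)
  neg <- n - pos
  fp <- round_half_up(type1 * neg)
  fn <- round_half_up(type2 * pos)
  counts <- confusion_counts(tp = pos - fn, fp = fp, fn = fn, tn = neg - fp)
  ok <- abs(fp / neg - type1) <= 0.01 && abs(fn / pos - type2) <= 0.01
  if (!ok) warnf("reconstructed counts disagree with the printed rates by > 0.01")
  attr(counts, "consistent") <- ok
  counts
}

#' Expected correct classification under a different prevalence
#'
#' When a classifier fitted on an indicator group is applied to a higher
#' taxonomic group, its expected correct classification changes with the
#' prevalence even if the error probabilities stay exactly the same.  With
#' `alpha` and `beta` the indicator group's exact Type I/II error-rate
#' ratios and `p_h` the higher group's prevalence (snapped to an integer
#' species count, `round(prevalence * n) / n`),
#' \deqn{C_{exp} = 100\,[(1 - p_h)(1 - \alpha) + p_h(1 - \beta)].}
#'
#' @param indicator a [confusion_counts()] for the indicator group.
#' @param higher_n number of species in the higher taxonomic group.
#' @param higher_prevalence prevalence of the positive class in the higher
#'   group (0 < p < 1).
#' @return expected correct classification, in percent.
#' @export
expected_correct <- function(indicator, higher_n, higher_prevalence) {
  if (higher_prevalence <= 0 || higher_prevalence >= 1) {
    stopf("higher_prevalence must lie strictly between 0 and 1")
  }
  if (indicator$fp + indicator$tn == 0 || indicator$tp + indicator$fn == 0) {
    stopf("degenerate indicator confusion: an error rate is undefined")
  }
  alpha <- indicator$fp / (indicator$fp + indicator$tn)
  beta <- indicator$fn / (indicator$tp + indicator$fn)
  p_h <- round_half_up(higher_prevalence * higher_n) / higher_n
  100 * ((1 - p_h) * (1 - alpha) + p_h * (1 - beta))
}

# Pearson chi-square on a 2x2 table, closed form, no continuity correction:
# X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
pearson_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  }
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Chi-square test of a classification against a random one
#'
#' Pearson chi-square (1 d.f., no continuity correction) on the 2x2 table
#' of true class by predicted class.  A zero marginal (e.g. the classifier
#' never predicts one class) yields statistic 0 and p = 1 with a
#' `degenerate` flag.
#'
#' @param counts a [confusion_counts()].
#' @return list with `statistic`, `p_value`, `degenerate`.
#' @export
chi_square_vs_random <- function(counts) {
  pearson_chisq_2x2(counts$tp, counts$fn, counts$fp, counts$tn)
}

#' Chi-square comparison of two classifications
#'
#' Tests whether two classifications differ in their correct-classification
#' fraction: Pearson chi-square (no continuity correction) on the 2x2 table
#' of classification (A/B) by outcome (correct/incorrect).
#'
#' @param a_correct,a_n correct count and total for classification A.
#' @param b_correct,b_n correct count and total for classification B.
#' @return list with `statistic`, `p_value`, `degenerate`.
#' @export
chi_square_two_classifications <- function(a_correct, a_n, b_correct, b_n) {
  if (a_correct < 0 || a_correct > a_n || b_correct < 0 || b_correct > b_n) {
    stopf("correct counts must lie in [0, n]")
  }
  pearson_chisq_2x2(a_correct, a_n - a_correct, b_correct, b_n - b_correct)
}
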