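test_that("classification reports compute the published-style rates", {
  # worked example: 49 butterflies, 37 declining
  rep <- report_from_confusion(confusion_counts(tp = 35, fp = 4, fn = 2,
                                                tn = 8))
  expect_equal(round(rep$correct_percent, 2), 87.76)
  expect_equal(round(rep$type1, 3), 0.333)
  expect_equal(round(rep$type2, 3), 0.054)
  expect_equal(rep$prevalence, 37 / 49)

  perfect <- report_from_confusion(confusion_counts(30, 0, 0, 20))
  expect_equal(perfect$correct_percent, 100)
  expect_equal(perfect$type1, 0)
  expect_equal(perfect$type2, 0)

  # an all-positive predictor: correct = 100 p, alpha = 1, beta = 0
  allpos <- report_from_confusion(confusion_counts(tp = 30, fp = 70,
                                                   fn = 0, tn = 0))
  expect_equal(allpos$correct_percent, 100 * allpos$prevalence)
  expect_equal(allpos$type1, 1)
  expect_equal(allpos$type2, 0)
})

test_that("undefined error rates are rejected by name", {
  expect_error(report_from_confusion(confusion_counts(10, 0, 5, 0)), "Type I")
  expect_error(report_from_confusion(confusion_counts(0, 10, 0, 5)), "Type II")
})

test_that("the accuracy identity holds exactly on random confusion tables", {
  set.seed(123)
  for (i in 1:1000) {
    cc <- random_confusion()
    rep <- report_from_confusion(cc)
    rhs <- (1 - rep$prevalence) * (1 - rep$type1) +
      rep$prevalence * (1 - rep$type2)
    expect_equal(rep$correct_percent / 100, rhs, tolerance = 1e-10)
  }
})

test_that("integer confusion counts are recovered from printed summaries", {
  cc <- confusion_from_summary(175, 0.44, 0.224, 0.494)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 39L, fp = 22L, fn = 38L, tn = 76L))
  cc <- confusion_from_summary(49, 0.76, 0.333, 0.054)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 35L, fp = 4L, fn = 2L, tn = 8L))
  cc <- confusion_from_summary(100, 0.5, 0, 0)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 50L, fp = 0L, fn = 0L, tn = 50L))
  expect_warning(confusion_from_summary(10, 0.5, 0.31, 0.2), "disagree")
})

test_that("reconstruction picks the unique best-fitting integer table", {
  # independent oracle: exhaustive search over all integer confusion
  # tables of size n for the one minimizing the summary discrepancy
  oracle <- function(n, prev, t1, t2) {
    best <- NULL; best_err <- Inf; ties <- 0L
    for (pos in 1:(n - 1)) {
      neg <- n - pos
      for (fp in 0:neg) for (fn in 0:pos) {
        err <- abs(pos / n - prev) + abs(fp / neg - t1) + abs(fn / pos - t2)
        if (err < best_err - 1e-12) {
          best_err <- err; best <- c(pos - fn, fp, fn, neg - fp); ties <- 1L
        } else if (abs(err - best_err) < 1e-12) ties <- ties + 1L
      }
    }
    list(counts = best, ties = ties)
  }
  got <- confusion_from_summary(49, 0.76, 0.333, 0.054)
  want <- oracle(49, 0.76, 0.333, 0.054)
  expect_equal(want$ties, 1L)
  expect_equal(c(got$tp, got$fp, got$fn, got$tn), want$counts)
})

test_that("summary reconstruction inverts reporting at full precision", {
  set.seed(77)
  for (i in 1:50) {
    cc <- random_confusion()
    if (cc$tp + cc$fn == 0 || cc$fp + cc$tn == 0) next
    rep <- report_from_confusion(cc)
    if (rep$prevalence %in% c(0, 1)) next
    back <- confusion_from_summary(rep$n, rep$prevalence, rep$type1,
                                   rep$type2)
    expect_equal(unclass(back)[c("tp", "fp", "fn", "tn")],
                 unclass(cc)[c("tp", "fp", "fn", "tn")])
  }
})

test_that("prevalence-corrected expected accuracy matches its worked example", {
  birds <- confusion_from_summary(77, 0.34, 0.176, 0.769)
  expect_equal(round(expected_correct(birds, 175, 0.44), 2), 56.27)
  # error-free indicators transfer perfectly at any prevalence
  ideal <- confusion_counts(10, 0, 0, 10)
  expect_equal(expected_correct(ideal, 200, 0.3), 100)
  # projecting onto the indicator's own prevalence returns its own accuracy
  cc <- confusion_counts(tp = 30, fp = 12, fn = 18, tn = 40)
  rep <- report_from_confusion(cc)
  expect_equal(expected_correct(cc, rep$n, rep$prevalence),
               rep$correct_percent, tolerance = 1e-10)
})

test_that("expected accuracy is linear in the higher-group prevalence", {
  cc <- confusion_counts(tp = 30, fp = 12, fn = 18, tn = 40)
  alpha <- 12 / 52; beta <- 18 / 48
  n_h <- 1000  # large n so the count snapping is exact at the test points
  p <- c(0.2, 0.5, 0.8)
  e <- vapply(p, function(ph) expected_correct(cc, n_h, ph), numeric(1))
  slope <- (e[3] - e[1]) / (p[3] - p[1])
  expect_equal(slope, 100 * (alpha - beta), tolerance = 1e-10)
  expect_equal(e[2], mean(e[c(1, 3)]), tolerance = 1e-10)
})

test_that("the chi-square test matches the closed form and the reference", {
  chi <- chi_square_vs_random(confusion_counts(tp = 35, fp = 4, fn = 2,
                                               tn = 8))
  expect_equal(chi$statistic, 49 * (35 * 8 - 2 * 4)^2 / (37 * 12 * 39 * 10))
  expect_equal(round(chi$statistic, 2), 20.94)
  # independence: identical row distributions give exactly zero
  flat <- chi_square_vs_random(confusion_counts(25, 25, 25, 25))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # reference implementation agreement on random tables
  set.seed(42)
  for (i in 1:100) {
    cc <- random_confusion()
    got <- chi_square_vs_random(cc)
    m <- matrix(c(cc$tp, cc$fn, cc$fp, cc$tn), 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      expect_true(got$degenerate)
      next
    }
    want <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-6)
    expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-6)
  }
})

test_that("a zero-margin classification is flagged, not an error", {
  out <- chi_square_vs_random(confusion_counts(tp = 30, fp = 70, fn = 0,
                                               tn = 0))
  expect_true(out$degenerate)
  expect_equal(out$p_value, 1)
})

test_that("two classifications are compared on their correct fractions", {
  same <- chi_square_two_classifications(80, 100, 80, 100)
  expect_equal(same$statistic, 0)
  got <- chi_square_two_classifications(90, 100, 60, 100)
  want <- suppressWarnings(stats::chisq.test(
    matrix(c(90, 10, 60, 40), 2, byrow = TRUE), correct = FALSE))
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
  extreme <- chi_square_two_classifications(0, 100, 100, 100)
  expect_lt(extreme$p_value, 1e-10)
  expect_error(chi_square_two_classifications(110, 100, 50, 100), "\\[0, n\\]")
})
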