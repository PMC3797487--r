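test_that("a perfectly separable attribute yields near-perfect OOB accuracy", {
  for (seed in 1:3) {
    fx <- separable_table(n = 200, seed = seed)
    fit <- grow_forest(fx$table, fx$labels, n_trees = 1000, seed = seed)
    expect_gte(mean(fit$oob_prediction == fx$labels), 0.95)
  }
})

test_that("labels independent of all attributes give chance-level OOB accuracy", {
  acc <- sapply(1:4, function(seed) {
    set.seed(seed)
    n <- 400
    specs <- lapply(sprintf("a%02d", 1:10), function(nm)
      attribute_spec(nm, "ordinal", 5L, "poorly_known"))
    data <- as.data.frame(setNames(
      lapply(1:10, function(j) sample(1:5, n, TRUE)), sprintf("a%02d", 1:10)))
    tbl <- species_table(data, specs, sprintf("s%03d", 1:n))
    labels <- rep(0:1, each = n / 2)
    fit <- grow_forest(tbl, labels, n_trees = 600, seed = seed)
    mean(fit$oob_prediction == labels)
  })
  expect_lt(abs(mean(acc) - 0.5), 0.05)
})

test_that("identical inputs and seed reproduce the forest exactly", {
  fx <- separable_table(n = 60, seed = 4)
  a <- grow_forest(fx$table, fx$labels, n_trees = 1, seed = 9)
  b <- grow_forest(fx$table, fx$labels, n_trees = 1, seed = 9)
  expect_identical(a$oob_prediction, b$oob_prediction)
  expect_identical(a$oob_vote_fraction, b$oob_vote_fraction)
  c <- grow_forest(fx$table, fx$labels, n_trees = 500, seed = 9)
  d <- grow_forest(fx$table, fx$labels, n_trees = 500, seed = 9)
  expect_identical(c$oob_prediction, d$oob_prediction)
  expect_identical(predict(c, fx$table), predict(d, fx$table))
})

test_that("prediction honours the contract on new tables", {
  fx <- separable_table(n = 100, seed = 2)
  fit <- grow_forest(fx$table, fx$labels, n_trees = 500, seed = 2)
  # resubstitution on a separable attribute reproduces the labels
  expect_equal(predict(fit, fx$table)$prediction, fx$labels)
  # one species duplicated five times: five identical predictions
  dup <- species_table(fx$table$data[rep(7L, 5), , drop = FALSE],
                       fx$table$specs, species_id = paste0("d", 1:5))
  p <- predict(fit, dup)$prediction
  expect_equal(length(unique(p)), 1L)
  # attribute mismatch is an error
  expect_error(predict(fit, subset_species(fx$table, cols = "signal")),
               "lacks model attributes")
})

test_that("degenerate inputs are rejected", {
  fx <- separable_table(n = 40, seed = 3)
  expect_error(grow_forest(fx$table, rep(1, 40)), "single-class")
  tbl <- fx$table
  tbl$data$signal[1] <- NA
  expect_error(grow_forest(tbl, fx$labels), "impute first")
})

test_that("permutation importance separates signal from noise", {
  for (seed in 1:2) {
    fx <- separable_table(n = 300, n_noise = 12, seed = seed)
    # a probabilistically informative attribute rather than a perfect copy
    set.seed(seed + 50)
    flip <- runif(300) < 0.15
    fx$table$data$signal <- ifelse(flip, 3L - fx$table$data$signal,
                                   fx$table$data$signal)
    fit <- grow_forest(fx$table, fx$labels, n_trees = 1500, seed = seed)
    imp <- permutation_importance(fit)
    expect_s3_class(imp, "importance_ranking")
    expect_setequal(imp$attribute, names(fx$table$data))
    expect_equal(imp$attribute[1], "signal")
    expect_gt(imp$importance[1], 0.1)
    noise_imp <- imp$importance[imp$attribute != "signal"]
    expect_true(all(abs(noise_imp) < 0.01))
  }
})

test_that("an attribute the forest never splits on has importance exactly zero", {
  fx <- separable_table(n = 80, n_noise = 1, seed = 6)
  # constant-ish noise column: with a perfect signal column and mtry = 1
  # some trees never split on noise; use mtry = 2 so signal is always
  # available and noise splits are never useful enough to occur at purity
  tbl <- fx$table
  tbl$data$noise01 <- rep(c(1L, 2L), each = 40)
  fit <- grow_forest(tbl, fx$labels, n_trees = 200, seed = 6, mtry = 2)
  imp <- permutation_importance(fit)
  expect_equal(imp$importance[imp$attribute == "noise01"], 0,
               tolerance = 1e-12)
})

test_that("OOB accuracy stabilises as the forest grows", {
  syn <- generate_synthetic(synthetic_config(n_species = 300L,
    group_sizes = c(birds = 150L, beetles = 150L),
    hierarchy = c(birds = "animals", beetles = "animals"),
    missing_rate = 0, seed = 12))
  lab <- axis_labels(syn$table, "decline")
  small <- grow_forest(syn$table, lab, n_trees = 4000, seed = 1)
  large <- grow_forest(syn$table, lab, n_trees = 8000, seed = 2)
  acc <- function(f) mean(f$oob_prediction == lab)
  expect_lt(abs(acc(small) - acc(large)), 0.01)
})
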