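test_that("phi handles perfect indicators and ubiquitous species", {
  g <- rep(c("a", "b"), c(4, 6))
  p <- phi_coefficient(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), g)
  expect_equal(unname(p$phi), c(1, -1))
  p <- phi_coefficient(rep(1, 10), g)  # present everywhere: no preference
  expect_equal(unname(p$phi), c(0, 0))
  p <- phi_coefficient(rep(0, 10), g)
  expect_equal(unname(p$phi), c(0, 0))
  expect_error(phi_coefficient(c(1, 0, 2, 0), rep(c("a", "b"), 2)), "binary")
  expect_error(phi_coefficient(c(1, 0), factor(c("a", "a"), levels = c("a", "b"))),
               "empty")
})

test_that("phi matches its closed-form worked example", {
  # K = 2, group sizes (4, 6), occupied (3, 1): f = (0.75, 1/6)
  p <- phi_coefficient(c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0),
                       rep(c("a", "b"), c(4, 6)))
  expect_equal(round(unname(p$phi[1]), 4), 0.5854)
  expect_equal(round(specialization(p), 4), 0.8278)
})

test_that("phi equals brute-force phi on the group-size-equalized 2x2 table", {
  set.seed(7)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    sizes <- sample(2:12, K, replace = TRUE)
    g <- rep(letters[1:K], sizes)
    pres <- rbinom(sum(sizes), 1, runif(1, 0.1, 0.9))
    got <- phi_coefficient(pres, g)$phi
    want <- phi_bruteforce(pres, g)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("phi is invariant under duplicating every site within a group", {
  set.seed(11)
  g <- rep(c("a", "b", "c"), c(5, 7, 4))
  pres <- rbinom(16, 1, 0.4)
  base <- phi_coefficient(pres, g)$phi
  # triple every site of group b: group equalization must not notice
  idx <- c(seq_along(g), rep(which(g == "b"), 2))
  dup <- phi_coefficient(pres[idx], g[idx])$phi
  expect_equal(unname(base), unname(dup), tolerance = 1e-12)
})

test_that("specialization is the Euclidean norm of the phi profile", {
  expect_equal(specialization(c(0, 0, 0)), 0)
  expect_equal(specialization(c(1, -1)), sqrt(2))
})

test_that("commonness is a Haldane-corrected logit, finite at the endpoints", {
  expect_equal(commonness(50, 100), 0)
  expect_equal(commonness(25, 100), log(25.5 / 75.5))
  expect_equal(round(commonness(25, 100), 4), -1.0855)
  expect_equal(round(commonness(0, 100), 4), -5.3033)
  expect_true(is.finite(commonness(100, 100)))
  expect_error(commonness(5, 0), "positive")
  expect_error(commonness(11, 10), "\\[0, group_cells\\]")
})

test_that("five equal bins cover the observed scale, missing stays missing", {
  v <- c(0:9, NA)
  b <- bin_ordinal(v)
  expect_equal(b[1], 1L)   # minimum anchors the first bin
  expect_equal(b[10], 5L)  # maximum closes the last bin
  expect_true(is.na(b[11]))
  expect_equal(b[!is.na(b)], c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  # log transform equalizes a geometric scale
  expect_equal(bin_ordinal(c(1, 10, 100, 1000, 10000), use_log = TRUE), 1:5)
  expect_error(bin_ordinal(rep(3, 10)), "constant")
  expect_error(bin_ordinal(c(-1, 0, 2), use_log = TRUE), "positive")
})

test_that("bin levels are monotone in the input values", {
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(50)
    b <- bin_ordinal(v)
    expect_true(all(diff(b[order(v)]) >= 0))
  }
})

test_that("dummy expansion zeroes not-applicable species, keeps missing", {
  out <- dummy_expand(c("stagnant", "running", "n/a", NA),
                      levels = c("stagnant", "running"),
                      not_applicable = "n/a", prefix = "water")
  expect_equal(colnames(out), c("water_stagnant", "water_running"))
  expect_equal(out[1, ], c(water_stagnant = 1L, water_running = 0L))
  expect_equal(out[2, ], c(water_stagnant = 0L, water_running = 1L))
  expect_equal(out[3, ], c(water_stagnant = 0L, water_running = 0L))
  expect_true(all(is.na(out[4, ])))
  expect_error(dummy_expand("lake", levels = c("a", "b")), "unknown level")
})

test_that("attribute filters drop dominant and poorly covered attributes", {
  n <- 200
  specs <- list(
    attribute_spec("ok", "binary", 2L, "poorly_known"),
    attribute_spec("dominant", "binary", 2L, "poorly_known"),
    attribute_spec("at_25", "binary", 2L, "poorly_known"),
    attribute_spec("at_26", "binary", 2L, "poorly_known")
  )
  data <- data.frame(
    ok = rep(1:2, 100),
    dominant = c(rep(1L, 199), 2L),            # share 0.995 > 0.99
    at_25 = c(rep(NA, 50), rep(1:2, 75)),      # exactly 25%: retained
    at_26 = c(rep(NA, 52), rep(1:2, 74))       # 26%: dropped
  )
  tbl <- species_table(data, specs, sprintf("s%03d", 1:n))
  out <- filter_attributes(tbl)
  expect_setequal(names(out$table$data), c("ok", "at_25"))
  expect_setequal(out$report$attribute, c("dominant", "at_26"))
  expect_equal(
    out$report$fraction[out$report$attribute == "dominant"], 0.995)
  expect_equal(
    out$report$rule[out$report$attribute == "at_26"], "missing_share")
  # idempotence
  again <- filter_attributes(out$table)
  expect_identical(again$table$data, out$table$data)
  expect_equal(nrow(again$report), 0L)
  # everything removed is an error
  all_bad <- subset_species(tbl, cols = "dominant")
  expect_error(filter_attributes(all_bad), "all attributes")
})
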