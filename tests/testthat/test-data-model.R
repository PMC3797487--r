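test_that("attribute specs enforce the category-count and kind rules", {
  expect_error(attribute_spec("x", "ordinal", 1), "between 2 and 10")
  expect_error(attribute_spec("x", "ordinal", 11), "between 2 and 10")
  expect_error(attribute_spec("x", "binary", 3), "exactly 2")
  expect_silent(s <- attribute_spec("x", "nominal", 10))
  expect_equal(s$n_categories, 10L)
})

test_that("Red List categories map monotonically onto the binary axes", {
  m <- redlist_mapping()
  expect_equal(map_redlist("rare", m, "rarity"), 1L)
  expect_equal(map_redlist("very rare", m, "rarity"), 1L)
  expect_equal(map_redlist("moderately declining", m, "decline"), 1L)
  expect_equal(map_redlist("strongly declining", m, "decline"), 1L)
  expect_equal(map_redlist("common", m, "rarity"), 0L)
  expect_equal(map_redlist("stable or increasing", m, "decline"), 0L)
  # everything at or above the threshold is positive, below negative
  for (ax in c("rarity", "decline")) {
    cats <- m[[ax]]$categories
    thr <- match(m[[ax]]$threshold, cats)
    expect_equal(map_redlist(cats, m, ax),
                 as.integer(seq_along(cats) >= thr))
  }
  expect_error(map_redlist("unheard of", m, "rarity"), "unknown")
})

test_that("species tables validate category domains and identifiers", {
  tbl <- toy_table()
  expect_equal(n_species(tbl), 12L)
  expect_equal(n_attributes(tbl), 5L)
  bad <- tbl$data
  bad$size[2] <- 6L
  expect_error(
    species_table(bad, tbl$specs, tbl$species_id, tbl$group, tbl$kingdom),
    "sp02.*size|size.*sp02"
  )
  expect_error(
    species_table(tbl$data, tbl$specs, rep("dup", 12)),
    "unique"
  )
})

test_that("tier column sets are nested and commonness is dropped for rarity", {
  tbl <- toy_table()
  pk <- select_tier(tbl, "poorly_known", "decline")
  wk <- select_tier(tbl, "well_known", "decline")
  ev <- select_tier(tbl, "evaluated", "decline")
  expect_true(all(names(pk$data) %in% names(wk$data)))
  expect_true(all(names(wk$data) %in% names(ev$data)))
  expect_equal(n_attributes(ev), 5L)
  # rarity runs never see the commonness attribute, whatever the tier
  ev_rar <- select_tier(tbl, "evaluated", "rarity")
  expect_equal(n_attributes(ev_rar), 4L)
  expect_false("commonness_1950_1990" %in% names(ev_rar$data))
  expect_identical(names(select_tier(tbl, "poorly_known", "rarity")$data),
                   names(pk$data))
})

test_that("group membership follows the supplied hierarchy", {
  tbl <- toy_table()
  expect_equal(sum(group_members(tbl, "birds")), 6L)
  expect_equal(sum(group_members(tbl, "vertebrates")), 6L)
  expect_equal(sum(group_members(tbl, "animals")), 12L)
  expect_true(all(group_members(tbl, "birds") <=
                    group_members(tbl, "vertebrates")))
})

test_that("species tables round-trip through CSV + YAML exactly", {
  tbl <- toy_table(with_missing = TRUE)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "species.csv")
  yml <- file.path(dir, "attributes.yml")
  write_species_table(tbl, csv, yml)
  back <- suppressMessages(read_species_table(csv, yml))
  expect_identical(back$data, tbl$data)
  expect_identical(back$species_id, tbl$species_id)
  expect_identical(back$rarity, tbl$rarity)
  expect_identical(back$decline, tbl$decline)
  expect_identical(back$hierarchy, tbl$hierarchy)
  expect_identical(lapply(back$specs, unclass), lapply(tbl$specs, unclass))
  expect_identical(is.na(back$data), is.na(tbl$data))
})

test_that("reading rejects unknown categories, attributes and duplicate ids", {
  tbl <- toy_table()
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "species.csv")
  yml <- file.path(dir, "attributes.yml")
  write_species_table(tbl, csv, yml)

  lines <- readLines(csv)
  # out-of-domain value: a 6 on the 5-level "size" attribute
  bad <- sub("^(sp03,[^,]*,[^,]*,[^,]*,[^,]*,)[0-9]", "\\16", lines)
  writeLines(bad, csv)
  expect_error(suppressMessages(read_species_table(csv, yml)),
               "categories")

  writeLines(c(lines, lines[2]), csv)
  expect_error(suppressMessages(read_species_table(csv, yml)), "duplicate")

  writeLines(sub("^size,", "mystery,", gsub(",size,", ",mystery,", lines)),
             csv)
  expect_error(suppressMessages(read_species_table(csv, yml)),
               "not in the metadata")
})
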