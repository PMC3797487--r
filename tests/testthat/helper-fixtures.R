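# Shared builders for small in-code fixtures.

# A tiny fully specified table: k attributes over three tiers, two groups.
toy_table <- function(n = 12, with_missing = FALSE) {
  set.seed(42)
  specs <- list(
    attribute_spec("size", "ordinal", 5L, "poorly_known"),
    attribute_spec("winged", "binary", 2L, "poorly_known"),
    attribute_spec("diet", "nominal", 3L, "well_known"),
    attribute_spec("habitat_pref", "ordinal", 5L, "evaluated",
                   derivation = "phi"),
    attribute_spec("commonness_1950_1990", "ordinal", 5L, "evaluated",
                   derivation = "commonness")
  )
  data <- data.frame(
    size = sample(1:5, n, TRUE),
    winged = sample(1:2, n, TRUE),
    diet = sample(1:3, n, TRUE),
    habitat_pref = sample(1:5, n, TRUE),
    commonness_1950_1990 = sample(1:5, n, TRUE)
  )
  if (with_missing) data$size[c(1, 3)] <- NA
  species_table(
    data, specs,
    species_id = sprintf("sp%02d", seq_len(n)),
    group = rep(c("birds", "beetles"), length.out = n),
    kingdom = "animals",
    rarity = rep(c(1L, 0L), length.out = n),
    decline = rep(c(0L, 1L), length.out = n),
    hierarchy = c(birds = "vertebrates", beetles = "insects",
                  vertebrates = "animals", insects = "animals")
  )
}

# Brute-force oracle for the group-equalized phi: weight every site by
# 1 / n_k so each group contributes total mass 1, then compute classical
# 2x2 phi between presence and membership-in-group-k:
# phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)).
phi_bruteforce <- function(presence, site_groups) {
  site_groups <- as.factor(site_groups)
  n_k <- table(site_groups)
  w <- 1 / as.numeric(n_k[site_groups])
  vapply(levels(site_groups), function(g) {
    ing <- site_groups == g
    a <- sum(w[ing] * presence[ing])
    b <- sum(w[ing] * (1 - presence[ing]))
    c_ <- sum(w[!ing] * presence[!ing])
    d <- sum(w[!ing] * (1 - presence[!ing]))
    den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
    if (den == 0) 0 else (a * d - b * c_) / sqrt(den)
  }, numeric(1))
}

# Random valid confusion counts (both classes present on both margins
# where required).
random_confusion <- function() {
  repeat {
    x <- sample(0:50, 4, replace = TRUE)
    if (x[1] + x[3] > 0 && x[2] + x[4] > 0 && sum(x) > 0) {
      return(confusion_counts(tp = x[1], fp = x[2], fn = x[3], tn = x[4]))
    }
  }
}

# A small separable classification problem: one attribute equal to the
# label plus pure-noise attributes.
separable_table <- function(n = 200, n_noise = 10, seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, length.out = n)
  data <- data.frame(signal = labels + 1L)
  specs <- list(attribute_spec("signal", "binary", 2L, "poorly_known"))
  for (j in seq_len(n_noise)) {
    nm <- sprintf("noise%02d", j)
    data[[nm]] <- sample(1:4, n, TRUE)
    specs[[nm]] <- attribute_spec(nm, "nominal", 4L, "poorly_known")
  }
  list(table = species_table(data, specs,
                             species_id = sprintf("s%03d", seq_len(n))),
       labels = labels)
}
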