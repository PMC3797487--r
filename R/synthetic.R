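#' Configuration of the synthetic species-attribute generator
#'
#' The generator emulates the statistical structure of a national Red List
#' trait dataset: species nested in taxonomic groups under a kingdom,
#' categorical/ordinal attributes in three nested availability tiers,
#' decline and rarity labels driven by a small set of planted informative
#' attributes plus label noise, grid-cell occupancy correlated with decline,
#' and missing-completely-at-random cells.  Defaults give 600 species in
#' four groups of 150 (two enclosing groups of 300), 30 attributes (28 raw
#' plus a commonness and a specialization attribute derived from the
#' generated occupancy), 5 informative attributes spread over the tiers,
#' label noise 0.1 and target prevalence 0.5 — class balance near 0.5 being
#' the regime the classification is designed for.
#'
#' @param n_species total number of species.
#' @param group_sizes named integer vector of species counts per finest
#'   group; must sum to `n_species`.
#' @param hierarchy named character vector of parent links for the group
#'   tree.
#' @param kingdom kingdom label for all species.
#' @param n_attributes named integer vector: number of *raw* attributes
#'   whose lowest availability tier is `poorly_known`, `well_known` and
#'   `evaluated`; two occupancy-derived attributes (commonness,
#'   specialization) are always appended to the evaluated tier.
#' @param kind_mix proportions of binary / 5-level ordinal / nominal kinds
#'   among the non-informative raw attributes.
#' @param n_informative number of label-informative attributes.
#' @param informative_tiers tier of each informative attribute (length
#'   `n_informative`); spreading them over the tiers makes classification
#'   improve from tier to tier as it does in real data.
#' @param effect_model `"logistic"` (weighted sum of informative attributes
#'   thresholded at a calibrated cutoff) or `"rules"` (a fixed interaction
#'   rule list, for testing tree-friendly nonadditive structure).
#' @param effect_size common weight of the informative attributes in the
#'   logistic model.
#' @param syndrome_noise standard deviation of each informative attribute's
#'   deviation from a shared latent trait axis.  Informative attributes are
#'   generated as noisy readouts of one latent "vulnerability syndrome" per
#'   species, mirroring how real trait sets correlate (body size, fecundity,
#'   lifespan move together); each planted attribute is therefore
#'   individually predictive while the joint rule stays learnable.
#' @param label_noise probability of flipping a label; scalar or named per
#'   finest group (values in \[0, 0.5)).  Group-asymmetric noise lets an
#'   indicator group be noisier than the rest of its higher group.
#' @param missing_rate MCAR missing-cell probability for raw attributes;
#'   scalar or named per tier (values in \[0, 0.4\]).  Derived distribution
#'   attributes are generated complete.
#' @param occupancy list: `n_sites`, `n_site_groups`, `base_rate`,
#'   `preference_strength` (added presence probability in the preferred
#'   site group), `commonness_effect` (logit shift of overall occupancy for
#'   declining species, tying historic commonness to decline).
#' @param target_prevalence target fraction of declining (and rare) species.
#' @param seed integer seed; the whole draw is a deterministic function of
#'   the configuration and this seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_species = 600L,
    group_sizes = c(birds = 150L, fish = 150L,
                    butterflies = 150L, beetles = 150L),
    hierarchy = c(birds = "vertebrates", fish = "vertebrates",
                  butterflies = "insects", beetles = "insects",
                  vertebrates = "animals", insects = "animals"),
    kingdom = "animals",
    n_attributes = c(poorly_known = 10L, well_known = 10L, evaluated = 8L),
    kind_mix = c(binary = 0.5, ordinal = 0.4, nominal = 0.1),
    n_informative = 5L,
    informative_tiers = c("poorly_known", "poorly_known",
                          "well_known", "well_known", "evaluated"),
    effect_model = c("logistic", "rules"),
    effect_size = 2,
    syndrome_noise = 0.5,
    label_noise = 0.1,
    missing_rate = 0.1,
    occupancy = list(n_sites = 120L, n_site_groups = 4L, base_rate = 0.25,
                     preference_strength = 0.35, commonness_effect = 0.3),
    target_prevalence = 0.5,
    seed = 1L) {
  effect_model <- match.arg(effect_model)
  if (sum(group_sizes) != n_species) {
    stopf("group sizes sum to %d, not n_species = %d",
          sum(group_sizes), n_species)
  }
  if (!all(names(n_attributes) %in% TIER_LEVELS)) {
    stopf("n_attributes must be named by tier")
  }
  if (n_informative > sum(n_attributes)) {
    stopf("more informative attributes than attributes")
  }
  if (length(informative_tiers) != n_informative ||
      !all(informative_tiers %in% TIER_LEVELS)) {
    stopf("informative_tiers must give a valid tier per informative attribute")
  }
  for (tier in TIER_LEVELS) {
    if (sum(informative_tiers == tier) > n_attributes[[tier]]) {
      stopf("tier %s cannot hold %d informative attributes", tier,
            sum(informative_tiers == tier))
    }
  }
  noise <- expand_by(label_noise, names(group_sizes), "label_noise")
  if (any(noise < 0 | noise >= 0.5)) stopf("label_noise must lie in [0, 0.5)")
  miss <- expand_by(missing_rate, TIER_LEVELS, "missing_rate")
  if (any(miss < 0 | miss > 0.4)) stopf("missing_rate must lie in [0, 0.4]")
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stopf("target_prevalence must lie strictly between 0 and 1")
  }
  nu_bar <- sum(noise * group_sizes) / n_species
  p0 <- (target_prevalence - nu_bar) / (1 - 2 * nu_bar)
  if (effect_model == "logistic" && (p0 <= 0 || p0 >= 1)) {
    stopf("target prevalence %.2f unreachable under label noise %.2f",
          target_prevalence, nu_bar)
  }
  structure(
    list(n_species = as.integer(n_species), group_sizes = group_sizes,
         hierarchy = hierarchy, kingdom = kingdom,
         n_attributes = n_attributes, kind_mix = kind_mix,
         n_informative = as.integer(n_informative),
         informative_tiers = informative_tiers,
         effect_model = effect_model, effect_size = effect_size,
         syndrome_noise = syndrome_noise,
         label_noise = noise, missing_rate = miss, occupancy = occupancy,
         target_prevalence = target_prevalence, pre_noise_prevalence = p0,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

expand_by <- function(x, names_out, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(setNames(rep(x, length(names_out)), names_out))
  }
  if (!all(names_out %in% names(x))) {
    stopf("%s must be a scalar or named over %s", what,
          paste(names_out, collapse = ", "))
  }
  x[names_out]
}

# Dirichlet draw around a uniform base, giving each taxonomic group its own
# category base rates (mild taxonomic signal without simulating phylogeny).
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# One informative attribute as a noisy readout of the latent axis z:
# binary attributes split at the latent median, ordinals cut the readout
# into five equal-mass levels.
latent_readout <- function(z, kind, sigma) {
  v <- z + stats::rnorm(length(z), 0, sigma)
  if (kind == "binary") {
    1L + (v > 0)
  } else {
    findInterval(stats::pnorm(v / sqrt(1 + sigma^2)), (1:4) / 5) + 1L
  }
}

#' Generate a synthetic species table, occupancy table and ground truth
#'
#' Draws attribute values with group-dependent base rates, assigns decline
#' and rarity labels from the configured effect model on the planted
#' informative attributes (with group-specific label noise), generates a
#' grid-cell occupancy table whose overall occupancy is shifted for
#' declining species, appends occupancy-derived commonness and
#' specialization attributes ([commonness()], [phi_coefficient()],
#' [specialization()], binned with [bin_ordinal()]), and finally applies
#' MCAR missingness to the raw attributes.
#'
#' The label rule is calibrated so that the pre-noise number of positives
#' is exactly `round(p0 * n)` with `p0` chosen such that the expected
#' post-noise prevalence equals `target_prevalence` (ties at the score
#' cutoff are resolved at random).  The ground truth records the rule and a
#' Monte Carlo estimate (100,000 draws) of the Bayes-optimal accuracy of
#' any classifier using the raw attributes; occupancy-derived attributes
#' carry additional signal not counted in that bound.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (a [species_table()] with rarity and decline
#'   labels), `occupancy` (an [occupancy_table()]) and `truth` (list:
#'   informative attribute names, model, weights or rules, cutoff,
#'   realized prevalences, `bayes_accuracy`).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_species
  groups <- rep(names(config$group_sizes), config$group_sizes)

  # ---- attribute specs ------------------------------------------------
  specs <- list()
  informative <- character()
  for (tier in TIER_LEVELS) {
    n_t <- config$n_attributes[[tier]]
    if (n_t == 0L) next
    n_inf_t <- sum(config$informative_tiers == tier)
    short <- c(poorly_known = "pk", well_known = "wk", evaluated = "ev")[[tier]]
    for (i in seq_len(n_t)) {
      nm <- sprintf("%s_attr%02d", short, i)
      if (i <= n_inf_t) {
        # planted signal: alternate binary / 5-level ordinal
        kind <- if (length(informative) %% 2 == 0) "binary" else "ordinal"
        specs[[nm]] <- attribute_spec(nm, kind,
                                      if (kind == "binary") 2L else 5L, tier)
        informative <- c(informative, nm)
      } else {
        kind <- sample(names(config$kind_mix), 1L, prob = config$kind_mix)
        k <- switch(kind, binary = 2L, ordinal = 5L,
                    nominal = sample(3:6, 1L))
        specs[[nm]] <- attribute_spec(nm, kind, k, tier)
      }
    }
  }

  # ---- attribute values -----------------------------------------------
  # Informative attributes are noisy readouts of one latent vulnerability
  # axis per species; the remaining attributes get group-dependent base
  # rates (Dirichlet-perturbed), which is what carries the taxonomic
  # structure.
  data <- as.data.frame(setNames(
    rep(list(integer(n)), length(specs)), names(specs)))
  z <- stats::rnorm(n)
  for (nm in names(specs)) {
    k <- specs[[nm]]$n_categories
    if (nm %in% informative) {
      data[[nm]] <- latent_readout(z, specs[[nm]]$kind,
                                   config$syndrome_noise)
    } else {
      for (g in names(config$group_sizes)) {
        rows <- which(groups == g)
        probs <- rdirichlet1(rep(20 / k, k))  # concentration 20 near uniform
        data[rows, nm] <- sample.int(k, length(rows), replace = TRUE,
                                     prob = probs)
      }
    }
  }

  # ---- labels from the effect model -----------------------------------
  noise <- config$label_noise[groups]
  w <- setNames(rep(config$effect_size, length(informative)), informative)
  score_fun <- function(df) {
    if (!length(informative)) return(rep(0, nrow(df)))
    contrib <- vapply(informative, function(nm) {
      x <- df[[nm]]
      if (specs[[nm]]$kind == "binary") w[nm] * (2 * x - 3) # {1,2} -> {-1,1}
      else w[nm] * (x - 3) / 2                              # 1..5 -> -1..1
    }, numeric(nrow(df)))
    rowSums(contrib)
  }
  rules_fun <- function(df) {
    # fixed interaction rules over the first informative attributes
    b1 <- df[[informative[1]]]; o1 <- df[[informative[2]]]
    b2 <- df[[informative[3]]]; o2 <- df[[informative[4]]]
    as.integer((b1 == 2 & o1 >= 3) | (b2 == 2 & o2 <= 2))
  }

  draw_labels <- function(score, p0) {
    k_pos <- as.integer(round_half_up(p0 * n))
    ord <- order(-score, stats::runif(n))   # random tie-breaking
    base <- integer(n)
    base[ord[seq_len(k_pos)]] <- 1L
    cutoff <- score[ord[k_pos]]
    tie <- score == cutoff
    frac_tie <- if (any(tie)) mean(base[tie] == 1L) else 0
    flip <- stats::runif(n) < noise
    list(labels = as.integer(ifelse(flip, 1L - base, base)),
         cutoff = cutoff, frac_tie = frac_tie)
  }

  if (config$effect_model == "logistic") {
    decl <- draw_labels(score_fun(data), config$pre_noise_prevalence)
    decline <- decl$labels
  } else {
    if (length(informative) < 4L) {
      stopf("the rule-list model needs at least 4 informative attributes")
    }
    base <- rules_fun(data)
    flip <- stats::runif(n) < noise
    decline <- as.integer(ifelse(flip, 1L - base, base))
    decl <- list(cutoff = NA_real_, frac_tie = NA_real_)
    if (abs(mean(decline) - config$target_prevalence) > 0.03) {
      stopf("rule-list prevalence %.3f misses the target %.2f by > 0.03",
            mean(decline), config$target_prevalence)
    }
  }
  # rarity: same machinery, reversed weight signs -> a different planted rule
  w_rar <- w * rep_len(c(1, -1), length(w))
  rar_score <- if (length(informative)) {
    contrib <- vapply(informative, function(nm) {
      x <- data[[nm]]
      if (specs[[nm]]$kind == "binary") w_rar[nm] * (2 * x - 3)
      else w_rar[nm] * (x - 3) / 2
    }, numeric(n))
    rowSums(contrib)
  } else rep(0, n)
  rarity <- draw_labels(rar_score, config$pre_noise_prevalence)$labels

  # ---- occupancy tied to decline --------------------------------------
  oc <- config$occupancy
  site_groups <- rep(paste0("region", seq_len(oc$n_site_groups)),
                     length.out = oc$n_sites)
  preferred <- sample(unique(site_groups), n, replace = TRUE)
  # with no planted signal the generator is fully null: the occupancy
  # link to decline is severed too
  cm_eff <- if (length(informative)) oc$commonness_effect else 0
  base_rate <- stats::plogis(stats::qlogis(oc$base_rate) +
                               cm_eff * (decline - mean(decline)))
  p_mat <- matrix(base_rate, n, oc$n_sites)
  pref_site <- outer(preferred, site_groups, "==")
  p_mat[pref_site] <- pmin(p_mat[pref_site] + oc$preference_strength, 0.95)
  presence <- matrix(as.integer(stats::runif(n * oc$n_sites) < p_mat),
                     n, oc$n_sites)
  rownames(presence) <- sprintf("sp%04d", seq_len(n))
  occ <- occupancy_table(presence, site_groups, era = "1950-1990")

  # ---- occupancy-derived evaluated-tier attributes --------------------
  cm <- commonness(rowSums(presence), oc$n_sites)
  sp_idx <- apply(presence, 1, function(row)
    specialization(phi_coefficient(row, site_groups)))
  data$commonness_1950_1990 <- bin_ordinal(cm)
  specs$commonness_1950_1990 <- attribute_spec(
    "commonness_1950_1990", "ordinal", 5L, "evaluated",
    derivation = "commonness")
  data$pgr_specialization <- bin_ordinal(sp_idx)
  specs$pgr_specialization <- attribute_spec(
    "pgr_specialization", "ordinal", 5L, "evaluated",
    derivation = "specialization")

  # ---- MCAR missingness on raw attributes -----------------------------
  for (nm in names(specs)) {
    if (specs[[nm]]$derivation != "raw") next
    rate <- config$missing_rate[[specs[[nm]]$tier]]
    if (rate > 0) {
      data[stats::runif(n) < rate, nm] <- NA_integer_
    }
  }

  table <- species_table(
    data = data, specs = specs,
    species_id = sprintf("sp%04d", seq_len(n)),
    group = groups, kingdom = config$kingdom,
    rarity = rarity, decline = decline,
    hierarchy = config$hierarchy
  )

  truth <- list(
    informative = informative,
    effect_model = config$effect_model,
    weights = if (config$effect_model == "logistic") w else NULL,
    cutoff = decl$cutoff, frac_tie = decl$frac_tie,
    realized_prevalence = c(decline = mean(decline), rarity = mean(rarity)),
    bayes_accuracy = bayes_accuracy_mc(config, specs, informative, w,
                                       decl$cutoff, decl$frac_tie,
                                       rules_fun, cm_range = range(cm))
  )
  list(table = table, occupancy = occ, truth = truth)
}

# Monte Carlo estimate (100,000 draws) of the Bayes-optimal accuracy of a
# classifier that sees the raw informative attributes plus the binned
# commonness attribute.  Per draw the label posterior is known exactly:
# P(y = 1 | x) follows from the planted rule and the group noise, and the
# commonness channel multiplies in the class-conditional bin likelihoods
# g(bin | y), themselves estimated by simulating occupancy counts per
# class.  Accuracy of the optimal decision is E[max(P, 1 - P)].
# With no informative attributes the generator plants no signal at all
# (the occupancy link is severed too), so the bound is max(p, 1 - p).
bayes_accuracy_mc <- function(config, specs, informative, w, cutoff,
                              frac_tie, rules_fun, cm_range,
                              n_mc = 100000L) {
  if (!length(informative)) {
    p <- config$target_prevalence
    return(max(p, 1 - p))
  }
  g_mc <- sample(names(config$group_sizes), n_mc, replace = TRUE,
                 prob = config$group_sizes)
  nu <- config$label_noise[g_mc]
  z_mc <- stats::rnorm(n_mc)
  x_mc <- as.data.frame(setNames(lapply(informative, function(nm) {
    latent_readout(z_mc, specs[[nm]]$kind, config$syndrome_noise)
  }), informative))
  if (config$effect_model == "logistic") {
    contrib <- vapply(informative, function(nm) {
      x <- x_mc[[nm]]
      if (specs[[nm]]$kind == "binary") w[nm] * (2 * x - 3)
      else w[nm] * (x - 3) / 2
    }, numeric(n_mc))
    s <- rowSums(contrib)
    pi_pos <- ifelse(s > cutoff, 1, ifelse(s == cutoff, frac_tie, 0))
  } else {
    pi_pos <- rules_fun(x_mc)
  }
  p_pos <- pi_pos * (1 - nu) + (1 - pi_pos) * nu

  # class-conditional likelihoods of the binned commonness attribute
  oc <- config$occupancy
  n_pref <- sum(rep(seq_len(oc$n_site_groups),
                    length.out = oc$n_sites) == 1L)
  bin_pmf <- function(y, m = 50000L) {
    base <- stats::plogis(stats::qlogis(oc$base_rate) +
                            oc$commonness_effect *
                            (y - config$target_prevalence))
    cnt <- stats::rbinom(m, n_pref, pmin(base + oc$preference_strength, 0.95)) +
      stats::rbinom(m, oc$n_sites - n_pref, base)
    cm <- commonness(cnt, oc$n_sites)
    lev <- pmax(ceiling((cm - cm_range[1]) /
                          diff(cm_range) * 5), 1)
    lev <- pmin(lev, 5)
    tabulate(lev, 5) / m
  }
  g1 <- bin_pmf(1); g0 <- bin_pmf(0)
  # draw the species' own label, then its commonness bin from that class
  y_mc <- as.integer(stats::runif(n_mc) < p_pos)
  bin_mc <- integer(n_mc)
  samp_bin <- function(g, k) sample.int(5, k, replace = TRUE, prob = g)
  bin_mc[y_mc == 1L] <- samp_bin(g1, sum(y_mc == 1L))
  bin_mc[y_mc == 0L] <- samp_bin(g0, sum(y_mc == 0L))
  post <- p_pos * g1[bin_mc] /
    (p_pos * g1[bin_mc] + (1 - p_pos) * g0[bin_mc])
  # conditional on (x, bin) the optimal decision is right with probability
  # max(post, 1 - post); averaging that instead of realized 0/1 outcomes
  # cuts the MC noise
  mean(pmax(post, 1 - post))
}

#' Mask observed cells completely at random
#'
#' Hides an exact number of observed cells (`round(rate * n_observed)`,
#' sampled without replacement) so that imputation recovery can be scored
#' against the hidden originals.
#'
#' @param table a [species_table()].
#' @param rate fraction of observed cells to mask, in \[0, 1).
#' @param seed integer seed.
#' @param cols attribute names eligible for masking (default: all).
#' @return list with `table` (masked copy) and `mask` (data.frame with
#'   columns `row`, `attribute`, `value` holding the hidden originals).
#' @export
mask_cells <- function(table, rate, seed = 1L, cols = names(table$data)) {
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1)")
  obs <- which(!is.na(as.matrix(table$data[cols])), arr.ind = TRUE)
  m <- as.integer(round_half_up(rate * nrow(obs)))
  mask <- data.frame(row = integer(), attribute = character(),
                     value = integer(), stringsAsFactors = FALSE)
  if (m > 0L) {
    set.seed(seed)
    pick <- obs[sample.int(nrow(obs), m), , drop = FALSE]
    mask <- data.frame(
      row = as.integer(pick[, "row"]),
      attribute = cols[pick[, "col"]],
      value = vapply(seq_len(m), function(i)
        table$data[pick[i, "row"], cols[pick[i, "col"]]], integer(1)),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(m)) {
      table$data[mask$row[i], mask$attribute[i]] <- NA_integer_
    }
  }
  list(table = table, mask = mask)
}
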