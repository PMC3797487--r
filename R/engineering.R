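#' Occupancy table
#'
#' Presence/absence of species over grid cells ("sites"), with a group label
#' per site.  Site groups come from a grouping scheme such as land-use
#' categories (LUC) or physical-geographical regions (PGR); preference and
#' specialization attributes are computed from them.
#'
#' @param presence binary species x site matrix (row names = species ids).
#' @param site_groups character/factor vector of group labels, one per site.
#' @param era free-text label for the observation period, e.g. "1950-1990".
#' @return An object of class `occupancy_table`.
#' @export
occupancy_table <- function(presence, site_groups, era = "") {
  presence <- as.matrix(presence)
  if (!all(presence %in% c(0, 1))) stopf("presence matrix must be binary 0/1")
  if (length(site_groups) != ncol(presence)) {
    stopf("need one site group label per site (%d sites, %d labels)",
          ncol(presence), length(site_groups))
  }
  site_groups <- as.factor(site_groups)
  if (nlevels(site_groups) < 2L) stopf("need at least 2 site groups")
  if (any(table(site_groups) == 0L)) stopf("every site group needs >= 1 site")
  structure(list(presence = presence, site_groups = site_groups, era = era),
            class = "occupancy_table")
}

#' Group-equalized phi preference coefficient
#'
#' Measures a species' preference for each site group as the classical
#' 2x2 phi (point-biserial) correlation between presence and
#' membership-in-group-k, computed as if all site groups had equal size.
#' With `f_k = a_k / n_k` the within-group occupancy fraction and
#' `fbar = mean(f_k)` over the K groups,
#' \deqn{\phi_k = (f_k - \bar f) / \sqrt{(K - 1)\,\bar f\,(1 - \bar f)}.}
#' A species present everywhere or nowhere (`fbar` 0 or 1) carries no
#' preference signal and gets `phi_k = 0` for all groups.
#'
#' Group equalization makes the coefficient invariant under duplicating all
#' sites within a group, so over- or under-sampled regions do not distort
#' preference.
#'
#' @param presence binary vector over sites (one species' occupancy row).
#' @param site_groups group label per site (>= 2 groups, none empty).
#' @return An object of class `phi_profile`: list with `phi` (named vector
#'   of coefficients in \[-1, 1\]), `f` (within-group occupancy fractions)
#'   and `fbar`.
#' @export
#' @examples
#' phi_coefficient(c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0),
#'                 rep(c("a", "b"), c(4, 6)))
phi_coefficient <- function(presence, site_groups) {
  if (!all(presence %in% c(0, 1))) stopf("presence vector must be binary 0/1")
  site_groups <- as.factor(site_groups)
  if (nlevels(site_groups) < 2L) stopf("need at least 2 site groups")
  n_k <- table(site_groups)
  if (any(n_k == 0L)) {
    stopf("empty site group: '%s'", names(n_k)[which(n_k == 0L)[1]])
  }
  if (length(presence) != length(site_groups)) {
    stopf("presence and site_groups lengths differ")
  }
  f <- tapply(presence, site_groups, mean)
  f <- setNames(as.numeric(f), names(f))
  K <- nlevels(site_groups)
  fbar <- mean(f)
  if (fbar %in% c(0, 1)) {
    phi <- setNames(rep(0, K), names(f))
  } else {
    phi <- (f - fbar) / sqrt((K - 1) * fbar * (1 - fbar))
  }
  structure(list(phi = phi, f = f, fbar = fbar), class = "phi_profile")
}

#' @export
print.phi_profile <- function(x, ...) {
  cat("phi profile (group-equalized):\n")
  print(round(x$phi, 4))
  cat(sprintf("specialization: %.4f\n", specialization(x)))
  invisible(x)
}

#' Habitat specialization index
#'
#' The Euclidean norm of a species' phi profile over all groups of a
#' grouping scheme: `S = sqrt(sum(phi_k^2))`.  A perfect specialist of one
#' of two groups has `S = sqrt(2)`; a species with no preference has 0.
#'
#' @param profile a [phi_coefficient()] result, or a bare numeric vector of
#'   phi coefficients.
#' @return non-negative scalar.
#' @export
specialization <- function(profile) {
  phi <- if (inherits(profile, "phi_profile")) profile$phi else profile
  sqrt(sum(phi^2))
}

#' Commonness (logit occupancy fraction)
#'
#' The logit of the fraction of all grid cells occupied by the species'
#' group in which the species itself was observed.  The fraction is
#' Haldane-corrected, `p' = (occupied + 0.5) / (total + 1)`, so species
#' observed in none or all cells still get a finite value.
#'
#' @param occupied_cells number of grid cells in which the species was
#'   observed.
#' @param group_cells number of grid cells in which the species group was
#'   observed (> 0).
#' @return scalar logit value.
#' @export
#' @examples
#' commonness(50, 100)  # 0: observed in half the group's cells
commonness <- function(occupied_cells, group_cells) {
  if (any(group_cells <= 0)) stopf("group_cells must be positive")
  if (any(occupied_cells < 0) || any(occupied_cells > group_cells)) {
    stopf("occupied_cells must lie in [0, group_cells]")
  }
  p <- (occupied_cells + 0.5) / (group_cells + 1)
  log(p / (1 - p))
}

#' Discretize a scale variable into a five-level ordinal attribute
#'
#' The observed range of the (optionally log-transformed) values is divided
#' into `n_bins` equal parts; each value is assigned the bin it falls in.
#' A value falling exactly on an interior bin edge goes to the lower bin;
#' the global minimum anchors the first bin and the global maximum the
#' last.  Missing values stay missing.
#'
#' @param values numeric vector; may contain `NA`.
#' @param use_log log-transform before binning (requires positive values);
#'   used for right-skewed scales to approach normality.
#' @param n_bins number of equal-width bins (default 5).
#' @return integer vector of levels `1..n_bins` with `NA` preserved.
#' @export
bin_ordinal <- function(values, use_log = FALSE, n_bins = 5L) {
  obs <- values[!is.na(values)]
  if (length(unique(obs)) < 2L) {
    stopf("cannot bin a constant or empty scale variable")
  }
  if (use_log) {
    if (any(obs <= 0)) stopf("log transform requires positive values")
    values <- log(values)
    obs <- log(obs)
  }
  lo <- min(obs); hi <- max(obs)
  lev <- ceiling((values - lo) / (hi - lo) * n_bins)  # edge ties -> lower bin
  lev[!is.na(lev) & lev < 1L] <- 1L                   # the global minimum
  as.integer(lev)
}

#' Expand a sometimes-irrelevant nominal variable into dummy attributes
#'
#' Some categorical variables are meaningless for part of the species (the
#' preference for stagnant versus running water is of no relevance for a
#' terrestrial species).  Such a variable becomes one binary attribute per
#' level; species for which the variable does not apply get 0 in every
#' dummy, while genuinely missing values stay missing in every dummy.
#'
#' @param values character/factor vector containing level labels, the
#'   `not_applicable` token, and `NA` for missing.
#' @param levels the real level labels, in order.
#' @param not_applicable token marking irrelevance (distinct from missing).
#' @param prefix name prefix for the dummy columns.
#' @return integer matrix with one 0/1 column per level (`NA` preserved).
#' @export
#' @examples
#' dummy_expand(c("stagnant", "running", "n/a", NA),
#'              levels = c("stagnant", "running"), not_applicable = "n/a")
dummy_expand <- function(values, levels, not_applicable = "not_applicable",
                         prefix = "dummy") {
  values <- as.character(values)
  known <- c(levels, not_applicable)
  bad <- !is.na(values) & !(values %in% known)
  if (any(bad)) stopf("unknown level '%s'", values[which(bad)[1]])
  out <- vapply(levels, function(lev) {
    v <- as.integer(values == lev)  # not_applicable rows -> 0 in every dummy
    v[is.na(values)] <- NA_integer_
    v
  }, integer(length(values)))
  colnames(out) <- paste(prefix, levels, sep = "_")
  out
}

#' Drop uninformative and poorly covered attributes
#'
#' Removes attributes with more than 99% of the (non-missing) species in a
#' single category, deemed uninformative, and attributes with more than 25%
#' missing values, where imputation could introduce bias.  Both rules are
#' strict inequalities: an attribute with exactly 25% missing is retained.
#' Shares are computed on the species subset present in `table`, so the
#' filter must be re-applied after row subsetting.
#'
#' @param table a [species_table()].
#' @param max_share maximum tolerated share of the modal category (default
#'   0.99, strict).
#' @param max_missing maximum tolerated missing share (default 0.25, strict).
#' @return list with `table` (filtered [species_table()]) and `report`
#'   (data.frame with columns `attribute`, `rule`, `fraction`).
#' @export
filter_attributes <- function(table, max_share = 0.99, max_missing = 0.25) {
  data <- table$data
  report <- data.frame(attribute = character(), rule = character(),
                       fraction = numeric(), stringsAsFactors = FALSE)
  keep <- rep(TRUE, ncol(data))
  for (j in seq_len(ncol(data))) {
    v <- data[[j]]
    miss <- mean(is.na(v))
    if (miss > max_missing) {
      keep[j] <- FALSE
      report <- rbind(report, data.frame(attribute = names(data)[j],
                                         rule = "missing_share",
                                         fraction = miss))
      next
    }
    obs <- v[!is.na(v)]
    share <- if (length(obs)) max(tabulate(obs)) / length(obs) else 1
    if (share > max_share) {
      keep[j] <- FALSE
      report <- rbind(report, data.frame(attribute = names(data)[j],
                                         rule = "dominant_category",
                                         fraction = share))
    }
  }
  if (!any(keep)) stopf("all attributes removed by the filters")
  list(table = subset_species(table, cols = names(data)[keep]),
       report = report)
}
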