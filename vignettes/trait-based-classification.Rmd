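---
title: "Trait-based classification of species rarity and decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based classification of species rarity and decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National Red Lists score a small, well-studied fraction of a country's
species for rarity and decline. If the relationship between species
attributes (morphology, demography, habitat requirements, distribution
summaries) and threat status can be learned across taxonomically disparate
groups, the threat status of the vast majority of unassessed species can be
estimated from their attributes alone — and the adequacy of popular
indicator groups (birds, butterflies, vascular plants) can be quantified
rather than assumed.

`redlistrf` implements that analysis as a reusable pipeline:

1. engineer raw traits and grid-cell occupancy into categorical attributes;
2. impute missing attribute values from random-forest proximities;
3. grow large random forests of classification trees and evaluate them
   out-of-bag (OOB) with conservation-relevant error probabilities;
4. transfer an indicator-group forest to its enclosing taxonomic group and
   compare the actual transfer accuracy with a prevalence-corrected
   expectation;
5. generate synthetic data with known ground truth so that every stage is
   testable although the original survey data are not deposited.

## The data model

A `species_table` is a species x attribute matrix of small integer category
codes (`1..k`, `NA` = missing) plus taxonomic labels and the two binary
response axes. Attributes are declared by `attribute_spec`: kind (binary,
ordinal, nominal), number of levels (2–10), an *availability tier*, and a
derivation note. Tiers model how much can be known about unassessed
species and are nested by construction: attributes of *poorly known*
species (morphology, taxonomy) are a subset of those of *well-known*
species (ecology, behaviour), which are a subset of those of *evaluated*
species (everything, including distribution-derived attributes).
`select_tier()` returns the column set of a tier; for the rarity axis it
always drops the commonness attribute, which is essentially the quantity
rarity is defined by.

Red List categories are reduced to binaries by a configurable, ordered
mapping (`redlist_mapping()`): "rare" and higher counts as rare,
"moderately declining" and higher as declining. Both thresholds follow the
published convention that put prevalence near 0.5, where binary forests
perform best.

## Attribute engineering

* **Preference (phi).** For a grouping of grid cells (land-use categories,
  physical-geographical regions), the group-equalized phi coefficient of
  species presence with membership in group $k$ is
  $$\phi_k = \frac{f_k - \bar f}{\sqrt{(K-1)\,\bar f\,(1-\bar f)}},$$
  with $f_k$ the within-group occupancy fraction and $\bar f$ their mean
  over the $K$ groups. This equals the classical 2x2 phi computed after
  reweighting every site group to equal size (the package tests assert the
  equivalence against a brute-force equalized table to 12 decimals), so
  over-sampled regions do not distort preference. A species present
  everywhere or nowhere carries no preference signal; its profile is
  defined as all zeros rather than left undefined.
* **Specialization** is the Euclidean norm of the phi profile,
  $S = \sqrt{\sum_k \phi_k^2}$.
* **Commonness** is the logit fraction of the group's occupied grid cells
  in which the species was observed. The fraction is Haldane-corrected,
  $p' = (a + 0.5)/(N + 1)$: the published definition is silent on empty or
  full occupancy, and the correction keeps the logit finite with minimal
  distortion elsewhere.
* **Scale variables** are cut into five equal-width bins over the observed
  range (optionally after a log transform for right-skewed scales). Values
  on an interior edge go to the lower bin; the global minimum anchors bin 1
  and the maximum closes bin 5. Derived scale attributes (phi,
  specialization, commonness) pass through the same binning before
  modelling, so every predictor the forest sees is categorical and
  cardinality cannot distort importance.
* **Sometimes-irrelevant nominals** (stagnant vs. running water for a
  terrestrial species) become one dummy per level with zeros for species
  the variable does not apply to; genuinely missing stays missing in every
  dummy.
* **Filters.** Attributes with more than 99% of non-missing species in one
  category, or more than 25% missing values, are dropped (both strict
  inequalities; an attribute at exactly 25% missing is retained). The
  shares are computed on the species subset entering an analysis, so the
  filter is re-applied per run; it is idempotent.

## Proximity imputation

Missing cells are initialised per attribute with the mode (binary/nominal)
or median level (ordinal), then refined iteratively: a forest (default
1000 trees) is grown on the current completed table with the binary labels
as response, the proximity of two species is the fraction of trees in
which they share a terminal node, and each originally missing cell is
replaced by the category with the largest proximity-weighted vote among
species whose cell was actually observed (ordinals: the proximity-weighted
mean level, rounded). Ten iterations by default; observed cells are never
altered; imputed values cannot leave the declared category set.
Proximities are computed over all cases, and the imputation forests are
label-aware by default (`supervised = FALSE` gives unsupervised
proximities), with one deterministic seed per iteration.

## Forests and evaluation

Forests are grown by the `randomForest` package with its canonical
defaults: bootstrap samples of size $n$ drawn with replacement,
$\lfloor\sqrt{p}\rfloor$ candidate attributes per node, Gini splits, trees
grown to purity, 10,000 trees for production runs. Nominal attributes
enter as factors (subset splits), binary and ordinal attributes as integer
levels (threshold splits). OOB predictions are recomputed from the vote
fractions so that exact vote ties go to the negative class — conservative
and deterministic. Permutation importance is the raw mean decrease in OOB
correct classification (not scaled by its standard error); top-10 lists
break ties by attribute name.

Evaluation follows conservation usage. With positives the rare/declining
species, a confusion matrix yields the correct classification
$C = (TP+TN)/n$, the Type I error probability $\alpha = FP/(FP+TN)$ (a
non-threatened species flagged as threatened), the Type II error
probability $\beta = FN/(TP+FN)$ (a threatened species missed), and the
prevalence $p$; the identity $C = (1-p)(1-\alpha) + p(1-\beta)$ holds
exactly and is tested on random integer tables. Classifications are
compared with Pearson chi-square tests (closed form, 1 d.f., no continuity
correction; the Yates-corrected variant of common software is deliberately
not used, and `stats::chisq.test(correct = FALSE)` serves as an
independent cross-check in the tests). A zero margin — a classifier that
never predicts one class — yields statistic 0 and p = 1 with a degeneracy
flag instead of an error.

Published tables report only $(n, p, \alpha, \beta)$, rounded.
`confusion_from_summary()` reconstructs the unique underlying integer
confusion matrix (half-up rounding throughout: half-up is what makes all
published rows internally consistent) and flags summaries whose exact
recomputed rates disagree with the printed ones by more than 0.01.

## Indicator transfer and the prevalence correction

`run_indicator()` grows a forest on an indicator group and classifies its
enclosing higher taxonomic group (decline axis only — decline is the
conservation signal an indicator is meant to carry). Because the higher
group's prevalence $p_h$ differs from the indicator's, the indicator's
accuracy cannot be compared directly with the transfer accuracy; the
*expected* correct classification re-projects the indicator's exact error
ratios:
$$C_{exp} = 100\,[(1-p_h)(1-\alpha) + p_h(1-\beta)],$$
with $p_h$ snapped to an integer species count. The whole procedure —
including the imputation — is replicated (default 10 times) under
deterministic replicate seeds, and 95% Student-t intervals over the
replicates quantify the random part of the procedure (`ci_method =
"normal"` gives $\pm 1.96\,\mathrm{sd}$ instead).

Two design points deserve emphasis:

* By default the indicator's own species are among the classified
  higher-group rows, mirroring the design of classifying the *whole*
  sample of the higher group. Since trees are grown to purity, those rows
  are close to resubstitution and are classified optimistically;
  `include_indicator = FALSE` gives the strictly out-of-sample transfer
  and is what the package's own null checks use.
* Replicate intervals measure only forest and imputation randomness on
  fixed data. The sampling noise of the accuracy *estimates* themselves
  (binomial noise of OOB error rates on $n_{ind}$ species, of transfer
  accuracy on the evaluation rows) is typically several times larger and
  does not shrink relative to the replicate intervals as the problem
  grows, because both scale as $1/\sqrt{n}$. Replicate intervals are
  therefore the wrong yardstick for deciding whether actual and expected
  transfer accuracy coincide under a shared generative rule; the package's
  test suite demonstrates (and documents) that the expectation is unbiased
  while the interval check fails for this structural reason.

`importance_overlap()` counts shared attributes between two top-10
importance lists, quantifying whether an indicator forest uses the same
attributes as the higher group's own forest.

## The synthetic generator

`generate_synthetic()` stands in for the unpublished survey data. What it
emulates, and what it deliberately does not:

* **Shape.** Species nested in taxonomic groups under a kingdom (default
  600 species in four groups of 150, two enclosing groups of 300 — scaled
  down from the published ~1200 species in 18 groups to keep test runs
  fast); 30 attributes in the three nested tiers, mostly binary and
  five-level ordinal; ~10% missing cells, completely at random, on raw
  attributes only (distribution-derived attributes are computed, not
  surveyed, hence complete).
* **Taxonomic structure** comes from Dirichlet-perturbed per-group
  category base rates on the non-informative attributes — realistic group
  signal without simulating phylogeny.
* **Planted signal.** Five informative attributes are noisy readouts of a
  single latent "vulnerability syndrome" axis per species
  (`syndrome_noise = 0.5`), spread over the availability tiers. The
  decline label thresholds a weighted sum of the readouts, calibrated so
  the pre-noise positive count is exact and the expected post-noise
  prevalence equals the target (default 0.5, the regime the method is
  designed for); labels then flip with group-specific noise (default
  0.1). The syndrome structure is a deliberate design choice over
  independent informative attributes: real trait syndromes are strongly
  correlated, each correlated attribute is individually recoverable and
  individually important (so imputation and importance rankings can be
  validated against the ground truth), and an equal-weight sum of
  *independent* attributes is the single most tree-hostile boundary there
  is — a property of CART ensembles, not of the ecology being emulated. A
  rule-list effect model (`effect_model = "rules"`) is provided as the
  interaction-heavy alternative.
* **Occupancy.** A grid of sites in site groups, with per-species
  preferred groups (driving phi and specialization) and an overall
  occupancy rate whose logit is shifted by `commonness_effect` (default
  0.3) for declining species — so historic commonness predicts decline, as
  it does in real data, without becoming an oracle. The commonness and
  specialization attributes appended to the evaluated tier are computed by
  the package's own engineering functions from this occupancy table.
* **Ground truth.** The generator records the informative attributes, the
  rule, and a Monte Carlo estimate (100,000 draws) of the Bayes-optimal
  accuracy of a classifier seeing the raw informative attributes *and* the
  binned commonness attribute (the commonness channel's class-conditional
  bin likelihoods are estimated by simulation). With no informative
  attributes the generator is fully null — the occupancy link is severed
  too — and the bound collapses to $\max(p, 1-p)$.

Passing tests on these data show that the pipeline recovers planted
structure under realistic noise, missingness and class balance; they do
not show robustness to phylogenetic autocorrelation, informative
missingness, expert disagreement between questionnaire answers, or
site-occupancy detection bias, none of which the generator emulates.

## Numerical choices and test scales

Determinism is enforced everywhere: one master seed fans out to stage
seeds through a fixed integer hash, vote ties break to the negative class,
importance ties break by name, bin-edge ties go to the lower bin, and
count reconstruction rounds half-up. Degenerate inputs (constant scale
variables, single-class labels, empty site groups, all-attribute removal)
are errors, not warnings, except the flagged zero-margin chi-square.

The package's test suite runs the full pipeline at reduced sizes chosen to
keep the default run in minutes on one CPU: imputation forests of 100–500
trees with 1–5 iterations, main forests of 300–4000 trees, tables of
120–600 species. Forest OOB accuracy stabilises well below these sizes
(the suite checks 4000- vs 8000-tree forests agree within one percentage
point); production analyses should use the 10,000-tree / 1000-tree x 10
iteration defaults.

## Limitations

* The pipeline classifies; it does not explain. Importance rankings name
  attributes, not mechanisms, and say nothing about causal direction.
* Error probabilities of a single species' prediction are far too high for
  species-level decisions; the method is meant for estimating threat
  levels of species *groups*.
* The prevalence correction assumes the indicator's error rates transfer
  unchanged; when the higher group genuinely follows the shared rules more
  faithfully (less label noise), actual transfer accuracy exceeds the
  expectation — the generator can reproduce this regime via per-group
  `label_noise`.
* Proximity imputation assumes values are recoverable from proximate
  species; under label-aware forests its leaves are label-pure rather than
  attribute-pure, so recovery of an attribute is capped by the label
  noise even when a perfect duplicate attribute exists.
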