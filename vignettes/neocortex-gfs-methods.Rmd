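---
title: "Methods: gene family size and relative neocortex expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene family size and relative neocortex expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neogfs)
```

## The question and the quantities

Across mammals, most of the variation in relative brain size is carried by
the neocortex. `neogfs` asks whether the per-species size of gene families
(GFS — the number of member genes a species contributes to a cross-species
homology cluster) covaries with the *neocortex ratio*

$$N_r = \frac{V_{\text{neocortex}}}{V_{\text{brain}} - V_{\text{neocortex}}},$$

i.e. neocortex volume over the volume of the rest of the brain (Dunbar's
ratio), and whether any such covariation is separable from two classic
confounds: the encephalization index
$E_i = \log m_{\text{brain}} - b \log m_{\text{body}}$ (with the allometric
slope $b = 0.64$ treated as a given constant from a published 493-species
regression) and maximum lifespan (MLSP).

The packaged 28-species phenotype compilation stores total brain volume and
neocortex volume; the first is labelled as such even though comparable
published compilations have mislabelled it as "non-neocortex" volume — for
27 of the 28 rows the tabulated ratio is reproduced from the two volumes at
printed precision, which settles the interpretation. The mouse row is the
single exception (0.12/(0.48-0.12) = 0.333 against a tabulated 0.32); it is
flagged `nr_source = "printed"` and its tabulated ratio is used as-is rather
than silently corrected. `validate_nr_consistency()` reports this
per-species audit.

## The pipeline

1. **Family filtering** (`filter_families`). A family enters the analysis if
   it has members (size ≥ 1) in at least 6 of the species and its sizes vary
   across species. Zeros count: a species without members contributes a size
   of 0, which is itself a count (the `absent_policy = "drop"` alternative
   restricts each family to its member species and is kept for sensitivity
   analysis).
2. **Per-family association** (`family_associations`). Pearson correlation
   of each family's size vector with the phenotype; two-sided p from the
   t transform with $n - 2$ df; Benjamini–Hochberg adjustment across all
   families jointly (via `stats::p.adjust`).
3. **Distribution-shift tests**. The interesting signal is not any single
   family but a shift of the whole distribution of correlations towards
   positive values. `permutation_null` builds the Monte-Carlo null of the
   *mean* correlation (default 10000 replicates); `zscore_shift_test`
   standardizes the observed mean against it and reports the one-tailed
   upper normal probability (the convention that reproduces the published
   p-values for the published Z statistics) together with the
   add-one-corrected empirical rank p. `sign_chisq` tests the
   positive/negative count balance (Pearson χ², df 1, no continuity
   correction; exact zeros excluded — whether published counts excluded
   exact zeros is not documented, so the behaviour is fixed here and
   stated).
4. **Confound and phylogeny correction** (`corrected_association`). First
   residualize the target trait and every family's sizes against the same
   covariates by OLS with intercept across species; then transform both
   residual vectors into Felsenstein independent contrasts; then correlate
   the contrasts *through the origin*. The order — residuals first, then
   contrasts — is part of the method. The through-origin correlation uses
   $n_{\text{contrasts}} - 1$ df (one slope, no intercept).
5. **Enrichment** (`build_term_map`, `enrichment_test`). GO-style terms with
   at least 200 *background* families are tested as-is; smaller terms merge
   into a `SMALL_BP` bucket and unannotated families into `NOT_ANNOTATED`,
   each bucket counting as one annotation and tested like a term (the
   unannotated class is a reportable result, not a discard). Family counts
   per term are divided by the sample's mean annotations per family, so
   samples rich in heavily annotated families are not enriched for
   everything. Significance is the one-sided empirical p over 1000 equally
   sized samples drawn *without replacement* from the background (a sample
   of families is a set), with the add-one correction — 1000 resamples
   cannot support claims below 1/1001. The inequality is non-strict
   (null ≥ observed).
6. **Developmental contrast** (`normalize_samples`, `window_means`,
   `paired_wilcoxon`). Expression columns are normalized to the per-sample
   total, samples are split at 13 years (the approximate age at which human
   cortical thickness peaks; a sample exactly at 13 falls in the "before"
   window, cortex having just matured), genes are averaged within windows
   (a plain mean over samples; `cell_means = TRUE` averages per
   (age, region) cell first), and the paired signed-rank test compares the
   windows, one-tailed "before > after" by default with the two-sided
   variant available. Exact distribution up to 25 non-zero pairs, normal
   approximation with continuity correction above; ties force the
   approximation.

## The permutation scheme

The default null permutes the species assignment *jointly* — one
permutation applied to every family per replicate, equivalent to permuting
the phenotype. This preserves the covariance between families, which the
Z test on the mean correlation requires: with independent per-family
shuffles (`scheme = "per_family"`, kept for sensitivity analysis) the null
of the mean is artificially narrow whenever families covary. With at most
8 species the joint null can be enumerated exhaustively
(`exhaustive = TRUE`), which the tests exploit as an exact oracle.

## The synthetic study system

Every stage is testable without external data through seeded generators
whose defaults are the package's documented study conditions:

* `simulate_tree`: Yule tree rescaled to unit height, 28 tips.
* `simulate_traits`: correlated Brownian motion of (latent log ratio,
  encephalization, log lifespan); per-unit-height SDs (0.5, 0.8, 0.5) give
  realistic spreads, and correlations (0.6 ratio–encephalization, 0.4
  elsewhere) deliberately recreate the identifiability problem: the
  encephalization index tracks the ratio without causing the family
  effects. (In the real 28-species table the corresponding correlations are
  even higher, ≈ 0.8–0.9; the moderate synthetic value keeps the planted
  truth recoverable while preserving the challenge.) Volumes are
  back-computed so `compute_nr` returns the simulated ratio exactly.
* `simulate_gfs`: sizes are Poisson with log-mean
  $a_j + \beta_j z(N_r) + \varepsilon$, baseline $a_j \sim N(\log 5, 0.3)$,
  $\beta_j = 1.5$ for a planted 10% of 1000 families and 0 otherwise, and
  Brownian noise on the tree (SD 0.5) so even unplanted families are
  phylogenetically autocorrelated. Poisson is the default for analytic
  transparency; a negative-binomial `overdispersion` option exists.
* `simulate_annotations`: 25 terms covering 20–35% of families each, three
  of them oversampling planted families 4:1; 10% of families unannotated.
* `simulate_expression`: 13 ages (three prenatal, stored as negative years,
  $(\text{pcw} - 40)/52$) × 11 cortical regions = 143 samples; log-normal
  gene baselines; genes of planted families boosted 1.5× before 13 years.
  Background genes matter here: a boost shared by *every* gene would cancel
  exactly in the per-sample normalization, so the bundle simulates
  unboosted background families alongside the planted ones.

What the generators do **not** emulate: the heavy right tail and
zero-inflation of real homology-cluster size distributions, correlated
annotation structure (terms are sampled independently given the planted
bias, with no ontology graph), region-specific expression trajectories, and
measurement error in the phenotypes. Passing recovery tests therefore shows
the machinery is correct and calibrated under its stated model — not that
real data carry the signal.

## Calibration and exchangeability

Null-calibration checks generate families with `beta = 0` **and**
`phylo_noise_sd = 0`. This is deliberate: with tree-structured family noise
a Brownian phenotype and the families are mutually autocorrelated even with
no planted effect, so no species-permutation test is calibrated there —
that anticonservatism is precisely why the contrast stage exists.
Calibration is asserted on the empirical rank p (the permutation-exact
quantity); the normal-approximation p is reported alongside and agrees
closely in practice.

A related caveat holds for the corrected stage itself: residualizing across
species before taking contrasts re-introduces mild dependence among
contrasts, and when a particular draw of the traits makes the covariates
nearly explain the target, the corrected test loses power (and its FDR
control degrades). The default preset documents one fixed seed at which
recovery of the planted truth is ≥ 80%; across seeds the corrected recovery
varies far more than the uncorrected one. This mirrors the real design's
weakness, and is reported rather than engineered away.

## Numerical choices

* Multifurcations are resolved to bifurcations with zero-length branches;
  zero lengths are then replaced by $10^{-12} \times$ tree height. The
  epsilon is kept this small so that on a star phylogeny the corrected
  correlation equals the ordinary residual correlation to $10^{-9}$ (a
  larger epsilon measurably breaks that identity).
* Contrasts are computed by `ape::pic`; because the transformation is
  linear in the tip values, a `(tips - 1) x tips` operator is built once
  per tree and applied to thousands of families as one matrix product.
* All empirical p-values use the add-one correction and are never zero.
* BH adjustment, the sign χ², and the signed-rank test are delegated to
  `stats::p.adjust`, `stats::chisq.test` and `stats::wilcox.test`; the
  tests check them against brute-force and exact-enumeration oracles.
* Output tables print floats at 6 significant digits; a written table
  re-round-trips bit-identically.

## Problem sizes used by the test suite

The suite runs the documented preset once (28 species, 1000 families), 200
calibration replicates at 100 families with 500-replicate nulls, 100
random-tree contrast oracles (≤ 32 tips), and 1000 random BH vectors; the
whole suite completes in well under a minute on one CPU. The published
genome-scale counts (11 943 families; 440/321/272/0 significant families;
the specific enriched term lists; the developmental p = 0.00013) depend on
proprietary-scale upstream resources and are covered qualitatively by the
planted-signal recovery and the role-swap asymmetry, not numerically.

## Known limitations

* Plain contrasts on residuals, per the original design — no PGLS or
  branch-length transform estimation; model misfit shows up as the power
  loss described above.
* The encephalization index is consumed as given for the real table (body
  masses are not tabulated); `compute_ei` serves the synthetic pathway.
* The flat family→term map has no ancestor-closure semantics.
* One-tailed conventions (shift test upper tail; before > after) follow the
  directional claims the pipeline is built to evaluate; two-sided variants
  are provided where meaningful.
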