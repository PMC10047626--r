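---
title: "Phylogenetic multilevel meta-analysis of state-dependent mate choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic multilevel meta-analysis of state-dependent mate choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choosiness)
```

## The scientific question

Animals vary widely in how choosy they are during mating, and sexual
selection theory predicts that part of this variation tracks the chooser's
own *state*: individuals with more resources to invest in reproduction, a
higher residual reproductive value, or no risk of dying unmated should be
able to afford stronger mate choice. `choosiness` implements the full
quantitative pipeline for synthesizing such evidence across studies and
species: effect-size extraction and sign coding, a four-level
phylogenetically controlled random-effects model fitted by REML,
heterogeneity partitioning, categorical moderator meta-regression, and
publication-bias diagnostics — together with a synthetic-data generator
that gives every stage a ground truth to recover.

## Effect sizes and sign coding

The unit of analysis is a correlation `r` between a state factor (age,
attractiveness, body size, condition, mating status, parasite load) and
the strength of mate choice, analyzed on Fisher's Z scale
(`zr = atanh(r)`) with sampling variance `1/(n - 3)`, `n` being the total
number of animals in the test. Four kinds of raw statistics are
convertible:

* reported correlations (used as-is, clamped to ±0.999 if printed as ±1);
* two-group comparisons summarized by means and SDs, converted through the
  bias-corrected standardized mean difference
  `d = J (m1 - m2)/s_pooled`, `J = 1 - 3/(4 df - 1)`, and then
  `r = d / sqrt(d^2 + a)` with the exact unequal-n constant
  `a = (n1 + n2)^2 / (n1 n2)`;
* two-group t or single-df F statistics, converted through the same
  estimator (`d = J t sqrt(1/n1 + 1/n2)`; `t = ±sqrt(F)` with the sign
  taken from the reported direction). Applying `J` on this route keeps the
  test-statistic path algebraically identical to the group-summary path,
  so the two agree to machine precision on the same data;
* 2×2 choice-frequency tables, via the phi coefficient
  `(ad - bc)/sqrt((a+b)(c+d)(a+c)(b+d))`.

Signs are then oriented so that a positive correlation always means
*choosier when young, attractive, large, in good condition, mated, or
carrying few parasites*; raw statistics pointing the other way are flipped
(`code_direction()`).

Two deliberate choices here were genuinely open. First, the d→r constant:
we use the exact `a = (n1+n2)^2/(n1 n2)` rather than the balanced-design
approximation `a = 4`, because unbalanced group sizes are common in field
studies; for balanced designs the two coincide. Second, nonsignificant
results reported *without a direction* ("directionless" records) are coded
`zr = 0` but keep their true `1/(n - 3)` variance — inflating their
variance would double-penalize studies that at least reported a null. The
analysis is run on both the *full* dataset (zeros retained) and a
*reduced* dataset (zeros dropped); the contrast between the two is itself
informative about reporting practices.

## The phylogeny

Correlations from closely related species are not independent. Supertrees
assembled from topology-only sources carry no meaningful branch lengths,
so the tree is calibrated with Grafen's method: each internal node sits at
height (number of descendant tips − 1), the root is scaled to height 1 and
tips to 0, giving an ultrametric depth-1 tree (`grafen_calibrate()`, with
the power parameter at its default of 1). Under Brownian trait evolution
the expected correlation between two species is then exactly the depth of
their most recent common ancestor (`brownian_correlation()`), e.g.

```{r grafen}
tr <- grafen_calibrate(read_species_tree(text = "((A,B),C);"))
brownian_correlation(tr)
```

Polytomies are preserved, never randomly resolved: the (tips − 1) height
rule handles them naturally, and random resolution would inject
irreproducible noise. When an analysis uses a data subset, the tree is
pruned to the species present and *re-calibrated*, so every fit sees a
depth-1 tree and variance components remain comparable across subsets
(`prune_tree(recalibrate = TRUE)`; the alternative of inheriting the full
tree's heights is available via `recalibrate = FALSE`).

## The four-level model

For effects `y_i = zr_i` with sampling variances `v_i`,

```
y = X beta + u_phylo + u_species + u_study + u_obs + e
```

with marginal covariance

```
V = s2_phylo * A  +  s2_species * S  +  s2_study * T  +  s2_obs * I  +  diag(v)
```

where `A` expands the Brownian correlation matrix to effects via the
species mapping, `S` and `T` are same-species and same-study indicators,
and the observation-level component captures residual heterogeneity. The
phylogenetic and species levels share a grouping but carry distinct
variance components — the first absorbs similarity proportional to shared
ancestry, the second species-specific deviations.

Variance components are estimated by REML. Numerical choices that matter:

* the objective is optimized on the **log-variance scale** with analytic
  gradients (`nlminb`), bounded to `exp(-35) .. exp(5)`;
* **five starting points** are used, including a zeros-boundary start, an
  equal split of a crude total-heterogeneity estimate, and
  single-level-dominant starts; the best converged solution wins;
* components pinned below `1e-12` are reported as **exactly zero** —
  boundary estimates are common and meaningful (a negligible level);
* Cholesky factorization is used throughout; if `V` is numerically
  singular a `1e-10` ridge jitter is added once, with a message;
* the reported restricted log-likelihood includes all constants, so it is
  directly comparable to standard meta-analytic software (and is verified
  against an independent implementation in the test suite).

Fixed effects are the GLS solution at the estimated components;
confidence intervals use Wald z critical values (the default of the
standard software in this field; a t-based variant was considered and not
adopted, since the reference analyses report z-type intervals). The mean
correlation is reported as `tanh(beta0)`, back-transforming interval
endpoints likewise. The 95% prediction interval widens the CI by the
summed variance components: `beta0 ± 1.96 sqrt(SE^2 + sum(s2))` — with
`z`, not a t quantile, for the same reason.

## Heterogeneity

`I^2` is the share of variance not attributable to sampling error,
computed against the *typical* sampling variance
`s2_m = (k - 1) Σw / ((Σw)^2 - Σw^2)`, `w_i = 1/v_i`. Each level's share
is `100 s2_level / (Σ s2 + s2_m)`; the components add exactly to the
total, and the partition is reported for the intercept-only fit of the
full dataset.

## Moderators

Each moderator is tested in its own meta-regression (no interactions).
Two companion fits are run (`moderator_analysis()`): an intercept model
that **excludes factor levels with fewer than 10 effects** — guarding the
omnibus QM test against near-empty categories — and a no-intercept model
over *all* levels that estimates each category's mean directly (the
orchard-plot summary). QM is the Wald quadratic form on the non-intercept
coefficients against a chi-square; the moderator's explanatory power is
the marginal `R^2 = Var(X beta) / (Var(X beta) + Σ s2)`, the share of
total (fixed + random) variance explained by the fixed part. Pairwise
level contrasts use Holm-adjusted Wald z tests among the well-sampled
levels.

## Publication bias

Two signatures are tested in a single minus-intercept meta-regression
with the full random structure: a time trend (mean-centered publication
year) and a small-study effect (the standard error `sqrt(v)`), each with
its Wald z. The *adjustment* model differs deliberately: it includes the
intercept and uses mean-centered year plus the sampling **variance** `v`
as covariates; its intercept — the expected effect for an average-year
study of unbounded precision — is the bias-adjusted mean, computed
regardless of whether either test was significant. The minus-intercept
form of the test model is implemented literally as specified by the
method it follows, though it departs from the conventional
intercept-included Egger regression; `bias_test(intercept = TRUE)`
restores the conventional form. Covariates that are constant across
effects are dropped with a warning rather than erroring, which makes the
degenerate single-year/single-n case collapse gracefully onto the plain
fit.

## The synthetic-data generator

`simulation_truth()` + `simulate_dataset()` generate datasets with
exactly the structure the model assumes: species effects drawn jointly
with covariance `s2_phylo A` plus independent `s2_species`, independent
study and observation effects, uniform per-effect sample sizes driving
`v = 1/(n - 3)`, an optional per-year trend, and a censoring process that
converts each *nonsignificant* effect (|zr|/sqrt(v) < 1.96) into a
directionless zero with a given probability — significant effects are
never altered, mirroring how directionless data points arise in the
literature. A single root seed is split into per-stage streams (tree,
species, study, observation, design, sampling error, censoring), so
adding a stage never perturbs earlier draws and identical truths yield
byte-identical outputs. `simulate_raw_payloads()` re-expresses the
simulated effects as the four raw data types (inverting each conversion
exactly, up to integer rounding for frequency tables), which exercises
the whole ingestion path.

The reference design — 40 species, 80 studies × 2 effects (k = 160),
variance components (0.02, 0.01, 0.03, 0.04) for
(phylogeny, species, study, observation), grand mean 0.1 Zr, per-effect n
uniform on 10–100, publication years 1980–2019 — was chosen once to
resemble a realistic mate-choice synthesis: heterogeneity dominating
sampling error, high total I², a small positive mean. What the generator
does *not* emulate: the taxonomic composition of any real dataset,
correlated moderators, non-normal true-effect distributions, or
study-level selection on significance (censoring here is at the effect
level). Passing recovery tests therefore demonstrate correctness of the
estimator under its own assumptions, not robustness to their violation.

## Validation design and problem sizes

The test suite validates each stage against an independent path:
hand-derivable worked examples for every conversion; a dense brute-force
REML implementation (explicit inverses and determinants, gradient-free
simplex optimization) agreeing with the production fitter on 20 random
small fixtures; an external multilevel REML implementation agreeing on
larger fixtures; a 1-D grid search for single-component fits; a
Monte-Carlo check that the empirical variance of `zr` matches
`1/(n - 3)`; parameter recovery over 200 replicates of the reference
design (bias of the grand mean below 0.01 Zr, variance components within
Monte-Carlo error of truth); and QM p-value calibration over 2000 null
replicates of a binary moderator at k = 120 with study + observation
components — the simplest regime for the chi-square reference, since the
Wald QM is visibly anticonservative at small k (about 10% rejection at
k = 48 with 5 degrees of freedom). Fixture sizes are chosen so the whole
suite runs in minutes.

One recovery property fails honestly and is asserted anyway: Wald 95%
confidence intervals for the grand mean cover at only ≈ 0.85 at the
reference design. The cause is structural, not numerical: Grafen
calibration makes shallow splits very recent, so the phylogenetic level
contributes what is effectively a handful of deep-lineage draws; REML
then frequently (and legitimately — the fit matches an independent
implementation to machine precision, including the boundary zeros)
estimates the phylogenetic variance at exactly zero, deflating the
intercept's Wald SE while the realized phylogenetic deviation remains in
the data. This undercoverage is a property of Wald-z intervals with
estimated variance components in phylogenetic meta-analysis generally,
and is worth keeping in mind when reading such intervals in applied
syntheses.

## Known limitations

* Only two-group and correlation-type raw statistics are convertible — no
  odds ratios, survival statistics, or >2-group omnibus tests.
* The model is univariate: one effect-size column, no multivariate
  outcomes, no robust (cluster-sandwich) variance estimators, no
  likelihood-ratio model comparison.
* REML variance components at the boundary (exact zeros) make interval
  coverage for *components* approximate; fixed-effect inference is
  unaffected in the sizes tested.
* Species matching is exact after normalization; no synonym resolution.
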