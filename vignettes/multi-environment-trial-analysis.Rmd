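---
title: "Methods: multi-environment hybrid maize trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment hybrid maize trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizemet)
```

## The problem

Hybrid maize varieties promise large yield gains in the West African
savanna, but a hybrid's performance depends strongly on where it is
grown. A multi-environment trial (MET) therefore evaluates a common set
of genotypes in replicated trials across locations and asks three
questions: how heritable is each trait within a location, which
genotypes differ significantly in yield, and which genotypes combine
high yield with consistency across locations. `maizemet` implements this
pipeline for randomized complete block designs (RCBD), modelled on a
nine-genotype, nine-location, three-replicate hybrid trial in Burkina
Faso whose summary tables ship with the package
(`reported_yield_means()`, `reported_genetic_params()`).

## Yield standardization

Grain yield is not measured directly: each plot yields an ear weight
`PE` (kg) and a harvest grain moisture `H` (%). The conversion to tons
per hectare at a reference moisture `Hr` is

$$\text{yield} = PE \cdot \frac{100-H}{100-H_r} \cdot
  \frac{S \cdot 100}{NPA \cdot 10},$$

with `S` the shelling coefficient (grain fraction of ear weight,
default 0.8) and `NPA` the net harvested plot area in m². The second
factor is a pure unit conversion: 1 kg of grain-equivalent per m² is
10 t/ha, so the formula is dimensionally consistent and is implemented
exactly as written (`grain_yield_t_ha()`). `Hr` defaults to 15%, the
usual commercial standard for maize. **`NPA` has no default**: gross
plot spacing (e.g. 0.80 m × 0.40 m between hills) does not determine
the harvested area, so the value must come from the trial's harvest
protocol. The worked examples use 8 m², a plausible net plot for a
four-row maize plot; with `NPA = 8` and `S = 0.8` the area/shelling
factor is exactly 1, which makes hand-checking convenient.

## Per-location RCBD analysis

For each location and trait the classical RCBD decomposition is
computed from marginal means: `SS_geno = r Σᵢ(ȳᵢ.−ȳ..)²`,
`SS_block = g Σₖ(ȳ.ₖ−ȳ..)²`, `SS_error` by subtraction, F tests of
genotype and block against `MS_error`. Genotypes absent from some
replicate are dropped with a warning by default (strict mode errors
instead), because MET reports treat absent entries as absent, not as
zeros. Degenerate inputs are flagged rather than mangled: zero residual
variance yields an infinite F with p = 0, constant data yields an
all-zero table with F = NaN.

Variance components come from the method of moments:

$$\sigma_g^2 = \frac{MS_g - MS_e}{r},\qquad
  \sigma_e^2 = \frac{MS_e}{r},\qquad
  \sigma_p^2 = \frac{MS_g}{r},$$

so that $\sigma_p^2 = \sigma_g^2 + \sigma_e^2$ holds exactly and
broad-sense heritability is $H^2 = \sigma_g^2/\sigma_p^2 =
1 - MS_e/MS_g$ (an identity the tests assert). A negative
$\hat\sigma_g^2$ (whenever $MS_g < MS_e$) is truncated to zero with an
explicit `negative_truncated` flag — real trial tables contain no
negative components, but simulated data regularly produce them and
silent truncation would bias recovery studies invisibly. GCV and PCV
read "√σ²" as the corresponding standard deviation:
$GCV = 100\,\sigma_g/\bar x$, $PCV = 100\,\sigma_p/\bar x$.

Two reporting choices deserve a note. The per-location report carries
the genotype-effect p-value *and* a true least significant difference
$LSD = t_{1-\alpha/2,\,df_e}\sqrt{2MS_e/r}$ as separate columns: trial
tables sometimes print p-values under an "LSD" heading, and keeping
both quantities explicit avoids that ambiguity. The residual CV is the
standard experimental CV, $100\sqrt{MS_e}/\bar y$; no other published
definition reproduces arbitrary printed CV columns, so the package
reports the standard one only.

## Means separation (SNK)

The Student–Newman–Keuls procedure orders the g genotype means
descending and compares the range of every stretch of p consecutive
ordered means with the critical range
$W_p = q_{\alpha,p,df_e}\sqrt{MS_e/r}$, where $q$ is the upper
studentized range quantile (`stats::qtukey`; for p = 2 it equals
$\sqrt2\,t_{1-\alpha/2}$, an identity the tests check to the quantile
routine's ~1e−7 accuracy). Stretches are examined from the widest
down, level by level, and a stretch found non-significant protects all
its sub-stretches: they are declared non-significant without testing.
The implementation evaluates this protection rule as a downward-closed
dynamic program over stretch sizes; the test-suite contains a literal
level-by-level simulation of the stepwise procedure as an independent
oracle and checks letter-for-letter agreement on randomized cases.

Numerical choices: rejection requires the range to *strictly* exceed
$W_p$, so with `MS_error = 0` tied means share a letter while distinct
means separate — the natural degenerate limit. Letters are attached to
maximal non-significant stretches; a genotype accumulates the letter of
every stretch containing it, which produces the familiar overlapping
displays ("ab", "bc"). Lettering direction is cosmetic and
configurable (`letters_from = "top"` default, `"bottom"` matches
reports that letter upward from the lowest mean).

## Combined analysis and stability

The across-location analysis decomposes into environment, block within
environment, genotype, genotype × environment and pooled error strata,
all F-tested against the pooled error. Because sparse genotype presence
breaks balance, the default `complete_cases` policy restricts the
combined analysis to genotypes fully replicated in every location and
always reports the exclusions; `listwise` refuses unbalanced input
outright.

The stability score is deliberately simple and assumption-free:
within each location genotypes are ranked by mean yield (1 = best,
ties mid-rank); a genotype's score is its mean rank plus the standard
deviation of its ranks over the locations it covers. Low scores mean
both high-performing and consistent. Rank-based scoring uses only
within-location orderings, so it is invariant to adding any constant to
one location's yields, is desk-checkable from a printed yield matrix,
and reproduces the source trial's qualitative conclusions (the
single-cross hybrids SD1, SD4, SD5 score best; the top two locations
are SG and BAM; PD ranks last). AMMI, GGE biplots, Finlay–Wilkinson
regression and Shukla's stability variance are deliberately out of
scope; the rank score is not a substitute for them, it is the method
this package claims. Genotypes covering fewer than `min_coverage`
(default 50%) of locations are excluded from scoring — with two of nine
locations, a rank SD is close to meaningless. Location means are
computed genotype-mean-first (unweighted by plot count), which is how a
printed means matrix reproduces a printed location-mean row.

## The synthetic trial generator

Because the source trial's plot-level data are not deposited, every
estimator is validated by parameter recovery on simulated trials. The
generator draws each trait from the additive normal linear model

$$y_{ijk} = \mu + g_i + e_j + (ge)_{ij} + b_{k(j)} +
\varepsilon_{ijk},$$

with independent zero-mean effects at configured variances. Normality
is a stand-in — the estimators are moment-based and the source analysis
states no distributional model — and that is exactly what the recovery
tests demonstrate: unbiasedness of moment estimators under a correctly
specified additive model, not robustness to field realities such as
spatial trend, non-normal error, or missing plots within a block.

Default conditions emulate the source trial: 9 genotypes × 9
environments × 3 replicates; yield grand mean 5.5 t/ha (mid-range of
the reported location means, 2.29–7.06); genotypic variance 2.5 and
plot residual 0.8 (t/ha)², inside the reported per-location component
range; environment variance 2.0 (matching the dispersion of the
reported location means); interaction variance 0.5 > 0 so G×E tests
are non-trivial by default; block variance 0.1 (blocks exist but are
small, as usual in well-managed stations). Harvest moisture is drawn as
N(18, 1.5²)% — a realistic few points above the 15% standard. Yield is
generated *indirectly*: the latent plot yield from the linear model
(clamped at zero in the rare negative tail) is converted to an ear
weight at the drawn moisture by inverting the standardization formula,
and the dataset's yield column is then filled by `derive_yields()`, so
simulation exercises the same code path as real data.

For a single location the genotypic signal includes the interaction,
so the expected value of the per-location heritability estimator is

$$H^2_{\exp} = \frac{r(\sigma_G^2+\sigma_{GE}^2)}
{\sigma_\varepsilon^2 + r(\sigma_G^2+\sigma_{GE}^2)},$$

which the generator stores with the realized effect vectors for
recovery tests. At $\sigma_G^2 = 2.5$, $\sigma_{GE}^2 = 0$,
$\sigma_\varepsilon^2 = 0.8$, $r = 3$ this is 7.5/8.3 ≈ 0.904, the
"heritability above 0.80" regime the source trial reports. The mean
recovered $\hat H^2$ sits ≈ 0.03 below $H^2_{\exp}$ at g = 9 — the
familiar small-sample bias of a ratio of mean squares, which the tests
show shrinking as g grows.

Determinism: one call to `set.seed(config$seed)` precedes a fixed draw
order (per trait: genotype, environment, interaction, block, residual
effects; then moisture), so a configuration maps to a bit-identical
dataset. Per-environment splittable streams were considered and
rejected: the package never regenerates single environments in
isolation, and a single documented draw order is easier to audit.

## Problem sizes in the test-suite

The suite validates against brute-force oracles on designs up to 5
genotypes × 3 blocks and 5 means (where enumeration is exact), and runs
Monte-Carlo checks at 500 trials for heritability recovery, 200 trials
for interaction-test type-I error and power, 200 replicates per
genotype count for the bias study, and 60 trials per replication level
for the precision study — sizes at which the binomial/Monte-Carlo error
is comfortably below the asserted tolerances. The entire suite runs in
well under a minute.

## Known limitations

- Unequal replication within a location is handled by dropping, not by
  recovering inter-block information; no REML/mixed models.
- The SNK procedure requires the common replicate count of the balanced
  subset; unequal-r extensions (harmonic-mean r) are not offered.
- The combined analysis needs a common replicate count across
  locations.
- The stability score ignores yield *magnitude* differences beyond
  rank; two genotypes separated by a hair can differ by a full rank.
- The generator does not simulate spatial field trend, non-normal
  errors, or within-block missingness.
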