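# maizemet

Analysis pipeline for multi-environment hybrid maize yield trials laid
out as randomized complete block designs (RCBD): grain-yield
standardization, per-location ANOVA with moment-based genetic
parameters, Student–Newman–Keuls means separation, combined
genotype-by-environment analysis, and rank-based genotype stability and
environment classification. It is written for plant breeders and
agronomists running replicated multi-location trials, and ships both
the published summary tables of a nine-genotype, nine-location hybrid
trial in Burkina Faso and a synthetic trial generator with known
variance components so every estimator is testable by parameter
recovery.

## The statistics at the core

* **Yield standardization.** Plot ear weight `PE` (kg) at harvest
  moisture `H` (%) becomes grain yield at reference moisture `Hr`
  (15%): `yield [t/ha] = PE · (100−H)/(100−Hr) · S·100/(NPA·10)`,
  with shelling coefficient `S` (0.8) and net plot area `NPA` (m²).
* **Per-location RCBD ANOVA** (g genotypes, r blocks) and
  method-of-moments components: `σg² = (MSg−MSe)/r`, `σe² = MSe/r`,
  `σp² = MSg/r`, broad-sense heritability `H² = σg²/σp²`, and
  `GCV/PCV = 100·σg/x̄, 100·σp/x̄`.
* **SNK multiple range test**: ordered means, critical ranges
  `W_p = q(α, p, df_e)·√(MSe/r)` from the studentized range, widest
  stretches first with the protection rule, compact letter display.
* **Combined G×E ANOVA** (environment, block-within-environment,
  genotype, G×E, pooled error) on the complete-case genotype set.
* **Stability score** per genotype: mean within-location rank plus
  rank standard deviation (lower = better: high-performing *and*
  consistent).

See `vignettes/multi-environment-trial-analysis.Rmd` for the full
account of the model, defaults and design choices.

## Worked example

```r
library(maizemet)

# the published genotype x environment yield means, as a dataset
d <- reported_yield_means_dataset()
rank_environments(d)
#>   environment n_genotypes mean_yield rank
#> 1          SG           8   7.059625    1
#> 2         BAM           8   6.544000    2
#> 3        NEB1           8   5.635750    3
#> 4         DAK           8   5.361750    4
#> 5        NEB2           8   5.208125    5
#> 6         YEN           8   5.007375    6
#> 7          TM           8   4.923625    7
#> 8          FN           8   4.715500    8
#> 9          PD           8   2.293625    9
```

The two best locations are SG (Soungalodaga) and BAM (Bama); PD
(Poundou) ranks last — the trial's environment classification, read
straight off the column means. Stability over the same matrix:

```r
stability_ranking(d)$genotypes[1:3, ]
#>   genotype n_environments mean_yield mean_rank  rank_sd stability_score
#> 1      SD1              9   7.041667  1.444444 1.013794        2.458238
#> 2      SD5              9   5.857667  3.444444 1.509231        4.953675
#> 3      SD4              9   5.776667  3.555556 1.589899        5.145454
```

SD1 wins or nearly wins everywhere (mean rank 1.44, rank SD 1.01); the
single-cross hybrids SD1, SD4, SD5 head the ranking. And on a simulated
trial with known truth:

```r
sim <- simulate_met(simulation_config(seed = 42))
tab <- anova_rcbd(sim$dataset, "E1", "grain_yield_t_ha")
vc  <- variance_components(tab)
heritability(vc$sigma_g2, vc$sigma_p2)
#> [1] 0.9217934
sim$true_params$grain_yield_t_ha$h2_exp
#> [1] 0.9183673
```

the per-location heritability estimate recovers its expected value.

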