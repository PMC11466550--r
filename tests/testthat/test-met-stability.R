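test_that("combined decomposition is additive and matches aov", {
  sim <- simulate_met(simulation_config(n_genotypes = 4,
                                        n_environments = 3, seed = 17))
  ca <- combined_anova(sim$dataset)
  expect_equal(sum(ca$ss[1:5]), ca$ss[6], tolerance = 1e-9)
  expect_equal(sum(ca$df[1:5]), ca$df[6])
  expect_equal(ca$df[6], 4 * 3 * 3 - 1)

  # independent route through stats::aov
  obs <- sim$dataset$observations
  fit <- summary(stats::aov(
    grain_yield_t_ha ~ environment + environment:replicate + genotype +
      environment:genotype, data = obs))[[1]]
  rn <- trimws(rownames(fit))
  expect_equal(ca$ss[ca$source == "environment"],
               fit[rn == "environment", "Sum Sq"], tolerance = 1e-9)
  expect_equal(ca$ss[ca$source == "genotype"],
               fit[rn == "genotype", "Sum Sq"], tolerance = 1e-9)
  expect_equal(ca$ss[ca$source == "genotype_x_environment"],
               fit[rn == "environment:genotype", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(ca$ss[ca$source == "block_within_env"],
               fit[rn == "environment:replicate", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(ca$ss[ca$source == "error"],
               fit[rn == "Residuals", "Sum Sq"], tolerance = 1e-9)
})

test_that("purely additive data has zero interaction sum of squares", {
  zn <- make_fixture("zero_noise")
  ca <- combined_anova(zn)
  expect_equal(ca$ss[ca$source == "genotype_x_environment"], 0,
               tolerance = 1e-16)
  expect_equal(ca$ss[ca$source == "error"], 0, tolerance = 1e-16)
})

test_that("single environment reduces to the per-environment analysis", {
  sim <- simulate_met(simulation_config(n_environments = 1, seed = 31))
  ca <- combined_anova(sim$dataset)
  pa <- anova_rcbd(sim$dataset, "E1", "grain_yield_t_ha")
  expect_equal(ca$ss[ca$source == "environment"], 0, tolerance = 1e-16)
  expect_equal(ca$df[ca$source == "genotype_x_environment"], 0)
  expect_equal(ca$ss[ca$source == "genotype"],
               pa$ss[pa$source == "genotype"], tolerance = 1e-9)
  expect_equal(ca$ss[ca$source == "block_within_env"],
               pa$ss[pa$source == "block"], tolerance = 1e-9)
  expect_equal(ca$ss[ca$source == "error"],
               pa$ss[pa$source == "error"], tolerance = 1e-9)
})

test_that("genotype policies handle sparse presence", {
  sparse <- make_fixture("sparse_like_reported")
  ca <- combined_anova(sparse)
  expect_setequal(attr(ca, "excluded_genotypes"),
                  c("SD7", "SD8", "SD9"))
  expect_equal(attr(ca, "g"), 6)
  expect_equal(attr(ca, "e"), 9)
  expect_error(combined_anova(sparse, genotype_policy = "listwise"),
               class = "maizemet_integrity_error")
})

test_that("interaction test has power at the configured signal", {
  specs <- list(grain_yield_t_ha = list(mean = 5.5, var_g = 2.5,
                                        var_e = 2.0, var_ge = 1.0,
                                        var_b = 0.1, var_eps = 0.8))
  reject <- vapply(1:200, function(i) {
    cfg <- simulation_config(trait_specs = specs, seed = 40000 + i)
    ca <- combined_anova(simulate_met(cfg)$dataset)
    ca$p[ca$source == "genotype_x_environment"] < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.9)
})

test_that("environment ranking reproduces the published column means", {
  d <- reported_yield_means_dataset()
  rk <- rank_environments(d)
  expect_equal(round(rk$mean_yield[rk$environment == "SG"], 2), 7.06)
  expect_equal(round(rk$mean_yield[rk$environment == "PD"], 2), 2.29)
  expect_equal(rk$rank[rk$environment == "PD"], 9)  # lowest yields
  expect_lte(rk$rank[rk$environment == "SG"], 2)
  expect_true(rk$rank[rk$environment == "BAM"] <= 2)

  # relabelling environments permutes ranks identically
  d2 <- d
  map <- setNames(paste0("X", 1:9), unique(d$observations$environment))
  d2$observations$environment <- map[d2$observations$environment]
  d2$environments$name <- map[d2$environments$name]
  rk2 <- rank_environments(d2)
  expect_equal(rk2$rank[match(map[rk$environment], rk2$environment)],
               rk$rank)
})

test_that("tied environments get mid-ranks", {
  obs <- expand.grid(replicate = "R1", genotype = c("G1", "G2"),
                     environment = c("E1", "E2", "E3"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  obs$grain_yield_t_ha <- rep(c(4, 6), 3)
  d <- trial_dataset(obs, plot_config = plot_config(npa_m2 = 8))
  rk <- rank_environments(d)
  expect_equal(rk$rank, rep(2, 3))
})

test_that("stability scoring favours high, consistent genotypes", {
  # a genotype that wins everywhere has mean rank 1, SD 0, minimal score
  sim <- simulate_met(simulation_config(n_genotypes = 5,
                                        n_environments = 6, seed = 13))
  d <- sim$dataset
  best <- d$observations$genotype == "G1"
  d$observations$grain_yield_t_ha[best] <-
    d$observations$grain_yield_t_ha[best] + 50
  st <- stability_ranking(d)
  g1 <- st$genotypes[st$genotypes$genotype == "G1", ]
  expect_equal(g1$mean_rank, 1)
  expect_equal(g1$rank_sd, 0)
  expect_equal(st$genotypes$genotype[1], "G1")

  # within-environment ranks are a permutation of 1..n_present
  for (env in unique(st$ranks$environment)) {
    r <- sort(st$ranks$rank[st$ranks$environment == env])
    expect_equal(r, seq_along(r))
  }
})

test_that("published means rank SD1 as more stable than SD7", {
  d <- reported_yield_means_dataset()
  st <- suppressWarnings(stability_ranking(d))
  expect_true("SD8" %in% st$excluded)  # 2 of 9 environments < 50%
  gt <- st$genotypes
  expect_equal(round(gt$mean_yield[gt$genotype == "SD1"], 2), 7.04)
  expect_lt(gt$stability_score[gt$genotype == "SD1"],
            gt$stability_score[gt$genotype == "SD7"])
  # the single-cross hybrids reported as most stable score in the top half
  expect_true(all(match(c("SD1", "SD4", "SD5"), gt$genotype) <= 4))
})

test_that("stability is invariant to a constant shift in one environment", {
  d <- make_fixture("sparse_like_reported")
  st <- suppressWarnings(stability_ranking(d))
  d2 <- d
  in_bam <- d2$observations$environment == "BAM"
  d2$observations$grain_yield_t_ha[in_bam] <-
    d2$observations$grain_yield_t_ha[in_bam] + 3
  st2 <- suppressWarnings(stability_ranking(d2))
  expect_equal(st2$genotypes$stability_score,
               st$genotypes$stability_score)
  expect_equal(st2$genotypes$genotype, st$genotypes$genotype)
})
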