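test_that("ANOVA matches the explicit marginal-mean oracle and aov", {
  tiny <- make_fixture("tiny_balanced")
  for (env in c("E1", "E2")) {
    tab <- anova_rcbd(tiny, env, "grain_yield_t_ha")
    sub <- tiny$observations[tiny$observations$environment == env, ]
    ora <- oracle_rcbd(sub, "grain_yield_t_ha")
    expect_equal(tab$ss[tab$source == "genotype"], ora$ss_geno,
                 tolerance = 1e-12)
    expect_equal(tab$ss[tab$source == "block"], ora$ss_block,
                 tolerance = 1e-12)
    expect_equal(tab$ss[tab$source == "error"], ora$ss_error,
                 tolerance = 1e-12)
    expect_equal(attr(tab, "grand_mean"), ora$grand_mean)

    # independent route: stats::aov on the same model
    fit <- summary(stats::aov(grain_yield_t_ha ~ genotype + replicate,
                              data = sub))[[1]]
    expect_equal(tab$ss[tab$source == "genotype"],
                 fit["genotype", "Sum Sq"], tolerance = 1e-10)
    expect_equal(tab$ss[tab$source == "error"],
                 fit["Residuals", "Sum Sq"], tolerance = 1e-10)
    expect_equal(tab$p[tab$source == "genotype"],
                 fit["genotype", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("ANOVA equals the oracle on random small designs", {
  set.seed(42)
  for (case in 1:20) {
    g <- sample(2:5, 1)
    r <- sample(2:3, 1)
    df <- random_rcbd_df(g, r)
    d <- as_dataset(df)
    tab <- anova_rcbd(d, "E1", "grain_yield_t_ha")
    ora <- oracle_rcbd(df, "grain_yield_t_ha")
    for (src in c("genotype", "block", "error", "total")) {
      expect_equal(tab$ss[tab$source == src],
                   ora[[paste0("ss_", sub("genotype", "geno", src))]],
                   tolerance = 1e-10)
    }
    # SS and df additivity
    expect_equal(sum(tab$ss[1:3]), tab$ss[4], tolerance = 1e-9)
    expect_equal(sum(tab$df[1:3]), tab$df[4])
    expect_equal(tab$df[4], g * r - 1)
  }
})

test_that("label permutations move only the matching stratum", {
  set.seed(7)
  df <- random_rcbd_df(4, 3)
  base <- anova_rcbd(as_dataset(df), "E1", "grain_yield_t_ha")

  perm_rep <- df
  perm_rep$replicate <- c(R1 = "R3", R2 = "R1",
                          R3 = "R2")[perm_rep$replicate]
  tab_r <- anova_rcbd(as_dataset(perm_rep), "E1", "grain_yield_t_ha")
  expect_equal(tab_r$ss[tab_r$source == "genotype"],
               base$ss[base$source == "genotype"], tolerance = 1e-12)
  expect_equal(tab_r$ss[tab_r$source == "block"],
               base$ss[base$source == "block"], tolerance = 1e-12)

  perm_gen <- df
  perm_gen$genotype <- c(G1 = "G4", G2 = "G1", G3 = "G2",
                         G4 = "G3")[perm_gen$genotype]
  tab_g <- anova_rcbd(as_dataset(perm_gen), "E1", "grain_yield_t_ha")
  expect_equal(tab_g$ss[tab_g$source == "block"],
               base$ss[base$source == "block"], tolerance = 1e-12)
  expect_equal(tab_g$ss[tab_g$source == "genotype"],
               base$ss[base$source == "genotype"], tolerance = 1e-12)
})

test_that("degenerate inputs are flagged, not mangled", {
  # constant data: every sum of squares is zero
  df <- random_rcbd_df(3, 3)
  df$grain_yield_t_ha <- 4
  tab <- anova_rcbd(as_dataset(df), "E1", "grain_yield_t_ha")
  expect_equal(tab$ss, rep(0, 4), tolerance = 1e-18)
  expect_true(is.nan(tab$f[tab$source == "genotype"]))

  # genotype signal only: error and block SS vanish, F is infinite
  zn <- make_fixture("zero_noise")
  env <- unique(zn$observations$environment)[1]
  tabz <- anova_rcbd(zn, env, "grain_yield_t_ha")
  expect_equal(tabz$ss[tabz$source == "error"], 0, tolerance = 1e-18)
  expect_true(is.infinite(tabz$f[tabz$source == "genotype"]))
  expect_equal(tabz$p[tabz$source == "genotype"], 0)
})

test_that("incomplete genotypes are dropped or rejected per policy", {
  df <- random_rcbd_df(4, 3)
  df <- df[!(df$genotype == "G4" & df$replicate == "R3"), ]
  d <- as_dataset(df)
  expect_warning(tab <- anova_rcbd(d, "E1", "grain_yield_t_ha"), "G4")
  expect_equal(attr(tab, "dropped_genotypes"), "G4")
  expect_equal(attr(tab, "g"), 3)
  expect_error(anova_rcbd(d, "E1", "grain_yield_t_ha",
                          drop_incomplete = FALSE),
               class = "maizemet_integrity_error")

  # fewer than 2 complete genotypes is unrecoverable
  df2 <- random_rcbd_df(2, 3)
  df2 <- df2[!(df2$genotype == "G2" & df2$replicate == "R3"), ]
  expect_error(
    suppressWarnings(anova_rcbd(as_dataset(df2), "E1",
                                "grain_yield_t_ha")),
    class = "maizemet_insufficient_data")

  expect_error(anova_rcbd(d, "E9", "grain_yield_t_ha"),
               class = "maizemet_lookup_error")
})

test_that("residual CV is the error SD as a percent of the mean", {
  df <- random_rcbd_df(4, 3)
  d <- as_dataset(df)
  tab <- anova_rcbd(d, "E1", "grain_yield_t_ha")
  ms_e <- tab$ms[tab$source == "error"]
  expect_equal(residual_cv(tab),
               100 * sqrt(ms_e) / attr(tab, "grand_mean"))

  # dimensionless: scaling all plot values leaves the CV unchanged
  df2 <- df
  df2$grain_yield_t_ha <- 3.7 * df2$grain_yield_t_ha
  tab2 <- anova_rcbd(as_dataset(df2), "E1", "grain_yield_t_ha")
  expect_equal(residual_cv(tab2), residual_cv(tab), tolerance = 1e-10)

  # hand arithmetic: MS_e 0.25, mean 5 -> 10%
  fake <- tab
  fake$ms[fake$source == "error"] <- 0.25
  attr(fake, "grand_mean") <- 5
  expect_equal(residual_cv(fake), 10)
})
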