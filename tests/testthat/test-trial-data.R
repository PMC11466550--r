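cfg <- plot_config(npa_m2 = 8)

make_obs <- function() {
  obs <- expand.grid(replicate = c("R1", "R2"),
                     genotype = c("G1", "G2", "G3"),
                     environment = c("E1", "E2"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  obs <- obs[, c("environment", "genotype", "replicate")]
  obs$ear_weight_kg <- seq(1, 2.1, by = 0.1)
  obs$grain_moisture_pct <- rep(c(17.25, 18.5), 6)
  obs$plant_height_m <- 2 + seq_len(12) / 10
  obs
}

test_that("trial CSV round-trips exactly, including missing cells", {
  obs <- make_obs()
  obs$plant_height_m[5] <- NA  # absent trait value, not zero
  d <- trial_dataset(obs, plot_config = cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(d, path)
  d2 <- read_trial_csv(path, cfg)
  expect_equal(d2$observations[names(obs)], d$observations[names(obs)],
               tolerance = 1e-12)
  expect_true(is.na(d2$observations$plant_height_m[5]))

  # zero-observation dataset round-trips as a header-only file
  empty <- trial_dataset(obs[0, ], plot_config = cfg)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(empty, path2)
  expect_length(readLines(path2), 1)
  expect_warning(d3 <- read_trial_csv(path2, cfg), "no observations")
  expect_equal(nrow(d3$observations), 0)
})

test_that("reading validates structure with precise error messages", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("environment,genotype,plant_height_m", "E1,G1,2.5"), path)
  expect_error(read_trial_csv(path, cfg), "replicate",
               class = "maizemet_format_error")

  writeLines(c("environment,genotype,replicate,plant_height_m",
               "E1,G1,R1,2.5", "E1,G2,R1,tall"), path)
  expect_error(read_trial_csv(path, cfg), "row\\(s\\) 2",
               class = "maizemet_parse_error")

  writeLines(c("environment,genotype,replicate,plant_height_m",
               "NEB1,SD1,rep1,2.5", "NEB1,SD1,rep1,2.6"), path)
  expect_error(read_trial_csv(path, cfg), "NEB1, SD1, rep1",
               class = "maizemet_integrity_error")

  # comma decimal separators are accepted on input
  writeLines(c("environment,genotype,replicate,grain_yield_t_ha",
               'E1,G1,R1,"6,992"', "E1,G2,R1,5.344"), path)
  d <- read_trial_csv(path, cfg)
  expect_equal(d$observations$grain_yield_t_ha, c(6.992, 5.344))

  # unknown trait columns survive with a warning
  writeLines(c("environment,genotype,replicate,tassel_count",
               "E1,G1,R1,4"), path)
  expect_warning(d <- read_trial_csv(path, cfg), "tassel_count")
  expect_true("tassel_count" %in% names(d$observations))

  # out-of-range moisture is rejected
  writeLines(c("environment,genotype,replicate,grain_moisture_pct",
               "E1,G1,R1,120"), path)
  expect_error(read_trial_csv(path, cfg),
               class = "maizemet_domain_error")
})

test_that("supplied registries are validated and joined", {
  path <- withr::local_tempfile(fileext = ".csv")
  gpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("environment,genotype,replicate,grain_yield_t_ha",
               paste0("BAM,SD", 1:9, ",R1,", 1:9)), path)
  file.copy(system.file("extdata", "genotypes.csv",
                        package = "maizemet"), gpath)
  d <- read_trial_csv(path, cfg, genotypes_path = gpath)
  sd8 <- d$genotypes[d$genotypes$code == "SD8", ]
  expect_equal(sd8$designation, "BONDOFA")
  expect_equal(sd8$material_class, "national_hybrid")

  # an observation whose genotype is missing from the registry fails
  writeLines(c("environment,genotype,replicate,grain_yield_t_ha",
               "BAM,SD99,R1,5"), path)
  expect_error(read_trial_csv(path, cfg, genotypes_path = gpath),
               "SD99", class = "maizemet_integrity_error")
})

test_that("validate_dataset reports balance and absences, purely", {
  obs <- make_obs()
  obs <- obs[!(obs$genotype == "G3" & obs$environment == "E2"), ]
  obs <- obs[!(obs$genotype == "G2" & obs$environment == "E1" &
                 obs$replicate == "R2"), ]
  d <- trial_dataset(obs, plot_config = cfg)
  before <- d
  rep <- validate_dataset(d)
  expect_identical(d, before)

  expect_false(rep$balance[["E1"]])   # G2 has 1 of 2 replicates
  expect_true(rep$balance[["E2"]])    # all present genotypes complete
  bad <- rep$per_environment[!rep$per_environment$complete, ]
  expect_equal(bad$environment, "E1")
  expect_equal(bad$genotype, "G2")
  expect_true(any(rep$absent$environment == "E2" &
                    rep$absent$genotype == "G3"))
})

test_that("subset_by_environment partitions and is idempotent", {
  d <- make_fixture("sparse_like_reported")
  envs <- unique(d$observations$environment)
  sub <- subset_by_environment(d, "BAM")
  expect_setequal(unique(sub$observations$environment), "BAM")
  expect_equal(nrow(sub$observations),
               sum(d$observations$environment == "BAM"))
  expect_false("SD9" %in% sub$genotypes$code)  # registry filtered

  sub2 <- subset_by_environment(sub, "BAM")
  expect_equal(sub2$observations, sub$observations)

  # union over subsets reproduces the full observation multiset
  parts <- lapply(envs, function(e) {
    subset_by_environment(d, e)$observations
  })
  whole <- do.call(rbind, parts)
  key <- function(x) do.call(paste, x[c("environment", "genotype",
                                        "replicate")])
  expect_setequal(key(whole), key(d$observations))
  expect_equal(nrow(whole), nrow(d$observations))

  expect_error(subset_by_environment(d, "NOWHERE"),
               class = "maizemet_lookup_error")
})
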