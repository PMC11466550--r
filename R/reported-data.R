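#' Published genotype-by-environment yield means
#'
#' The reported mean grain yields (t/ha at 15% moisture) of nine hybrid
#' maize genotypes across nine Burkina Faso locations, with the published
#' means-separation letters, in long format. Absent cells (genotypes not
#' grown at a location) are simply absent rows: SD8 appears only at BAM
#' and DAK, SD7 is missing from DAK and SD9 from BAM.
#'
#' @return Data frame with columns `environment`, `genotype`,
#'   `yield_t_ha`, `letters`.
#' @export
reported_yield_means <- function() {
  utils::read.csv(system.file("extdata", "reported_yield_means.csv",
                              package = "maizemet"),
                  stringsAsFactors = FALSE)
}

#' Published yield means as a trial dataset
#'
#' Wraps [reported_yield_means()] in a [trial_dataset()] (one pseudo
#' replicate per cell, trait `grain_yield_t_ha`) so the ranking and
#' stability operations can run directly on the published means. Means of
#' replicated plots, not raw plots, so it supports only means-level
#' analyses (environment ranking, stability), not ANOVA.
#'
#' @return A [trial_dataset()].
#' @export
reported_yield_means_dataset <- function() {
  means <- reported_yield_means()
  obs <- data.frame(environment = means$environment,
                    genotype = means$genotype,
                    replicate = "mean",
                    grain_yield_t_ha = means$yield_t_ha,
                    stringsAsFactors = FALSE)
  trial_dataset(obs, genotypes = hybrid_registry(),
                environments = environment_registry(),
                plot_config = plot_config(npa_m2 = 8))
}

#' Published per-location genetic parameters for grain yield
#'
#' The reported genotypic variance, phenotypic variance, broad-sense
#' heritability and location mean for grain yield at each of the nine
#' locations, as printed (2-decimal rounding).
#'
#' @return Data frame with columns `environment`, `sigma_g2`, `sigma_p2`,
#'   `heritability`, `mean_yield`.
#' @export
reported_genetic_params <- function() {
  utils::read.csv(system.file("extdata",
                              "reported_yield_genetic_params.csv",
                              package = "maizemet"),
                  stringsAsFactors = FALSE)
}

#' Genotype registry of the evaluated hybrids
#'
#' Codes SD1..SD9 with commercial designation, material class (single
#' cross, double cross, national hybrid or composite) and origin.
#'
#' @return Data frame with columns `code`, `designation`,
#'   `material_class`, `origin`.
#' @export
hybrid_registry <- function() {
  utils::read.csv(system.file("extdata", "genotypes.csv",
                              package = "maizemet"),
                  stringsAsFactors = FALSE)
}

#' Environment registry of the trial locations
#'
#' Location codes and full names for the nine trial environments.
#'
#' @return Data frame with columns `name`, `full_name`.
#' @export
environment_registry <- function() {
  utils::read.csv(system.file("extdata", "environments.csv",
                              package = "maizemet"),
                  stringsAsFactors = FALSE)
}
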