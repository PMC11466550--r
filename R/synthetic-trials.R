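default_trait_specs <- function() {
  list(
    grain_yield_t_ha = list(mean = 5.5, var_g = 2.5, var_e = 2.0,
                            var_ge = 0.5, var_b = 0.1, var_eps = 0.8),
    plant_height_m = list(mean = 2.4, var_g = 0.03, var_e = 0.02,
                          var_ge = 0.005, var_b = 0.001, var_eps = 0.01),
    rows_per_ear = list(mean = 14, var_g = 1.5, var_e = 0.3,
                        var_ge = 0.2, var_b = 0.05, var_eps = 0.5)
  )
}

#' Configuration for the synthetic multi-environment trial generator
#'
#' Defines an RCBD multi-environment trial with known variance
#' components. Each trait follows the additive linear model
#' \deqn{y_{ijk} = \mu + g_i + e_j + (ge)_{ij} + b_{k(j)} +
#'   \varepsilon_{ijk}}
#' with independent zero-mean normal effects at the configured variances.
#' The defaults emulate a 9-genotype x 9-environment x 3-replicate hybrid
#' maize trial with yield variance components in the range reported from
#' West African multi-location trials (genotypic variance 2.5, plot
#' residual 0.8 (t/ha)^2) and a non-zero G x E component so interaction
#' tests are non-trivial by default.
#'
#' @param n_genotypes,n_environments Number of genotypes / environments
#'   (>= 2); defaults 9 and 9.
#' @param n_replicates Blocks per environment (>= 2); default 3.
#' @param trait_specs Named list; each element is a list with `mean`,
#'   `var_g`, `var_e`, `var_ge`, `var_b`, `var_eps` (all variances >= 0).
#'   Traits named in the canonical vocabulary are emitted under those
#'   column names; `grain_yield_t_ha` is realized indirectly through ear
#'   weight and moisture (see [simulate_met()]).
#' @param missing_pattern Optional data frame (environment, genotype) of
#'   cells to drop entirely, emulating sparse genotype presence.
#' @param seed Integer seed; fixes the full output deterministically.
#' @param moisture_mean,moisture_sd Harvest grain moisture model
#'   (percent); defaults 18 and 1.5.
#' @param genotype_labels,environment_labels Optional label vectors;
#'   defaults G1..Gn and E1..En.
#' @param plot_config A [plot_config()]; default NPA 8 m2, Hr 15%,
#'   shelling 0.8 (with these values the area/shelling factor is exactly
#'   1, so latent yield in t/ha equals moisture-adjusted ear weight in
#'   kg/plot).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genotypes = 9, n_environments = 9,
                              n_replicates = 3,
                              trait_specs = default_trait_specs(),
                              missing_pattern = NULL, seed = 1,
                              moisture_mean = 18, moisture_sd = 1.5,
                              genotype_labels = NULL,
                              environment_labels = NULL,
                              plot_config = maizemet::plot_config(
                                npa_m2 = 8)) {
  if (n_genotypes < 2 || n_environments < 1 || n_replicates < 2) {
    abort_mm("need >= 2 genotypes, >= 1 environment, >= 2 replicates",
             "config_error")
  }
  if (length(trait_specs) == 0 || is.null(names(trait_specs))) {
    abort_mm("trait_specs must be a named list", "config_error")
  }
  for (tn in names(trait_specs)) {
    sp <- trait_specs[[tn]]
    need <- c("mean", "var_g", "var_e", "var_ge", "var_b", "var_eps")
    if (!all(need %in% names(sp))) {
      abort_mm(sprintf("trait spec `%s` missing fields: %s", tn,
                       paste(setdiff(need, names(sp)), collapse = ", ")),
               "config_error")
    }
    vars <- unlist(sp[need[-1]])
    if (any(!is.finite(vars)) || any(vars < 0)) {
      abort_mm(sprintf("trait spec `%s` has a negative or non-finite variance",
                       tn), "config_error")
    }
  }
  if (is.null(genotype_labels)) {
    genotype_labels <- sprintf("G%d", seq_len(n_genotypes))
  }
  if (is.null(environment_labels)) {
    environment_labels <- sprintf("E%d", seq_len(n_environments))
  }
  stopifnot(length(genotype_labels) == n_genotypes,
            length(environment_labels) == n_environments)
  if (!is.null(missing_pattern)) {
    missing_pattern <- as.data.frame(missing_pattern,
                                     stringsAsFactors = FALSE)
    if (!all(c("environment", "genotype") %in% names(missing_pattern))) {
      abort_mm("missing_pattern needs columns environment, genotype",
               "config_error")
    }
    bad_e <- setdiff(missing_pattern$environment, environment_labels)
    bad_g <- setdiff(missing_pattern$genotype, genotype_labels)
    if (length(bad_e) > 0 || length(bad_g) > 0) {
      abort_mm(sprintf("missing_pattern references unknown label(s): %s",
                       paste(c(bad_e, bad_g), collapse = ", ")),
               "config_error")
    }
  }
  if (moisture_sd < 0 || moisture_mean < 0 || moisture_mean >= 100) {
    abort_mm("invalid moisture model", "config_error")
  }
  structure(list(n_genotypes = n_genotypes,
                 n_environments = n_environments,
                 n_replicates = n_replicates, trait_specs = trait_specs,
                 missing_pattern = missing_pattern, seed = as.integer(seed),
                 moisture_mean = moisture_mean, moisture_sd = moisture_sd,
                 genotype_labels = genotype_labels,
                 environment_labels = environment_labels,
                 plot_config = plot_config),
            class = "simulation_config")
}

#' Simulate a multi-environment RCBD trial with known parameters
#'
#' Draws every trait from the additive normal linear model of
#' [simulation_config()]. Grain yield is generated indirectly to exercise
#' the yield-standardization path end to end: a latent target yield is
#' drawn from the linear model (negative draws clamped to zero), harvest
#' moisture is drawn independently, ear weight is back-solved through the
#' standardization formula, and the dataset's `grain_yield_t_ha` column is
#' then filled by [derive_yields()]. Identical configuration (including
#' seed) gives an identical dataset.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (a [trial_dataset()]) and `true_params`:
#'   per trait the realized effect vectors (`g`, `e`, `ge`, `b`), the
#'   configured variances, and `h2_exp`, the expected value of the
#'   per-environment broad-sense heritability estimator,
#'   \eqn{r(\sigma^2_G + \sigma^2_{GE}) /
#'        (\sigma^2_\varepsilon + r(\sigma^2_G + \sigma^2_{GE}))}
#'   (within one environment the genotypic signal includes the
#'   interaction).
#' @export
simulate_met <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ng <- config$n_genotypes
  ne <- config$n_environments
  r <- config$n_replicates
  gl <- config$genotype_labels
  el <- config$environment_labels
  grid <- expand.grid(replicate = sprintf("R%d", seq_len(r)),
                      genotype = gl, environment = el,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("environment", "genotype", "replicate")]
  gi <- match(grid$genotype, gl)
  ej <- match(grid$environment, el)
  rk <- match(grid$replicate, sprintf("R%d", seq_len(r)))

  set.seed(config$seed)
  true_params <- list()
  values <- list()
  for (tn in names(config$trait_specs)) {
    sp <- config$trait_specs[[tn]]
    g_eff <- stats::rnorm(ng, 0, sqrt(sp$var_g))
    e_eff <- stats::rnorm(ne, 0, sqrt(sp$var_e))
    ge_eff <- matrix(stats::rnorm(ng * ne, 0, sqrt(sp$var_ge)), ng, ne)
    b_eff <- matrix(stats::rnorm(ne * r, 0, sqrt(sp$var_b)), ne, r)
    eps <- stats::rnorm(nrow(grid), 0, sqrt(sp$var_eps))
    y <- sp$mean + g_eff[gi] + e_eff[ej] + ge_eff[cbind(gi, ej)] +
      b_eff[cbind(ej, rk)] + eps
    values[[tn]] <- y
    sig_within <- sp$var_g + sp$var_ge
    true_params[[tn]] <- list(
      g = g_eff, e = e_eff, ge = ge_eff, b = b_eff,
      variances = sp,
      h2_exp = if (sp$var_eps + r * sig_within > 0) {
        r * sig_within / (sp$var_eps + r * sig_within)
      } else NA_real_)
  }
  moisture <- stats::rnorm(nrow(grid), config$moisture_mean,
                           config$moisture_sd)
  moisture <- pmin(pmax(moisture, 1), 99)

  obs <- grid
  cfg <- config$plot_config
  for (tn in names(values)) {
    if (tn == "grain_yield_t_ha") {
      latent <- pmax(values[[tn]], 0)
      # invert the standardization formula: PE such that derived yield
      # equals the latent target at the drawn moisture
      obs$ear_weight_kg <- latent * (100 - cfg$hr_pct) /
        (100 - moisture) * (cfg$npa_m2 * 10) / (cfg$shelling * 100)
      obs$grain_moisture_pct <- moisture
    } else {
      v <- values[[tn]]
      if (tn %in% COUNT_TRAITS) v <- pmax(v, 0)
      obs[[tn]] <- v
    }
  }
  if (!is.null(config$missing_pattern)) {
    mp <- config$missing_pattern
    drop_key <- paste(mp$environment, mp$genotype, sep = "\r")
    obs_key <- paste(obs$environment, obs$genotype, sep = "\r")
    obs <- obs[!obs_key %in% drop_key, , drop = FALSE]
  }
  dataset <- trial_dataset(obs, plot_config = cfg)
  if ("grain_yield_t_ha" %in% names(config$trait_specs)) {
    dataset <- derive_yields(dataset)
  }
  list(dataset = dataset,
       true_params = structure(true_params, config = config))
}

#' Deterministic built-in fixtures
#'
#' Small datasets used throughout the test-suite and the examples:
#' \describe{
#'   \item{tiny_balanced}{3 genotypes x 2 environments x 2 replicates
#'     with hand-set yields (12 observations), small enough to check the
#'     ANOVA against explicit marginal-mean arithmetic.}
#'   \item{sparse_like_reported}{A simulated 9 x 9 x 3 trial using the
#'     genotype codes SD1..SD9 and the nine location codes of the Burkina
#'     Faso hybrid trial, with the reported sparse presence pattern: SD8
#'     observed only at BAM and DAK, SD7 absent from DAK, SD9 absent from
#'     BAM.}
#'   \item{zero_noise}{4 genotypes x 2 environments x 3 replicates with
#'     genotype effects only (every other variance zero), so downstream
#'     error and block sums of squares vanish and heritability is 1.}
#' }
#'
#' @param name One of `"tiny_balanced"`, `"sparse_like_reported"`,
#'   `"zero_noise"`.
#' @return A [trial_dataset()].
#' @export
make_fixture <- function(name) {
  switch(
    name,
    tiny_balanced = {
      obs <- expand.grid(replicate = c("R1", "R2"),
                         genotype = c("G1", "G2", "G3"),
                         environment = c("E1", "E2"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      obs <- obs[, c("environment", "genotype", "replicate")]
      obs$grain_yield_t_ha <- c(
        5.1, 5.3, 6.0, 6.4, 4.2, 4.0,   # E1: G1, G2, G3
        6.5, 6.1, 7.2, 7.0, 5.0, 5.4)   # E2
      trial_dataset(obs, plot_config = plot_config(npa_m2 = 8))
    },
    sparse_like_reported = {
      env_codes <- c("NEB1", "NEB2", "TM", "BAM", "SG", "FN", "DAK",
                     "YEN", "PD")
      missing <- rbind(
        data.frame(environment = setdiff(env_codes, c("BAM", "DAK")),
                   genotype = "SD8"),
        data.frame(environment = "DAK", genotype = "SD7"),
        data.frame(environment = "BAM", genotype = "SD9"))
      cfg <- simulation_config(
        n_genotypes = 9, n_environments = 9, n_replicates = 3,
        genotype_labels = sprintf("SD%d", 1:9),
        environment_labels = env_codes,
        missing_pattern = missing, seed = 20181L)
      simulate_met(cfg)$dataset
    },
    zero_noise = {
      specs <- list(grain_yield_t_ha = list(
        mean = 5, var_g = 2.5, var_e = 0, var_ge = 0, var_b = 0,
        var_eps = 0))
      cfg <- simulation_config(n_genotypes = 4, n_environments = 2,
                               n_replicates = 3, trait_specs = specs,
                               moisture_sd = 0, seed = 7L)
      simulate_met(cfg)$dataset
    },
    abort_mm(sprintf("unknown fixture: %s", name), "lookup_error"))
}
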