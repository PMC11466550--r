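#' Moment-based variance components from an RCBD ANOVA
#'
#' Method-of-moments estimates from the genotype and error mean squares of
#' a single-environment RCBD with r replicates:
#' \deqn{\sigma_g^2 = (MS_g - MS_e)/r, \quad \sigma_e^2 = MS_e/r, \quad
#'       \sigma_p^2 = MS_g/r}
#' so that \eqn{\sigma_p^2 = \sigma_g^2 + \sigma_e^2} exactly. A negative
#' genotypic component (possible whenever \eqn{MS_g < MS_e}) is truncated
#' at zero and flagged, never silently.
#'
#' @param table An [anova_rcbd()] result (or any list-like with elements
#'   reachable as `ms` for genotype/error and attribute `r`).
#' @return List with `sigma_g2`, `sigma_e2`, `sigma_p2`,
#'   `negative_truncated`.
#' @export
variance_components <- function(table) {
  stopifnot(inherits(table, "rcbd_anova"))
  r <- attr(table, "r")
  if (is.null(r) || r <= 0) abort_mm("invalid replicate count",
                                     "domain_error")
  ms_g <- table$ms[table$source == "genotype"]
  ms_e <- table$ms[table$source == "error"]
  sigma_g2 <- (ms_g - ms_e) / r
  truncated <- sigma_g2 < 0
  if (truncated) sigma_g2 <- 0
  list(sigma_g2 = sigma_g2, sigma_e2 = ms_e / r, sigma_p2 = ms_g / r,
       negative_truncated = truncated)
}

#' Broad-sense heritability
#'
#' \eqn{H^2 = \sigma_g^2 / \sigma_p^2}: the fraction of phenotypic variance
#' attributable to total genotypic variance.
#'
#' @param sigma_g2 Genotypic variance (>= 0).
#' @param sigma_p2 Phenotypic variance.
#' @return H-squared in \[0, 1\]; `NA` (with a warning) when
#'   `sigma_p2 == 0`.
#' @examples
#' heritability(2.10, 2.50)  # 0.84
#' @export
heritability <- function(sigma_g2, sigma_p2) {
  if (any(sigma_g2 < 0) || any(sigma_p2 < 0)) {
    abort_mm("variances must be non-negative", "domain_error")
  }
  if (any(sigma_g2 > sigma_p2 + 1e-12)) {
    abort_mm("genotypic variance exceeds phenotypic variance",
             "domain_error")
  }
  out <- ifelse(sigma_p2 > 0, sigma_g2 / sigma_p2, NA_real_)
  if (any(is.na(out) & sigma_p2 == 0)) {
    warning("heritability undefined where phenotypic variance is zero",
            call. = FALSE)
  }
  out
}

#' Genotypic and phenotypic coefficients of variation
#'
#' GCV and PCV express the genotypic and phenotypic standard deviations as
#' percentages of the trait mean:
#' \eqn{GCV = 100\sqrt{\sigma_g^2}/\bar{x}},
#' \eqn{PCV = 100\sqrt{\sigma_p^2}/\bar{x}}.
#'
#' @param sigma_g2,sigma_p2 Variance components (>= 0).
#' @param mean Trait mean (> 0).
#' @return List with `gcv_pct` and `pcv_pct`; `pcv_pct >= gcv_pct`.
#' @export
gcv_pcv <- function(sigma_g2, sigma_p2, mean) {
  if (any(mean <= 0)) abort_mm("mean must be > 0 for a CV",
                               "domain_error")
  if (any(sigma_g2 < 0) || any(sigma_p2 < 0)) {
    abort_mm("variances must be non-negative", "domain_error")
  }
  list(gcv_pct = 100 * sqrt(sigma_g2) / mean,
       pcv_pct = 100 * sqrt(sigma_p2) / mean)
}

#' Genetic parameter report across environments and traits
#'
#' Runs the per-environment RCBD analysis for every environment x trait
#' combination and assembles the moment-based genetic parameters: trait
#' mean, variance components, broad-sense heritability, GCV/PCV, the
#' genotype-effect p-value, the residual CV and the least significant
#' difference. Environments that fail (too few genotypes, no data for the
#' trait) are recorded in the `failures` attribute, not fatal.
#'
#' @param dataset A [trial_dataset()]; run [derive_yields()] first if the
#'   yield trait is requested.
#' @param traits Character vector of trait columns; defaults to every
#'   canonical trait present in the data.
#' @param alpha Level for the LSD column, default 0.05.
#' @return Data frame, one row per environment x trait, of class
#'   `genetic_report`.
#' @export
genetic_report <- function(dataset, traits = NULL, alpha = 0.05) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (is.null(traits)) {
    traits <- intersect(TRAIT_VOCAB, names(dataset$observations))
  }
  envs <- sort(unique(dataset$observations$environment))
  rows <- list()
  failures <- data.frame(environment = character(), trait = character(),
                         message = character())
  for (env in envs) {
    for (tr in traits) {
      res <- tryCatch({
        tab <- suppressWarnings(
          anova_rcbd(dataset, env, tr, alpha = alpha))
        vc <- variance_components(tab)
        h2 <- suppressWarnings(heritability(vc$sigma_g2, vc$sigma_p2))
        m <- attr(tab, "grand_mean")
        cvs <- if (m > 0) gcv_pcv(vc$sigma_g2, vc$sigma_p2, m) else
          list(gcv_pct = NA_real_, pcv_pct = NA_real_)
        data.frame(
          environment = env, trait = tr, mean = m,
          sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
          sigma_p2 = vc$sigma_p2, heritability = h2,
          gcv_pct = cvs$gcv_pct, pcv_pct = cvs$pcv_pct,
          p_genotype = tab$p[tab$source == "genotype"],
          cv_pct = residual_cv(tab), lsd = attr(tab, "lsd"),
          negative_truncated = vc$negative_truncated)
      }, maizemet_error = function(e) e)
      if (inherits(res, "maizemet_error")) {
        failures <- rbind(failures, data.frame(
          environment = env, trait = tr, message = conditionMessage(res)))
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(environment = character(), trait = character())
  rownames(out) <- NULL
  structure(out, class = c("genetic_report", "data.frame"),
            failures = failures, alpha = alpha)
}
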