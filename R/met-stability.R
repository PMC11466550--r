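#' Combined genotype-by-environment ANOVA
#'
#' Two-factor-with-blocks decomposition across environments for one trait:
#' environment (df e-1), block within environment (e(r-1)), genotype
#' (g-1), genotype x environment ((g-1)(e-1)) and pooled error
#' (e(g-1)(r-1)), all F-tested against the pooled error mean square. The
#' analysis runs on the balanced complete-case subset: under the default
#' `complete_cases` policy, genotypes not fully replicated in every
#' included environment are excluded (and reported); under `listwise` any
#' imbalance is an error.
#'
#' @param dataset A [trial_dataset()].
#' @param trait Trait column, default `grain_yield_t_ha`.
#' @param genotype_policy `"complete_cases"` (default) or `"listwise"`.
#' @return A `combined_anova` data frame (source, df, ss, ms, f, p) with
#'   attributes `g`, `e`, `r`, `grand_mean`, `excluded_genotypes`,
#'   `excluded_environments`.
#' @export
combined_anova <- function(dataset, trait = "grain_yield_t_ha",
                           genotype_policy = c("complete_cases",
                                               "listwise")) {
  genotype_policy <- match.arg(genotype_policy)
  stopifnot(inherits(dataset, "trial_dataset"))
  obs <- dataset$observations
  if (!trait %in% names(obs)) {
    abort_mm(sprintf("trait `%s` not present", trait), "format_error")
  }
  obs <- obs[!is.na(obs[[trait]]), , drop = FALSE]
  envs <- sort(unique(obs$environment))
  excluded_envs <- character(0)
  per_env_complete <- list()
  per_env_r <- integer(0)
  for (env in envs) {
    sub <- obs[obs$environment == env, ]
    reps <- unique(sub$replicate)
    counts <- table(factor(sub$genotype),
                    factor(sub$replicate, levels = reps))
    per_env_complete[[env]] <- rownames(counts)[apply(counts == 1, 1,
                                                      all)]
    per_env_r[env] <- length(reps)
  }
  keep_envs <- envs[lengths(per_env_complete[envs]) >= 2]
  excluded_envs <- setdiff(envs, keep_envs)
  if (length(keep_envs) < 1) {
    abort_mm("no environment with >= 2 fully replicated genotypes",
             "insufficient_data")
  }
  r <- unique(per_env_r[keep_envs])
  if (length(r) != 1) {
    abort_mm(sprintf(
      "replicate count differs between environments (%s); a common r is required",
      paste(sprintf("%s: %d", keep_envs, per_env_r[keep_envs]),
            collapse = ", ")), "insufficient_data")
  }
  common <- Reduce(intersect, per_env_complete[keep_envs])
  all_genos <- sort(unique(obs$genotype))
  excluded_genos <- setdiff(all_genos, common)
  if (length(common) < 2) {
    abort_mm(sprintf(
      "fewer than 2 genotypes present in every environment; bottleneck genotype(s): %s",
      paste(excluded_genos, collapse = ", ")), "insufficient_data")
  }
  if (genotype_policy == "listwise" && length(excluded_genos) > 0) {
    abort_mm(sprintf(
      "listwise policy: genotype(s) %s are not complete in every environment",
      paste(excluded_genos, collapse = ", ")), "integrity_error")
  }
  sub <- obs[obs$environment %in% keep_envs & obs$genotype %in% common, ]
  y <- sub[[trait]]
  g <- length(common)
  e <- length(keep_envs)
  grand <- mean(y)
  env_means <- tapply(y, sub$environment, mean)
  geno_means <- tapply(y, sub$genotype, mean)
  cell_means <- tapply(y, list(sub$genotype, sub$environment), mean)
  envblock_means <- tapply(y, list(sub$environment, sub$replicate), mean)

  ss_total <- sum((y - grand)^2)
  ss_env <- g * r * sum((env_means - grand)^2)
  ss_geno <- e * r * sum((geno_means - grand)^2)
  ss_ge <- r * sum((sweep(sweep(cell_means, 1, geno_means),
                          2, env_means) + grand)^2)
  ss_block <- g * sum((sweep(envblock_means, 1,
                             env_means[rownames(envblock_means)]))^2)
  ss_error <- ss_total - ss_env - ss_geno - ss_ge - ss_block
  if (ss_error < 0 && ss_error > -1e-9 * max(ss_total, 1)) ss_error <- 0

  df <- c(environment = e - 1, block = e * (r - 1), genotype = g - 1,
          gxe = (g - 1) * (e - 1), error = e * (g - 1) * (r - 1),
          total = g * e * r - 1)
  ss <- c(ss_env, ss_block, ss_geno, ss_ge, ss_error, ss_total)
  ms <- ifelse(df[1:5] > 0, ss[1:5] / df[1:5], NA_real_)
  ms_error <- ms[5]
  f <- rep(NA_real_, 6)
  p <- rep(NA_real_, 6)
  for (k in 1:4) {
    if (is.na(ms[k]) || df[k] == 0) next
    f[k] <- if (!is.na(ms_error) && ms_error > 0) ms[k] / ms_error else
      ifelse(ms[k] > 0, Inf, NaN)
    p[k] <- if (is.finite(f[k])) {
      stats::pf(f[k], df[k], df[5], lower.tail = FALSE)
    } else if (is.infinite(f[k])) 0 else NA_real_
  }
  tab <- data.frame(
    source = c("environment", "block_within_env", "genotype",
               "genotype_x_environment", "error", "total"),
    df = unname(df), ss = ss, ms = c(ms, NA_real_), f = f, p = p)
  structure(tab, class = c("combined_anova", "data.frame"),
            g = g, e = e, r = r, grand_mean = grand,
            excluded_genotypes = excluded_genos,
            excluded_environments = excluded_envs,
            environments = keep_envs, genotypes = sort(common))
}

# genotype-mean-then-environment-mean yield table, long format
env_genotype_means <- function(dataset, trait) {
  obs <- dataset$observations
  if (!trait %in% names(obs)) {
    abort_mm(sprintf("trait `%s` not present", trait), "format_error")
  }
  obs <- obs[!is.na(obs[[trait]]), , drop = FALSE]
  if (nrow(obs) == 0) abort_mm("no non-missing values for trait",
                               "insufficient_data")
  agg <- stats::aggregate(obs[[trait]],
                          by = list(environment = obs$environment,
                                    genotype = obs$genotype),
                          FUN = mean)
  names(agg)[3] <- "mean_yield"
  agg
}

#' Rank environments by mean yield
#'
#' The environment mean is the unweighted mean of the per-genotype mean
#' yields of the genotypes present in that environment (so sparse
#' genotype presence does not weight environments unevenly by plot
#' count). Environments are ranked descending; ties get mid-ranks.
#'
#' @param dataset A [trial_dataset()] with yields present (run
#'   [derive_yields()] first if needed).
#' @param trait Trait column, default `grain_yield_t_ha`.
#' @return Data frame (environment, n_genotypes, mean_yield, rank),
#'   sorted by rank.
#' @export
rank_environments <- function(dataset, trait = "grain_yield_t_ha") {
  stopifnot(inherits(dataset, "trial_dataset"))
  all_envs <- unique(dataset$observations$environment)
  cells <- env_genotype_means(dataset, trait)
  skipped <- setdiff(all_envs, unique(cells$environment))
  if (length(skipped) > 0) {
    warning(sprintf("environment(s) without yields excluded: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  means <- tapply(cells$mean_yield, cells$environment, mean)
  out <- data.frame(environment = names(means),
                    n_genotypes = as.integer(
                      table(cells$environment)[names(means)]),
                    mean_yield = as.numeric(means))
  out$rank <- rank(-out$mean_yield, ties.method = "average")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}

#' Rank-based genotype stability across environments
#'
#' Within each environment genotypes are ranked by mean yield (1 = best,
#' ties mid-rank). For each genotype the report gives its coverage, its
#' overall mean yield (mean of its per-environment means), its mean rank
#' and rank standard deviation across the environments it covers, and a
#' stability score = mean rank + rank SD. Low scores identify genotypes
#' that are both high-performing and consistent. The score is
#' deliberately assumption-free: it uses only within-environment
#' orderings, so it is invariant to adding any constant to all yields of
#' a single environment.
#'
#' @param dataset A [trial_dataset()] with yields present.
#' @param trait Trait column, default `grain_yield_t_ha`.
#' @param min_coverage Minimum fraction of environments a genotype must
#'   appear in to be scored (default 0.5); genotypes below it are
#'   excluded with a warning.
#' @return A `stability_report` list: `genotypes` (data frame sorted by
#'   score), `environments` (the [rank_environments()] table) and `ranks`
#'   (long per-cell data frame with within-environment ranks).
#' @export
stability_ranking <- function(dataset, trait = "grain_yield_t_ha",
                              min_coverage = 0.5) {
  stopifnot(inherits(dataset, "trial_dataset"))
  cells <- env_genotype_means(dataset, trait)
  n_env <- length(unique(cells$environment))
  cells$rank <- stats::ave(-cells$mean_yield, cells$environment,
                           FUN = function(v) rank(v,
                                                  ties.method = "average"))
  coverage <- table(cells$genotype) / n_env
  low <- names(coverage)[coverage < min_coverage]
  if (length(low) > 0) {
    warning(sprintf(
      "genotype(s) below %.0f%% environment coverage excluded: %s",
      100 * min_coverage, paste(low, collapse = ", ")), call. = FALSE)
    cells_kept <- cells[!cells$genotype %in% low, , drop = FALSE]
  } else {
    cells_kept <- cells
  }
  covered <- table(cells_kept$genotype)
  if (all(covered < 2)) {
    abort_mm("every genotype covers fewer than 2 environments",
             "insufficient_data")
  }
  genos <- names(covered)
  rows <- lapply(genos, function(gn) {
    sub <- cells_kept[cells_kept$genotype == gn, ]
    rank_sd <- if (nrow(sub) > 1) stats::sd(sub$rank) else 0
    data.frame(genotype = gn, n_environments = nrow(sub),
               mean_yield = mean(sub$mean_yield),
               mean_rank = mean(sub$rank), rank_sd = rank_sd,
               stability_score = mean(sub$rank) + rank_sd)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$stability_score, tab$mean_rank), ]
  rownames(tab) <- NULL
  structure(list(genotypes = tab,
                 environments = suppressWarnings(
                   rank_environments(dataset, trait)),
                 ranks = cells, excluded = low,
                 min_coverage = min_coverage),
            class = "stability_report")
}

#' @export
print.combined_anova <- function(x, ...) {
  cat(sprintf(
    "Combined G x E ANOVA (g = %d, e = %d, r = %d, mean = %.4g)\n",
    attr(x, "g"), attr(x, "e"), attr(x, "r"), attr(x, "grand_mean")))
  disp <- as.data.frame(x)
  disp$p <- format_p(disp$p)
  print(disp, row.names = FALSE, digits = 5)
  if (length(attr(x, "excluded_genotypes")) > 0) {
    cat("excluded genotypes (incomplete coverage):",
        paste(attr(x, "excluded_genotypes"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Genotype stability (score = mean rank + rank SD; lower = better)\n")
  print(x$genotypes, row.names = FALSE, digits = 4)
  cat("\nEnvironment ranking by mean yield\n")
  print(x$environments, row.names = FALSE, digits = 4)
  invisible(x)
}
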