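#' Randomized-complete-block ANOVA for one trait in one environment
#'
#' Classical moment decomposition for an RCBD with g genotypes and r
#' blocks (replicates): genotype and block sums of squares from marginal
#' means, the error sum of squares by subtraction from the total, mean
#' squares as SS/df, and F tests of genotype and block against the error
#' mean square. Blocks are treated as a fixed effect; only `MS_geno` and
#' `MS_error` feed the downstream genetic parameters, so that choice does
#' not affect heritability.
#'
#' Genotypes not observed in every replicate of the environment are, by
#' default, dropped with a warning (trial reports routinely omit absent
#' entries rather than impute them); `drop_incomplete = FALSE` errors
#' instead.
#'
#' @param dataset A [trial_dataset()].
#' @param environment_id Environment to analyse.
#' @param trait Trait column name.
#' @param drop_incomplete Drop genotypes with missing replicates (default
#'   `TRUE`); if `FALSE`, unbalanced data is an error.
#' @param alpha Level used for the least significant difference column,
#'   default 0.05.
#' @return An `rcbd_anova` object: a data frame with rows genotype, block,
#'   error, total and columns `df`, `ss`, `ms`, `f`, `p`; attributes `g`,
#'   `r`, `grand_mean`, `environment`, `trait`, `dropped_genotypes` and
#'   `lsd` (\eqn{t_{1-\alpha/2, df_e} \sqrt{2 MS_e / r}}).
#' @export
anova_rcbd <- function(dataset, environment_id, trait,
                       drop_incomplete = TRUE, alpha = 0.05) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!environment_id %in% unique(dataset$observations$environment)) {
    abort_mm(sprintf("unknown environment: %s", environment_id),
             "lookup_error")
  }
  obs <- dataset$observations
  sub <- obs[obs$environment == environment_id, , drop = FALSE]
  if (!trait %in% names(sub)) {
    abort_mm(sprintf("trait `%s` not present", trait), "format_error")
  }
  sub <- sub[!is.na(sub[[trait]]), , drop = FALSE]
  reps <- sort(unique(sub$replicate))
  r <- length(reps)
  if (r < 2) abort_mm("need at least 2 replicates", "insufficient_data")
  counts <- table(factor(sub$genotype),
                  factor(sub$replicate, levels = reps))
  complete <- rownames(counts)[apply(counts == 1, 1, all)]
  dropped <- setdiff(rownames(counts), complete)
  if (length(dropped) > 0) {
    if (!drop_incomplete) {
      abort_mm(sprintf(
        "unbalanced data for trait `%s` in %s: genotype(s) %s not in all replicates",
        trait, environment_id, paste(dropped, collapse = ", ")),
        "integrity_error")
    }
    warning(sprintf("dropping incomplete genotype(s) in %s: %s",
                    environment_id, paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  sub <- sub[sub$genotype %in% complete, , drop = FALSE]
  g <- length(complete)
  if (g < 2) {
    abort_mm("fewer than 2 genotypes with complete replication",
             "insufficient_data")
  }
  y <- sub[[trait]]
  grand <- mean(y)
  geno_means <- tapply(y, sub$genotype, mean)
  block_means <- tapply(y, sub$replicate, mean)
  ss_total <- sum((y - grand)^2)
  ss_geno <- r * sum((geno_means - grand)^2)
  ss_block <- g * sum((block_means - grand)^2)
  ss_error <- ss_total - ss_geno - ss_block
  if (ss_error < 0 && ss_error > -1e-9 * max(ss_total, 1)) ss_error <- 0
  df_geno <- g - 1
  df_block <- r - 1
  df_error <- (g - 1) * (r - 1)
  ms_geno <- ss_geno / df_geno
  ms_block <- ss_block / df_block
  ms_error <- ss_error / df_error
  f_geno <- if (ms_error > 0) ms_geno / ms_error else
    ifelse(ms_geno > 0, Inf, NaN)
  f_block <- if (ms_error > 0) ms_block / ms_error else
    ifelse(ms_block > 0, Inf, NaN)
  p_geno <- if (is.finite(f_geno)) {
    stats::pf(f_geno, df_geno, df_error, lower.tail = FALSE)
  } else if (is.infinite(f_geno)) 0 else NA_real_
  p_block <- if (is.finite(f_block)) {
    stats::pf(f_block, df_block, df_error, lower.tail = FALSE)
  } else if (is.infinite(f_block)) 0 else NA_real_
  tab <- data.frame(
    source = c("genotype", "block", "error", "total"),
    df = c(df_geno, df_block, df_error, g * r - 1),
    ss = c(ss_geno, ss_block, ss_error, ss_total),
    ms = c(ms_geno, ms_block, ms_error, NA_real_),
    f = c(f_geno, f_block, NA_real_, NA_real_),
    p = c(p_geno, p_block, NA_real_, NA_real_))
  structure(tab, class = c("rcbd_anova", "data.frame"),
            g = g, r = r, grand_mean = grand,
            environment = environment_id, trait = trait,
            dropped_genotypes = dropped,
            genotype_means = geno_means,
            lsd = stats::qt(1 - alpha / 2, df_error) *
              sqrt(2 * ms_error / r))
}

#' Residual coefficient of variation of an RCBD analysis
#'
#' The standard experimental CV: \eqn{100 \sqrt{MS_e} / \bar{y}}.
#'
#' @param table An [anova_rcbd()] result.
#' @return CV in percent.
#' @export
residual_cv <- function(table) {
  stopifnot(inherits(table, "rcbd_anova"))
  grand <- attr(table, "grand_mean")
  if (grand == 0) abort_mm("grand mean is zero; CV undefined",
                           "domain_error")
  100 * sqrt(table$ms[table$source == "error"]) / grand
}

format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-4, "<0.0001", formatC(p, digits = 4,
                                             format = "f")))
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat(sprintf("RCBD ANOVA: %s, trait %s (g = %d, r = %d, mean = %.4g)\n",
              attr(x, "environment"), attr(x, "trait"),
              attr(x, "g"), attr(x, "r"), attr(x, "grand_mean")))
  disp <- as.data.frame(x)
  disp$p <- format_p(disp$p)
  print(disp, row.names = FALSE, digits = 5)
  if (length(attr(x, "dropped_genotypes")) > 0) {
    cat("dropped (incomplete):",
        paste(attr(x, "dropped_genotypes"), collapse = ", "), "\n")
  }
  invisible(x)
}
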