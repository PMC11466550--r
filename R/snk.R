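#' Upper quantile of the studentized range distribution
#'
#' Thin validated wrapper over [stats::qtukey()], the critical value
#' needed by the stepwise multiple range procedure. For a stretch of two
#' means it reduces to the t distribution:
#' \eqn{q(\alpha, 2, df) = \sqrt{2}\, t_{1-\alpha/2, df}}.
#'
#' @param alpha Significance level in (0, 1).
#' @param p Stretch size (number of ordered means spanned), >= 2.
#' @param df Error degrees of freedom, >= 1.
#' @return The upper-alpha quantile of the studentized range.
#' @export
studentized_range_quantile <- function(alpha, p, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_mm("alpha must be in (0, 1)", "domain_error")
  }
  if (p < 2) abort_mm("stretch size p must be >= 2", "domain_error")
  if (df < 1) abort_mm("df must be >= 1", "domain_error")
  stats::qtukey(1 - alpha, nmeans = p, df = df)
}

# Protected significance map for the stepwise range procedure.
# nonsig[i, j] (i <= j, indices into means sorted descending) is TRUE when
# the stretch i..j is declared non-significant: either its own range fails
# to exceed the critical range for its stretch size, or it is contained in
# a larger stretch already declared non-significant (the protection rule).
# Computed top-down over decreasing stretch size, so containment
# propagates inward. Rejection requires range strictly above the critical
# value, so a zero error variance with tied means keeps ties together.
snk_nonsig_map <- function(means_sorted, w) {
  g <- length(means_sorted)
  nonsig <- diag(g) > 0
  if (g < 2) return(nonsig)
  for (p in g:2) {
    for (i in seq_len(g - p + 1)) {
      j <- i + p - 1
      protected <- (i > 1 && nonsig[i - 1, j]) ||
        (j < g && nonsig[i, j + 1])
      nonsig[i, j] <- protected ||
        (means_sorted[i] - means_sorted[j] <= w[p])
    }
  }
  nonsig
}

# Maximal non-significant stretches -> compact letter display.
letters_from_map <- function(nonsig, letters_from) {
  g <- nrow(nonsig)
  stretches <- list()
  for (i in seq_len(g)) {
    for (j in i:g) {
      if (nonsig[i, j] &&
          !(i > 1 && nonsig[i - 1, j]) &&
          !(j < g && nonsig[i, j + 1])) {
        stretches[[length(stretches) + 1]] <- c(i, j)
      }
    }
  }
  starts <- vapply(stretches, `[`, numeric(1), 1)
  ord <- if (letters_from == "top") order(starts) else
    order(-vapply(stretches, `[`, numeric(1), 2))
  stretches <- stretches[ord]
  lab <- character(g)
  for (s in seq_along(stretches)) {
    idx <- stretches[[s]][1]:stretches[[s]][2]
    lab[idx] <- paste0(lab[idx], letters[((s - 1) %% 26) + 1])
  }
  # letters within a set kept in alphabetical order for readability
  vapply(strsplit(lab, ""), function(ch) paste(sort(ch), collapse = ""),
         character(1))
}

#' Student-Newman-Keuls means separation with compact letters
#'
#' The classical stepwise multiple range test: genotype means are sorted
#' (descending), the range of every stretch of p consecutive ordered means
#' is compared against the critical range
#' \eqn{W_p = q(\alpha, p, df_e)\sqrt{MS_e / r}}, stretches are examined
#' from the widest down, and any stretch found non-significant protects
#' all its sub-stretches (they are declared non-significant untested).
#' Letters are attached to the maximal non-significant stretches; two
#' means share a letter exactly when the procedure failed to separate
#' them.
#'
#' @param means Named numeric vector of genotype means.
#' @param ms_error Error mean square from the RCBD analysis (>= 0).
#' @param df_error Error degrees of freedom.
#' @param r Number of replicates behind each mean.
#' @param alpha Significance level, default 0.05.
#' @param letters_from `"top"` (default) letters the highest mean "a";
#'   `"bottom"` letters upward from the lowest mean. The choice is purely
#'   cosmetic.
#' @return An `snk_grouping` data frame (genotype, mean, letters, sorted
#'   by descending mean) with attributes `alpha`, `ms_error`, `df_error`,
#'   `r` and `critical_ranges` (named vector W_p, p = 2..g).
#' @export
snk_grouping <- function(means, ms_error, df_error, r, alpha = 0.05,
                         letters_from = c("top", "bottom")) {
  letters_from <- match.arg(letters_from)
  if (length(means) < 2) abort_mm("need at least 2 means",
                                  "insufficient_data")
  if (is.null(names(means)) || any(names(means) == "")) {
    abort_mm("`means` must be a named vector", "format_error")
  }
  if (ms_error < 0) abort_mm("ms_error must be >= 0", "domain_error")
  if (r < 2) abort_mm("r must be >= 2", "domain_error")
  if (df_error < 1) abort_mm("df_error must be >= 1", "domain_error")
  g <- length(means)
  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]
  w <- c(NA_real_, vapply(2:g, function(p) {
    if (ms_error == 0) 0 else
      studentized_range_quantile(alpha, p, df_error) * sqrt(ms_error / r)
  }, numeric(1)))
  nonsig <- snk_nonsig_map(unname(ms), w)
  lab <- letters_from_map(nonsig, letters_from)
  out <- data.frame(genotype = names(ms), mean = unname(ms),
                    letters = lab, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("snk_grouping", "data.frame"),
            alpha = alpha, ms_error = ms_error, df_error = df_error,
            r = r, critical_ranges = stats::setNames(w[-1], 2:g))
}

#' SNK grouping straight from an RCBD analysis
#'
#' Convenience wrapper extracting the genotype means, error mean square
#' and degrees of freedom from an [anova_rcbd()] result.
#'
#' @param table An [anova_rcbd()] result.
#' @inheritParams snk_grouping
#' @return An `snk_grouping` data frame; see [snk_grouping()].
#' @export
snk_from_anova <- function(table, alpha = 0.05,
                           letters_from = c("top", "bottom")) {
  stopifnot(inherits(table, "rcbd_anova"))
  snk_grouping(attr(table, "genotype_means"),
               ms_error = table$ms[table$source == "error"],
               df_error = table$df[table$source == "error"],
               r = attr(table, "r"), alpha = alpha,
               letters_from = letters_from)
}

#' @export
print.snk_grouping <- function(x, ...) {
  cat(sprintf("SNK means separation (alpha = %g, MS_e = %.4g, df_e = %d)\n",
              attr(x, "alpha"), attr(x, "ms_error"),
              attr(x, "df_error")))
  print(as.data.frame(x), row.names = FALSE, digits = 5)
  invisible(x)
}
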