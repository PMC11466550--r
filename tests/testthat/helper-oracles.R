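# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized code paths on small inputs.

# RCBD ANOVA by explicit double loops over cell and marginal means.
oracle_rcbd <- function(env_df, trait) {
  genos <- sort(unique(env_df$genotype))
  reps <- sort(unique(env_df$replicate))
  g <- length(genos)
  r <- length(reps)
  y <- matrix(NA_real_, g, r, dimnames = list(genos, reps))
  for (i in seq_len(nrow(env_df))) {
    y[env_df$genotype[i], env_df$replicate[i]] <- env_df[[trait]][i]
  }
  stopifnot(!anyNA(y))
  grand <- 0
  for (i in 1:g) for (k in 1:r) grand <- grand + y[i, k]
  grand <- grand / (g * r)
  ss_total <- 0
  for (i in 1:g) for (k in 1:r) ss_total <- ss_total + (y[i, k] - grand)^2
  ss_geno <- 0
  for (i in 1:g) {
    mi <- 0
    for (k in 1:r) mi <- mi + y[i, k]
    ss_geno <- ss_geno + r * (mi / r - grand)^2
  }
  ss_block <- 0
  for (k in 1:r) {
    mk <- 0
    for (i in 1:g) mk <- mk + y[i, k]
    ss_block <- ss_block + g * (mk / g - grand)^2
  }
  list(g = g, r = r, grand_mean = grand, ss_total = ss_total,
       ss_geno = ss_geno, ss_block = ss_block,
       ss_error = ss_total - ss_geno - ss_block)
}

# Stepwise multiple range test simulated literally: stretches are examined
# level by level from the widest down; a stretch is tested only if it was
# spawned by a significant parent and is not contained in any stretch
# already declared non-significant (the protection rule). Letters come
# from a left-to-right sweep over maximal homogeneous stretches.
# Structurally independent of the DP in the package.
oracle_snk_letters <- function(means, ms_error, df_error, r,
                               alpha = 0.05) {
  ord <- order(means, decreasing = TRUE)
  m <- unname(means[ord])
  g <- length(m)
  crit <- function(p) {
    if (ms_error == 0) 0 else
      qtukey(1 - alpha, p, df_error) * sqrt(ms_error / r)
  }
  nonsig <- list()
  contained_in_nonsig <- function(i, j) {
    for (s in nonsig) if (s[1] <= i && j <= s[2]) return(TRUE)
    FALSE
  }
  level <- list(c(1, g))
  for (p in g:2) {
    next_level <- list()
    seen <- character(0)
    for (s in level) {
      key <- paste(s, collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      i <- s[1]; j <- s[2]
      if (contained_in_nonsig(i, j)) next
      if (m[i] - m[j] > crit(j - i + 1)) {
        if (j - i > 1) {
          next_level <- c(next_level, list(c(i, j - 1), c(i + 1, j)))
        }
      } else {
        nonsig[[length(nonsig) + 1]] <- c(i, j)
      }
    }
    level <- next_level
  }
  homogeneous <- function(i, j) i == j || contained_in_nonsig(i, j)
  stretches <- list()
  i <- 1
  prev_end <- 0
  while (i <= g) {
    j <- i
    while (j < g && homogeneous(i, j + 1)) j <- j + 1
    if (j > prev_end) {
      stretches[[length(stretches) + 1]] <- c(i, j)
      prev_end <- j
    }
    i <- i + 1
  }
  lab <- character(g)
  for (s in seq_along(stretches)) {
    idx <- stretches[[s]][1]:stretches[[s]][2]
    lab[idx] <- paste0(lab[idx], letters[s])
  }
  data.frame(genotype = names(means)[ord], mean = m, letters = lab,
             stringsAsFactors = FALSE)
}

# small random balanced RCBD environment
random_rcbd_df <- function(g, r, sd = 1, mu = 10) {
  df <- expand.grid(genotype = sprintf("G%d", 1:g),
                    replicate = sprintf("R%d", 1:r),
                    stringsAsFactors = FALSE)
  df$environment <- "E1"
  df$grain_yield_t_ha <- mu + rnorm(g)[match(df$genotype,
                                             sprintf("G%d", 1:g))] +
    rnorm(nrow(df), 0, sd)
  df
}

as_dataset <- function(df) {
  trial_dataset(df, plot_config = plot_config(npa_m2 = 8))
}

# mean per-environment broad-sense heritability estimate for grain yield
# over the environments of one simulated trial
h2_hats <- function(dataset) {
  envs <- unique(dataset$observations$environment)
  vapply(envs, function(env) {
    tab <- anova_rcbd(dataset, env, "grain_yield_t_ha")
    vc <- variance_components(tab)
    heritability(vc$sigma_g2, vc$sigma_p2)
  }, numeric(1))
}
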