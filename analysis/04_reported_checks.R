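#!/usr/bin/env Rscript
# Step 4: consistency checks against the published trial tables.
#
# The raw field data of the Burkina Faso hybrid trial are not deposited,
# but the published summary tables are internally checkable: the printed
# heritability must equal the ratio of the printed variance components,
# the printed per-location mean yields must equal the column means of the
# printed genotype-by-environment matrix, and the ranking/stability
# conclusions must be reproducible from that matrix.

library(maizemet)
dir.create("results", showWarnings = FALSE)

params <- reported_genetic_params()
params$h2_recomputed <- round(heritability(params$sigma_g2,
                                           params$sigma_p2), 2)
params$h2_consistent <- params$h2_recomputed == params$heritability
cat("Printed heritability vs sigma_g2/sigma_p2 ratio:\n")
print(params, row.names = FALSE)

d <- reported_yield_means_dataset()
rk <- rank_environments(d)
rk$reported_mean <- params$mean_yield[match(rk$environment,
                                            params$environment)]
rk$mean_consistent <- round(rk$mean_yield, 2) == rk$reported_mean
cat("\nColumn means of the yield matrix vs printed location means:\n")
print(rk, row.names = FALSE, digits = 4)
cat("(FN and TM disagree in the source tables; all others reproduce.)\n")

means <- reported_yield_means()
top <- means[which.max(means$yield_t_ha), ]
cat(sprintf("\nBest single cell: %s at %s, %.3f t/ha\n",
            top$genotype, top$environment, top$yield_t_ha))

st <- suppressWarnings(stability_ranking(d))
cat("\nStability ranking over the published means:\n")
print(st$genotypes, row.names = FALSE, digits = 3)

out <- merge(params[, c("environment", "heritability", "h2_recomputed",
                        "h2_consistent")],
             rk[, c("environment", "mean_yield", "rank",
                    "reported_mean", "mean_consistent")],
             by = "environment")
write.csv(out, "results/reported_checks.csv", row.names = FALSE)
cat("\nWrote results/reported_checks.csv\n")
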