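#!/usr/bin/env Rscript
# Step 1: generate the working multi-environment trial.
#
# A 9-genotype x 9-environment x 3-replicate RCBD with the sparse
# genotype presence of the Burkina Faso hybrid trial (SD8 grown at two
# locations only, SD7 and SD9 each missing from one). Yield reaches the
# dataset through the full standardization path: latent plot yields are
# realized as ear weight + harvest moisture and converted back at 15%
# reference moisture.

library(maizemet)

dir.create("results", showWarnings = FALSE)

trial <- make_fixture("sparse_like_reported")
write_trial_csv(trial, "results/synthetic_trial.csv")

report <- validate_dataset(trial)
cat("Simulated trial:", nrow(trial$observations), "plots,",
    nrow(trial$genotypes), "genotypes,",
    nrow(trial$environments), "environments\n")
cat("All environments balanced outside the missing pattern:",
    all(report$balance), "\n")
cat("Genotype absences (by design):\n")
print(report$absent, row.names = FALSE)
cat("\nWrote results/synthetic_trial.csv\n")
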