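#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces the full input bundle the rest of the workflow consumes: a dated
# family tree (Newick, Myr), a region table with tropical/temperate areas,
# the species checklist with horticulture flags, and long-format native +
# naturalized occurrence records. Ground-truth regression coefficients and
# variance components are stored alongside so later stages can be checked
# against what was actually simulated.
#
# Usage: Rscript analysis/01_simulate_data.R [seed]

library(natdiv)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- simulation_config(seed = seed)
bundle <- simulate_study(cfg)
write_bundle(bundle, "results/bundle")

cat(sprintf("families simulated:   %d\n", cfg$n_families))
cat(sprintf("species simulated:    %d\n", nrow(bundle$species)))
cat(sprintf("occurrence records:   %d\n", nrow(bundle$occurrences)))
cat(sprintf("families passing the >=%d-species filter: %d\n",
            cfg$min_richness, nrow(bundle$family_data)))
cat(sprintf("true coefficients (standardized scale): %s\n",
            paste(sprintf("%s=%.2f", names(cfg$beta), cfg$beta), collapse = ", ")))
cat("bundle written to results/bundle/\n")
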