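#!/usr/bin/env Rscript
# Stage 1: generate the paper-like synthetic cohort (27,271 species with >= 2
# reported maximum sizes each, rare injected unit/colony errors) and write it
# in the ingest CSV schemas under results/cohort/.

suppressPackageStartupMessages(library(sizerange))
seed <- 1L

truth <- simulation_truth(seed = seed)
sim <- simulate_measurements(truth)
write_cohort(sim, "results/cohort")

cat(sprintf("wrote %d measurements for %d species to results/cohort/\n",
            nrow(sim$records), truth$n_species))
cat(sprintf("injected gross errors: %d (unit: %d, colony: %d)\n",
            nrow(sim$error_ledger),
            sum(sim$error_ledger$error_type == "unit_factor"),
            sum(sim$error_ledger$error_type == "colony_factor")))
cat(sprintf("clean zero-range fraction: %.3f\n",
            mean(sim$species_truth$maxsize_range == 0)))
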