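#!/usr/bin/env Rscript
# Stage 1: generate the demonstration dataset.
#
# Simulates 50,000 spontaneous reports over the packaged 20-drug catalog
# (10 steroids, 10 non-steroid comparators) with planted reporting-odds
# effects: venous-term multiplier 4 on the three sex-hormone drugs and
# arterial-term multiplier 3 on spironolactone. Writes FAERS-dialect
# tables plus the generator's closed-form ground truth under results/sim/.

suppressPackageStartupMessages(library(steroidror))

out <- "results/sim"
cfg <- example_study_config(n_cases = 50000, seed = 20240901)
sim <- simulate_reports(cfg)
paths <- write_faers(sim, out)
write_sim_truth(cfg, file.path(out, "sim_truth.json"))

cat("cases simulated:     ", cfg$n_cases, "\n")
cat("drug records:        ", nrow(sim$drug), "\n")
cat("reaction records:    ", nrow(sim$reac), "\n")
cat("polypharmacy cases:  ", sum(sim$truth$cases$n_drugs > 1), "\n")
cat("duplicated cases:    ", sum(sim$truth$cases$duplicated), "\n")
cat("planted venous drugs:", paste(example_study_truth()$venous,
                                   collapse = ", "), "\n")
cat("planted arterial drug:", example_study_truth()$arterial, "\n")
cat("tables written under ", out, "\n")
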