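#!/usr/bin/env Rscript
# Stage 2: run the full signal-detection pipeline on the simulated tables
# from stage 1 and report what it found.
#
# Ingestion -> integration -> deduplication -> monotherapy filter ->
# SMARTS steroid cohort -> ROR/Fisher signal scan -> sex/route strata and
# class summary -> ln(ROR) matrix -> PCA -> Ward clustering. All outputs
# land under results/pipeline/.

suppressPackageStartupMessages(library(steroidror))

stopifnot(file.exists("results/sim/drug.txt")) # run 01_simulate.R first

cfg <- pipeline_config(
  drug = "results/sim/drug.txt",
  reac = "results/sim/reac.txt",
  demo = "results/sim/demo.txt",
  ther = "results/sim/ther.txt",
  smiles = system.file("extdata", "scaffold_fixture.tsv",
                       package = "steroidror"),
  out_dir = "results/pipeline",
  # demonstration-scale thresholds: the FAERS-scale defaults (1000 drug
  # reports, 2000 term reports) are proportional to a database three
  # orders of magnitude larger than this 50k-case simulation
  min_drug_reports = 200, min_pt_reports = 50,
  n_clusters = 3, market_cutoff_year = 2024)

res <- run_pipeline(cfg)

cat("\n---- signal scan ----\n")
flagged <- res$signals[res$signals$flagged, ]
print(as.data.frame(flagged[, c("drug_name", "a", "ror", "ci_low",
                                "ci_high", "p")]), digits = 4)
truth <- example_study_truth()
planted <- unique(c(truth$venous, truth$arterial))
cat("\nplanted drugs recovered:",
    sum(planted %in% flagged$drug_name), "of", length(planted), "\n")

if (!is.null(res$pca)) {
  cat("\n---- multivariate ----\n")
  cat("explained ratios (PC1-3):",
      paste0(round(100 * res$pca$explained_ratio[1:min(3,
             length(res$pca$explained_ratio))], 1), "%", collapse = ", "),
      "\n")
  print(split(names(res$clusters), res$clusters))
  cmp <- tryCatch(smq_axis_comparison(res$pca, thrombosis_terms(), 2),
                  error = function(e) NULL)
  if (!is.null(cmp)) {
    cat(sprintf("venous vs arterial loadings on PC2: %.3f vs %.3f (Welch p = %.3g)\n",
                cmp$mean_venous, cmp$mean_arterial, cmp$p))
  }
}
cat("\noutputs under results/pipeline/\n")
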