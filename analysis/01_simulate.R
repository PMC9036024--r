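#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a synthetic three-group cohort (NC / MCI / AD) whose regional
# radiomics feature tables carry a planted AD atrophy pattern, with annual
# follow-up visits, pattern-dependent conversion hazards, and a separate
# latent-truth table. Writes the cohort to scratch/analysis/ (bulk
# per-subject tables) and a compact summary to results/.

suppressPackageStartupMessages(library(r2sn))

dir.create("scratch/analysis/features", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(n_nc = 60, n_mci = 80, n_ad = 60,
                    n_regions = 40, n_features = 20, seed = 101)
cohort <- generate_cohort(spec)
print(cohort)

write.csv(cohort$phenotypes, "scratch/analysis/phenotypes.csv",
          row.names = FALSE)
write.csv(cohort$visits, "scratch/analysis/visits.csv", row.names = FALSE)
write.csv(cohort$truth, "scratch/analysis/truth.csv", row.names = FALSE)
writeLines(attr(cohort$truth, "atrophy_regions"),
           "scratch/analysis/atrophy_regions.txt")
for (id in names(cohort$feature_matrices)) {
  write_feature_tsv(cohort$feature_matrices[[id]],
                    file.path("scratch/analysis/features",
                              paste0(id, ".tsv")))
}

# a second observation of the same latent cohort (perturbed measurement),
# used by the robustness stage
cohort_b <- reobserve_cohort(cohort, seed = 102)
dir.create("scratch/analysis/features_b", showWarnings = FALSE)
for (id in names(cohort_b$feature_matrices)) {
  write_feature_tsv(cohort_b$feature_matrices[[id]],
                    file.path("scratch/analysis/features_b",
                              paste0(id, ".tsv")))
}

summ <- do.call(rbind, lapply(split(cohort$phenotypes,
                                    cohort$phenotypes$diagnosis), function(d) {
  data.frame(diagnosis = d$diagnosis[1], n = nrow(d),
             age = round(mean(d$age), 1), MMSE = round(mean(d$MMSE), 1),
             ADAS_cog13 = round(mean(d$ADAS_cog13), 1),
             CSF_Abeta = round(mean(d$CSF_Abeta)))
}))
write.table(summ[c("NC", "MCI", "AD"), ], "results/cohort_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("cohort summary (baseline means):\n")
print(summ[c("NC", "MCI", "AD"), ], row.names = FALSE)
cat("atrophy regions planted:",
    length(attr(cohort$truth, "atrophy_regions")), "of", spec$n_regions, "\n")
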