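#!/usr/bin/env Rscript
# Stage 3 — individual R2SN construction.
#
# Min-max normalizes each subject's regional feature table, fits the
# feature redundancy screen (|r| > 0.9) on the NC reference group, freezes
# it, and builds every subject's region-by-region correlation network.
# Edge vectors are stacked in the canonical upper-triangle order.

suppressPackageStartupMessages(library(r2sn))

pheno <- read.csv("scratch/analysis/phenotypes.csv")
read_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  fms <- lapply(files, read_feature_tsv)
  names(fms) <- sub("\\.tsv$", "", basename(files))
  fms
}

for (obs in c("features", "features_b")) {
  fms <- read_dir(file.path("scratch/analysis", obs))
  nc_ids <- pheno$subject_id[pheno$diagnosis == "NC"]
  nets <- build_cohort_networks(fms, reference_ids = nc_ids)
  out <- file.path("scratch/analysis", paste0("edges_", obs, ".tsv"))
  write_edges_tsv(nets$edges, out)
  if (obs == "features") {
    writeLines(nets$retention$retained, "results/retained_features.txt")
    cat("redundancy screen on", length(nc_ids), "NC subjects:",
        length(nets$retention$retained), "of",
        length(nets$retention$retained) + length(nets$retention$dropped),
        "features retained\n")
    cat("networks:", nrow(nets$edges), "subjects x", ncol(nets$edges),
        "edges; edge range [", round(min(nets$edges), 2), ",",
        round(max(nets$edges), 2), "]\n")
  }
}
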