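#!/usr/bin/env Rscript
# Stage 4 — NC-vs-AD discrimination and consistent-connection selection.
#
# Edgewise pooled t-tests (Bonferroni-corrected) and a tenfold
# cross-validated linear SVM separate the NC and AD networks; the
# consistent connections are the edges passing both the statistical and
# the classifier-weight rule. Decision values are correlated with the
# clinical measures.

suppressPackageStartupMessages(library(r2sn))

pheno <- read.csv("scratch/analysis/phenotypes.csv")
edges <- read_edges_tsv("scratch/analysis/edges_features.tsv")
dx <- setNames(pheno$diagnosis, pheno$subject_id)
nc <- edges[dx[rownames(edges)] == "NC", ]
ad <- edges[dx[rownames(edges)] == "AD", ]

stats <- edgewise_ttest(nc, ad)
cat("edgewise NC vs AD:", sum(stats$p_adjusted < 0.05), "of",
    length(stats$p_adjusted), "edges significant (Bonferroni 0.05)\n")

clf <- crossvalidated_classifier(
  rbind(nc, ad),
  factor(rep(c("NC", "AD"), c(nrow(nc), nrow(ad))), levels = c("NC", "AD")),
  scheme = "kfold", k = 10, positive = "AD", seed = 104)
print(clf)

consistent <- select_consistent_edges(stats, clf, alpha = 0.05,
                                      top_frac = 0.05)
print(consistent)
writeLines(consistent$edge_ids, "results/consistent_edges.txt")

st_tab <- data.frame(edge = names(stats$t_values), t = stats$t_values,
                     p = stats$p_values, p_bonf = stats$p_adjusted)
write.table(st_tab, "scratch/analysis/edgewise_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# decision values of the evaluated NC/AD subjects against their clinical
# measures (a negative r with MMSE means higher disease scores track
# lower cognition)
eval_ids <- names(clf$decision_values)
clin <- pheno[match(eval_ids, pheno$subject_id),
              c("MMSE", "ADAS_cog13", "AVLT1", "FDG", "CSF_Abeta", "CSF_Tau")]
dvc <- decision_value_correlations(clf$decision_values, clin)
dvc[c("r", "p")] <- lapply(dvc[c("r", "p")], signif, 3)
write.table(dvc, "results/decision_value_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("decision-value correlations:\n")
print(dvc, row.names = FALSE)

rep_json <- sprintf(
  '{"scheme":"%s","auc":%.4f,"acc":%.4f,"sen":%.4f,"spe":%.4f,"n_consistent":%d}',
  clf$scheme, clf$auc, clf$acc, clf$sen, clf$spe, length(consistent$edge_ids))
writeLines(rep_json, "results/classifier_report.json")
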