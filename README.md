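# r2sn — regional radiomics similarity networks for MCI subtyping

Mild cognitive impairment (MCI) is clinically heterogeneous: some
patients progress to Alzheimer's disease (AD) within a few years, others
remain stable. `r2sn` implements a single-subject network approach to
stratifying that risk. Each subject's parcellated T1-weighted volume is
summarized as a **regional radiomics similarity network (R2SN)**: nodes
are atlas regions, and the edge between regions *i* and *j* is the
Pearson correlation of their radiomics feature vectors

> A\_ij = corr(f\_i, f\_j),

where f\_i holds the region's retained intensity/texture features (47
computed: 14 first-order, 22 GLCM, 11 GLRLM) after per-subject min–max
normalization and cohort-level redundancy pruning (|r| > 0.9).

On top of the networks the package runs the full analysis chain:

- **edgewise NC-vs-AD statistics** (pooled two-sample *t*, Bonferroni)
  and a **tenfold cross-validated linear SVM**, intersected into the
  *consistent connections*;
- **rank-2 NMF subtyping** of MCI consistent-connection profiles into
  A-CI ("similar to AD") and N-CI ("similar to NC"), with a per-subject
  A-CI probability and cross-run reproducibility metrics (overlap AUC,
  probability correlation);
- **subtype characterization**: clinical/CSF contrasts with permutation
  checks, CSF amyloid/tau categories (Aβ+ < 980 pg/mL, Tau+ > 245
  pg/mL), covariate-adjusted trajectories, windowed conversion
  proportions, Kaplan–Meier curves and a risk-set log-rank test;
- **imaging transcriptomics**: first PLS component relating the subtype
  difference map to regional gene expression, region-permutation
  significance, and a weight-ranked gene list for enrichment tools.

Because the motivating imaging cohorts are access-gated, the package
ships a first-class synthetic module (`generate_cohort()`,
`generate_labeled_volume()`, `generate_expression()`) that plants known
subtype structure, conversion hazards and signal genes, so every stage
is testable end to end. See `vignettes/r2sn-methods.Rmd` for the model,
parameter and calibration details.

## Worked example

The `analysis/` directory holds the staged workflow
(`01_simulate.R` … `07_transcriptomics.R`); run them in order from the
repository root. Condensed from an actual run (synthetic cohort, 60 NC /
80 MCI / 60 AD, 40 regions × 20 features, planted effect size 2):

```
$ Rscript analysis/04_discriminate.R
edgewise NC vs AD: 369 of 780 edges significant (Bonferroni 0.05)
Linear SVM (kfold): AUC=1.000 ACC=1.000 SEN=1.000 SPE=1.000 (positive: AD)
Consistent connections: 39 edges

$ Rscript analysis/05_subtype.R
MCI subtypes: 47 A-CI / 33 N-CI
agreement with planted latent pattern: 1
reproducibility across observations: overlap AUC = 1.000, A-CI probability r = 0.979

$ Rscript analysis/06_characterize.R
3-year conversion: A-CI 23/47 = 48.94%; N-CI 7/33 = 21.21%
log-rank: chi-square = 22.38, p = 2.24e-06 (permutation p = 0.000999)

$ Rscript analysis/07_transcriptomics.R
PLS1: r with t-map = 0.994, permutation p = 0.000999
planted signal genes: 25 of 25 in the top decile of weights
```

Reading the output: the planted atrophy pattern makes NC and AD networks
perfectly separable at this effect size; the NMF subtypes coincide with
the planted MCI patterns; the A-CI group converts to AD at roughly twice
the N-CI rate with a decisive log-rank test; and the PLS gene ranking
puts every planted signal gene in the top decile. Stage summaries land
in `results/` (assignments, contrast tables, KM curves, ranked genes);
bulk intermediates in `scratch/`.

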