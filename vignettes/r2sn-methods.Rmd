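---
title: "Regional radiomics similarity networks for MCI subtyping: methods"
author: "r2sn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional radiomics similarity networks for MCI subtyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(r2sn)
```

## The model

An individual regional radiomics similarity network (R2SN) describes one
subject's brain as a weighted graph. Nodes are atlas regions of a
parcellated T1-weighted volume; the edge between regions $i$ and $j$ is
the Pearson correlation between the two regions' radiomics feature
vectors,

$$ A_{ij} \;=\; \mathrm{corr}\!\left(\mathbf{f}_i,\ \mathbf{f}_j\right), $$

where $\mathbf{f}_i$ collects the retained regional features after
per-subject min–max normalization. Two regions that express similar
intensity and texture statistics are strongly connected regardless of
their spatial distance, so the network captures a morphological
covariance structure at the single-subject level — no group template and
no temporal signal is required.

The pipeline implemented here runs, end to end:

1. **Features** — 47 regional radiomics descriptors per region: 14
   first-order intensity statistics, 22 grey-level co-occurrence (GLCM)
   features and 11 grey-level run-length (GLRLM) features.
2. **Networks** — per-subject min–max normalization of each feature
   across regions, cohort-level pruning of redundant features
   ($|r| > 0.9$), and the interregional correlation matrix, flattened to
   a canonical upper-triangle edge vector.
3. **Discrimination** — edgewise two-sample pooled $t$-tests between the
   normal-control (NC) and Alzheimer's disease (AD) groups with
   Bonferroni control, and a tenfold cross-validated linear SVM on the
   same edges. The *consistent connections* are the intersection of the
   Bonferroni-significant edges and the top fraction of edges by
   absolute SVM weight.
4. **Subtyping** — the mild-cognitive-impairment (MCI) subjects'
   consistent-connection profiles, mapped to $[0,1]$ by
   $x \mapsto (x+1)/2$, are factorized with rank-2 nonnegative matrix
   factorization (NMF). The component whose coefficient-weighted mean
   profile lies closer to the AD mean profile is labeled A-CI, the other
   N-CI; the coefficient ratio gives each subject's probability of
   A-CI membership.
5. **Characterization** — baseline clinical and CSF-biomarker contrasts
   between subtypes (pooled $t$, 1000-label-permutation checks), CSF
   amyloid/tau categories (A$\beta$+ if A$\beta$ < 980 pg/mL, Tau+ if
   Tau > 245 pg/mL), covariate-adjusted longitudinal trajectories,
   windowed conversion proportions, Kaplan–Meier curves, and a log-rank
   test computed from explicit risk-set sums with a label-permutation
   distribution.
6. **Transcriptomics** — the regional A-CI-vs-N-CI $t$-map of node
   strength is related to a regions × genes expression matrix through
   the first partial-least-squares component: gene columns are z-scored,
   the map centered, and the component weights are the classical
   first-component solution $\mathbf{w} \propto X^\top \mathbf{y}$.
   Significance comes from uniform region permutation; the weight-ranked
   gene list is exported for external enrichment tools.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_bins` | 32 | texture discretization bins, fixed bin count over each region's own min–max range |
| offsets | 13 directions | the unique distance-1 3D displacements (isotropic 26-neighbourhood); texture features are averaged over directions |
| retention `threshold` | 0.9 | absolute feature–feature correlation above which the later feature is dropped |
| `alpha` | 0.05 | Bonferroni-adjusted significance cutoff for the edge screen |
| `top_frac` | 0.05 | fraction of edges kept by absolute SVM weight |
| SVM `cost` | 1 | L2 regularization constant of the linear SVM; metrics at decision threshold 0 |
| `n_restarts` | 20 | NMF random restarts; convergence at relative error change < 1e-6 or 500 iterations |
| `n_perm` | 1000 | label/region permutations; p-values use the add-one correction and never return 0 |
| CSF cutoffs | 980 / 245 pg/mL | amyloid and tau positivity thresholds |
| conversion `window` | 36 months | horizon for the windowed conversion proportion |

The 47-feature list is a package constant (`r2sn_feature_names()`), so an
alternative catalogue can be swapped in at one place without touching the
extraction machinery.

## What the synthetic generator emulates

`generate_cohort()` draws a base regions × features template and plants
an AD pattern on a fixed 20% subset of "atrophy" regions: each such
region loses its own fixed nonnegative mix of features, scaled by
`effect_size`. NC subjects are template plus i.i.d. noise; AD subjects
carry the full shift; each MCI subject carries the shift with probability
`frac_mci_adlike` (default 514/766, the observed subtype split). Because
the shifts are region-specific, edges between two shifted regions
decorrelate focally — a shared shift direction would leave their mutual
correlation almost unchanged while per-subject min–max normalization
spread the difference over the whole network, which is why the
region-specific construction was chosen.

Conversion times are exponential. The NC-like monthly hazard is
calibrated so that 21.77% convert within 36 months, and the default
hazard ratio `hazard_ratio_adlike` $= \log(1-0.6154)/\log(1-0.2177)
\approx 3.89$ raises the AD-like pattern to 61.54% — the two printed
three-year conversion proportions. Events surface at the first annual
visit after the latent conversion time and are administratively censored
at the last of `n_visits` (default 6) annual visits. Baseline clinical
measures are Gaussian per stratum (NC, NC-like MCI, AD-like MCI, AD)
with means ordered NC → AD; follow-up scores decline linearly at
pattern-dependent rates plus visit noise. Latent pattern labels and true
conversion times live only in a separate truth table.

The generator deliberately omits realistic brain geometry, scanner and
site effects, missing-data mechanisms, and spatially autocorrelated
anatomy. Passing tests therefore demonstrate that the statistical
machinery recovers planted structure under the stated noise model — not
that the pipeline's effect sizes or error rates transfer to real imaging
cohorts.

`generate_labeled_volume()` partitions a compact grid into contiguous
boxes with region-specific intensity distributions (mean, spread,
gradient), exercising the image-input path of the feature extractor.
`generate_expression()` plants `n_signal` gene columns as positive
multiples of a supplied regional statistic plus noise among pure-noise
genes.

## Numerical choices

- **Discretization**: fixed bin count over the region's own min–max
  range; a constant region maps to a single bin (first-order entropy 0,
  uniformity 1, texture matrices on one bin).
- **GLCM normalization** divides by the total pair count so the matrix
  is a joint probability distribution, which every co-occurrence feature
  formula presupposes; matrices are symmetrised before normalization.
  Directions contributing no in-mask pair are excluded from the
  direction average. The grey-level count $N_g$ used by the normalized
  inverse-difference features is the number of levels present in the
  region.
- **Degenerate inputs**: empty regions raise errors (silent NaN rows
  would corrupt networks downstream; an explicit permissive flag yields
  NaN rows instead); constant feature columns abort min–max
  normalization naming the feature; regions with zero variance across
  retained features abort network construction naming the region; a
  zero-pooled-variance edge yields $t=0$, $p=1$ with a warning.
- **Greedy pruning order** is the canonical feature order, making the
  retained set deterministic; the screen is fitted once on the NC
  reference group and applied frozen to everyone, so no diagnostic
  information leaks into the feature selection.
- **Edge order**: row-major upper triangle, $(1,2), (1,3), \dots$ — one
  canonical order used by every module and by the `i_j` edge ids in all
  interchange files.
- **NMF**: multiplicative updates under Frobenius loss with an additive
  guard of `.Machine$double.eps` in the denominators; best of
  `n_restarts` seeded initializations; the error trace of the winning
  run is retained and is non-increasing.
- **PLS sign**: the first component is oriented so its correlation with
  the t-map is nonnegative; weights and scores flip together. Variance
  explained is by default the fraction of expression (X) variance
  captured by the rank-1 reconstruction; the share of t-map variance
  ($r^2$) is available via `var_type = "y"`.
- **Ties**: ranked gene export breaks equal weights lexicographically;
  an exact centroid-distance tie in component labeling is an error
  rather than an arbitrary choice.

## Design decisions taken where the procedure was open

- The classifier-side edge selection ranks edges by the absolute weight
  of the linear SVM refit on all training data and keeps the top
  `top_frac`; this is the simplest faithful reading of selecting
  connections "from the classification analysis". Because an L2 SVM
  distributes weight across correlated edges, the intersection with the
  statistical rule is enriched for — but need not strictly contain —
  every planted edge; the statistical rule alone recovers them all at
  the tested effect sizes.
- Equal-variance pooled $t$ is the default (Welch available by flag);
  age and sex are not regressed out of edges before testing — they are
  controlled only in the longitudinal trajectories, via a linear model
  fitted on baseline records whose centered covariate contribution is
  subtracted, keeping the measure on its original scale.
- The at-risk denominator of a windowed conversion proportion excludes
  subjects censored before the window, which is the construction under
  which the printed 200/325 and 27/124 fractions are consistent with
  larger group sizes.
- Cross-parcellation robustness is emulated by re-observing the same
  latent cohort with fresh measurement noise (`reobserve_cohort()`) and
  rerunning the whole pipeline: real alternative atlases are out of
  scope, and a second noisy observation of the same anatomy captures the
  same question — does the subtyping depend on one particular
  measurement realization?
- The PLS permutation null permutes region labels uniformly and does not
  preserve spatial autocorrelation; with spatially smooth real maps this
  is anticonservative, a documented limitation.

## Problem sizes

The bundled analysis scripts and the test suite run at desk scale,
chosen so the planted effects sit comfortably above noise while each
stage completes in seconds: cohorts of 40–80 subjects per group over
30–40 regions and 15–20 features (780 edges at 40 regions), 200-replicate
null calibrations at 15 regions, and expression matrices of 100–500
genes. The feature extractor is exercised at full atlas scale (246
regions on a 60×72×60 grid) once, in the feature-count contract check.

## Known limitations

Rank-2 NMF assumes exactly two subtypes; no model-order selection is
performed. The survival model has a single event type — reversion from
MCI is not modeled. Texture features are computed on the raw grid
without wavelet or shape descriptors. The synthetic noise model is
i.i.d. Gaussian per feature entry, so cross-feature noise correlation,
which real radiomics features exhibit strongly, enters only through the
planted structure.
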