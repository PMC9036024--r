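# End-to-end orchestration: feature tables -> networks -> NC/AD
# discrimination -> consistent connections -> NMF subtyping, plus the
# region-level summaries feeding the transcriptomics stage.

#' Node strength profiles from canonical edge vectors
#'
#' Per subject and region, the mean weight of the region's incident edges —
#' the region-level summary of a subject's network.
#'
#' @param edges subjects x edges matrix in canonical order.
#' @param region_ids ordered region labels the edges were built from.
#' @return subjects x regions matrix.
#' @export
node_strength <- function(edges, region_ids) {
  ei <- edge_index(region_ids)
  n <- length(region_ids)
  stopifnot(ncol(edges) == nrow(ei))
  out <- matrix(0, nrow(edges), n,
                dimnames = list(rownames(edges), as.character(region_ids)))
  for (r in seq_len(n)) {
    inc <- ei$i == r | ei$j == r
    out[, r] <- rowMeans(edges[, inc, drop = FALSE])
  }
  out
}

#' Region-level t-map between two groups of node-strength profiles
#'
#' @param strength_a,strength_b subjects x regions matrices.
#' @return named numeric vector of per-region pooled t-statistics.
#' @export
regional_tmap <- function(strength_a, strength_b) {
  st <- edgewise_ttest(strength_a, strength_b)
  st$t_values
}

#' Run the full subtyping pipeline on a cohort of feature tables
#'
#' Normalizes every subject's regional feature matrix, fits the feature
#' redundancy screen on the NC reference group, builds all R2SNs, runs the
#' NC-vs-AD edgewise statistics and cross-validated linear SVM, intersects
#' the two selections into the consistent-connection set, clusters the MCI
#' subjects' consistent-edge profiles with rank-2 NMF, and labels the
#' components A-CI / N-CI by proximity to the AD and NC mean profiles.
#'
#' @param feature_matrices named list of regions x features matrices.
#' @param phenotypes data.frame with subject_id and diagnosis
#'   (NC/MCI/AD) for every subject.
#' @param seed integer seed (folds and NMF restarts).
#' @param alpha adjusted-p cutoff for the statistical edge selection.
#' @param top_frac classifier-weight fraction for the selection.
#' @param retention_threshold redundancy cutoff; default 0.9.
#' @param k SVM cross-validation folds; default 10.
#' @param n_restarts NMF restarts; default 20.
#' @return list of class \code{r2sn_pipeline}: \code{edges},
#'   \code{retention}, \code{stats}, \code{classifier},
#'   \code{consistent}, \code{nmf}, \code{assignment}, \code{groups}
#'   (subject ids per diagnosis), \code{region_ids}.
#' @export
run_subtype_pipeline <- function(feature_matrices, phenotypes, seed = 1L,
                                 alpha = 0.05, top_frac = 0.05,
                                 retention_threshold = 0.9, k = 10L,
                                 n_restarts = 20L) {
  stopifnot(all(names(feature_matrices) %in% phenotypes$subject_id))
  dx <- stats::setNames(phenotypes$diagnosis, phenotypes$subject_id)
  ids <- names(feature_matrices)
  groups <- split(ids, dx[ids])
  for (g in c("NC", "MCI", "AD")) {
    if (is.null(groups[[g]]) || length(groups[[g]]) < 2L) {
      stop("need at least 2 subjects in group ", g)
    }
  }
  nets <- build_cohort_networks(feature_matrices,
                                reference_ids = groups$NC,
                                threshold = retention_threshold)
  edges <- nets$edges
  nc <- edges[groups$NC, , drop = FALSE]
  ad <- edges[groups$AD, , drop = FALSE]
  mci <- edges[groups$MCI, , drop = FALSE]

  stats <- edgewise_ttest(nc, ad)
  clf_edges <- rbind(nc, ad)
  clf_labels <- factor(rep(c("NC", "AD"), c(nrow(nc), nrow(ad))),
                       levels = c("NC", "AD"))
  clf <- crossvalidated_classifier(clf_edges, clf_labels, scheme = "kfold",
                                   k = min(k, nrow(nc), nrow(ad)),
                                   positive = "AD", seed = seed)
  consistent <- select_consistent_edges(stats, clf, alpha = alpha,
                                        top_frac = top_frac)

  prof <- mci[, consistent$edge_ids, drop = FALSE]
  nmf <- nmf_cluster(to_nonnegative(prof), seed = seed,
                     n_restarts = n_restarts)
  assignment <- label_components(
    nmf, prof,
    nc_mean_profile = colMeans(nc[, consistent$edge_ids, drop = FALSE]),
    ad_mean_profile = colMeans(ad[, consistent$edge_ids, drop = FALSE])
  )
  structure(list(edges = edges, retention = nets$retention, stats = stats,
                 classifier = clf, consistent = consistent, nmf = nmf,
                 assignment = assignment, groups = groups,
                 region_ids = rownames(feature_matrices[[1L]])),
            class = "r2sn_pipeline")
}

#' @export
print.r2sn_pipeline <- function(x, ...) {
  cat("R2SN subtyping pipeline\n")
  cat("  edges: ", ncol(x$edges), " (", length(x$region_ids), " regions); ",
      "consistent: ", length(x$consistent$edge_ids), "\n", sep = "")
  print(x$classifier)
  cat("  subtypes: ", sum(x$assignment$label == "A-CI"), " A-CI / ",
      sum(x$assignment$label == "N-CI"), " N-CI\n", sep = "")
  invisible(x)
}

#' Subtype difference t-map on node strength
#'
#' Per-region pooled t between the A-CI and N-CI subjects' node-strength
#' profiles — the regional difference map fed to the transcriptomics stage.
#'
#' @param pipeline an \code{r2sn_pipeline}.
#' @return named numeric vector, one t per region (A-CI minus N-CI).
#' @export
subtype_tmap <- function(pipeline) {
  strength <- node_strength(pipeline$edges[pipeline$groups$MCI, , drop = FALSE],
                            pipeline$region_ids)
  a <- pipeline$assignment$subject_id[pipeline$assignment$label == "A-CI"]
  n <- pipeline$assignment$subject_id[pipeline$assignment$label == "N-CI"]
  regional_tmap(strength[a, , drop = FALSE], strength[n, , drop = FALSE])
}
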