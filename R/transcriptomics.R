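# Imaging-transcriptomics: first partial-least-squares component relating
# regional gene expression (genes z-scored across regions) to the subtype
# difference t-map, permutation significance, per-gene correlations, and
# export of the weight-ranked gene list for enrichment tools.

#' First PLS component between regional expression and a t-map
#'
#' Gene columns are z-scored across regions and the t-map centered; the
#' first component's gene weights are the classical solution w proportional
#' to X'y (the gene-space direction maximizing covariance between the
#' expression projection and the map). Region scores are X w. The sign is
#' fixed so that the component correlates nonnegatively with the t-map.
#' Variance explained is, by default, the fraction of total expression
#' variance captured by the component (rank-1 reconstruction); set
#' \code{var_type = "y"} for the share of t-map variance instead.
#'
#' @param expression regions x genes numeric matrix, columns named by gene.
#' @param tmap numeric per-region statistic vector, regions aligned with
#'   the expression rows.
#' @param var_type \code{"x"} (default) or \code{"y"}.
#' @return list of class \code{pls_result}: \code{gene_weights} (named,
#'   unit norm), \code{region_scores}, \code{var_explained},
#'   \code{r_with_tmap}, \code{dropped_genes}, \code{var_type}.
#' @export
pls_first_component <- function(expression, tmap, var_type = c("x", "y")) {
  var_type <- match.arg(var_type)
  X <- as.matrix(expression)
  if (nrow(X) < 3L) stop("need at least 3 regions")
  if (length(tmap) != nrow(X)) stop("tmap length must match region count")
  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0L) {
    warning(length(dropped), " zero-variance gene(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no genes with nonzero variance")
  Z <- scale(X)
  y <- tmap - mean(tmap)
  w <- drop(crossprod(Z, y))
  w <- w / sqrt(sum(w^2))
  scores <- drop(Z %*% w)
  r <- stats::cor(scores, y)
  if (r < 0) {
    w <- -w
    scores <- -scores
    r <- -r
  }
  ve <- if (var_type == "x") {
    loadings <- drop(crossprod(Z, scores)) / sum(scores^2)
    sum(loadings^2) * sum(scores^2) / sum(Z^2)
  } else {
    r^2
  }
  structure(list(
    gene_weights = stats::setNames(w, colnames(X)),
    region_scores = scores,
    var_explained = ve,
    r_with_tmap = r,
    dropped_genes = dropped,
    var_type = var_type
  ), class = "pls_result")
}

#' Permutation p-value for the PLS1 / t-map correlation
#'
#' Permutes the region order of the t-map, refits the first component each
#' time, and compares the permuted |correlation| with the observed one
#' (add-one corrected). Uniform region permutation; spatial autocorrelation
#' is not preserved.
#'
#' @param expression regions x genes matrix.
#' @param tmap per-region statistic vector.
#' @param n_perm number of permutations; default 1000.
#' @param seed integer seed.
#' @return list with p_perm, r_obs, n_perm.
#' @export
pls_permutation_p <- function(expression, tmap, n_perm = 1000L, seed = 1L) {
  obs <- suppressWarnings(pls_first_component(expression, tmap))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      r <- suppressWarnings(
        pls_first_component(expression, sample(tmap))$r_with_tmap)
      abs(r) >= abs(obs$r_with_tmap)
    }, logical(1)))
  })
  list(p_perm = (1 + exceed) / (n_perm + 1),
       r_obs = obs$r_with_tmap, n_perm = n_perm)
}

#' Correlate named genes with the t-map
#'
#' Pearson correlation of each queried gene's regional expression with the
#' t-map, Bonferroni-corrected over the queried list only.
#'
#' @param expression regions x genes matrix with gene column names.
#' @param tmap per-region statistic vector.
#' @param gene_names genes to test.
#' @param correction method for \code{\link[stats]{p.adjust}}; default
#'   "bonferroni".
#' @return data.frame (gene, r, p, p_adjusted); missing genes are reported
#'   in the \code{missing_genes} attribute and skipped.
#' @export
gene_tmap_correlations <- function(expression, tmap, gene_names,
                                   correction = "bonferroni") {
  present <- intersect(gene_names, colnames(expression))
  missing <- setdiff(gene_names, colnames(expression))
  if (length(present) == 0L) stop("none of the queried genes are present")
  res <- do.call(rbind, lapply(present, function(g) {
    ct <- stats::cor.test(expression[, g], tmap)
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- stats::p.adjust(res$p, method = correction)
  attr(res, "missing_genes") <- missing
  res
}

#' Export the weight-ranked gene list
#'
#' Genes sorted by descending first-component weight (ties broken
#' lexicographically), one symbol per line — the input format expected by
#' ranked-list GO enrichment tools.
#'
#' @param result a \code{pls_result} (or a named weight vector).
#' @param path output file; NULL returns the ranking without writing.
#' @return invisibly, a data.frame (gene, weight) in rank order.
#' @export
export_ranked_genes <- function(result, path = NULL) {
  w <- if (inherits(result, "pls_result")) result$gene_weights else result
  if (any(!is.finite(w))) stop("weights must be finite")
  ord <- order(-w, names(w))
  out <- data.frame(gene = names(w)[ord], weight = unname(w[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) writeLines(out$gene, path)
  invisible(out)
}
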