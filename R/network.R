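# Individual regional radiomics similarity networks (R2SN): per-subject
# min-max normalization of the regional feature matrix, cohort-level pruning
# of redundant features, and interregional Pearson correlation.

#' Min-max normalize a regional feature matrix
#'
#' Each feature column is independently mapped to [0, 1] across the
#' subject's regions via (x - min) / (max - min).
#'
#' @param fm regions x features numeric matrix.
#' @return matrix of the same shape with every column spanning [0, 1].
#' @export
minmax_normalize <- function(fm) {
  fm <- as.matrix(fm)
  if (nrow(fm) < 2L) stop("need at least 2 regions to normalize")
  rng <- apply(fm, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  if (any(span == 0)) {
    bad <- colnames(fm)[span == 0] %||% which(span == 0)
    stop("degenerate feature(s) constant across regions: ",
         paste(bad, collapse = ", "))
  }
  out <- sweep(fm, 2L, rng[1L, ], "-")
  sweep(out, 2L, span, "/")
}

#' Fit the redundancy screen for radiomics features
#'
#' Pools the rows (regions) of all supplied normalized feature matrices,
#' computes the feature-feature Pearson correlation matrix and greedily
#' eliminates, scanning features in their canonical column order, any
#' feature whose absolute correlation with an already-retained feature
#' exceeds \code{threshold}.
#'
#' @param fms a list of normalized regions x features matrices with
#'   identical column names, or a single matrix.
#' @param threshold absolute-correlation cutoff; default 0.9.
#' @return a list of class \code{feature_retention} with elements
#'   \code{retained} (ordered feature names), \code{threshold},
#'   \code{dropped}, and \code{provenance}.
#' @export
fit_feature_retention <- function(fms, threshold = 0.9,
                                  provenance = NA_character_) {
  if (is.matrix(fms) || is.data.frame(fms)) fms <- list(as.matrix(fms))
  stopifnot(length(fms) >= 1L)
  nm <- colnames(fms[[1L]])
  pooled <- do.call(rbind, lapply(fms, function(m) {
    m <- as.matrix(m)
    if (!identical(colnames(m), nm)) stop("feature names differ across subjects")
    m
  }))
  cc <- suppressWarnings(stats::cor(pooled))
  cc[is.na(cc)] <- 0
  p <- ncol(pooled)
  retained <- logical(p)
  for (j in seq_len(p)) {
    prior <- which(retained)
    retained[j] <- length(prior) == 0L || all(abs(cc[j, prior]) <= threshold)
  }
  structure(list(retained = nm[retained], threshold = threshold,
                 dropped = nm[!retained], provenance = provenance),
            class = "feature_retention")
}

#' @export
print.feature_retention <- function(x, ...) {
  cat("Feature retention (|r| threshold ", x$threshold, "): ",
      length(x$retained), " retained, ", length(x$dropped), " dropped\n",
      sep = "")
  invisible(x)
}

#' Build a subject's R2SN from a normalized feature matrix
#'
#' Edge (i, j) is the Pearson correlation between the retained-feature
#' vectors of regions i and j.
#'
#' @param fm normalized regions x features matrix.
#' @param retention a \code{feature_retention}, or a character vector of
#'   feature names to keep; NULL keeps all columns.
#' @return symmetric n_regions x n_regions matrix with unit diagonal, rows
#'   and columns named by region.
#' @export
build_r2sn <- function(fm, retention = NULL) {
  fm <- as.matrix(fm)
  keep <- if (is.null(retention)) colnames(fm)
          else if (inherits(retention, "feature_retention")) retention$retained
          else as.character(retention)
  missing <- setdiff(keep, colnames(fm))
  if (length(missing) > 0L) {
    stop("retained features absent from matrix: ", paste(missing, collapse = ", "))
  }
  sub <- fm[, keep, drop = FALSE]
  if (ncol(sub) < 2L) stop("need at least 2 retained features")
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(sub)[sds == 0] %||% which(sds == 0)
    stop("region(s) with zero variance across retained features: ",
         paste(bad, collapse = ", "))
  }
  net <- stats::cor(t(sub))
  diag(net) <- 1
  net
}

#' Canonical edge ordering of an n-region network
#'
#' Upper-triangle pairs (i, j), i < j, in row-major order: (1,2), (1,3),
#' ..., (1,n), (2,3), ... This single ordering is used by every module.
#'
#' @param region_ids ordered region labels (or a single count n).
#' @return data.frame with columns i, j, id ("i_j" from the region labels).
#' @export
edge_index <- function(region_ids) {
  if (length(region_ids) == 1L && is.numeric(region_ids)) {
    region_ids <- seq_len(region_ids)
  }
  n <- length(region_ids)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(i = i, j = j,
             id = paste(region_ids[i], region_ids[j], sep = "_"),
             stringsAsFactors = FALSE)
}

#' Flatten a network to its canonical edge vector
#'
#' @param net symmetric matrix.
#' @return named numeric vector of length n(n-1)/2 in canonical order.
#' @export
vectorize_edges <- function(net) {
  net <- as.matrix(net)
  n <- nrow(net)
  stopifnot(n == ncol(net))
  v <- t(net)[lower.tri(net)]    # row-major upper triangle
  ids <- rownames(net) %||% seq_len(n)
  names(v) <- edge_index(ids)$id
  v
}

#' Rebuild a symmetric unit-diagonal matrix from a canonical edge vector
#'
#' @param v edge vector of length n(n-1)/2.
#' @param region_ids ordered region labels for the reconstructed matrix.
#' @return symmetric matrix with unit diagonal.
#' @export
devectorize_edges <- function(v, region_ids) {
  n <- length(region_ids)
  if (length(v) != n * (n - 1L) / 2L) {
    stop("edge vector length ", length(v), " does not match ",
         n, " regions (expected ", n * (n - 1L) / 2L, ")")
  }
  m <- matrix(0, n, n, dimnames = list(region_ids, region_ids))
  m[lower.tri(m)] <- v    # fills column-major lower = row-major upper of t
  m <- t(m)
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Build R2SNs for a whole cohort of feature matrices
#'
#' Convenience wrapper: min-max normalizes each subject, fits the redundancy
#' screen on a reference subset (default: all supplied subjects), then
#' builds every subject's network and returns the stacked canonical edge
#' vectors.
#'
#' @param fms named list of regions x features matrices (one per subject).
#' @param retention optional pre-fitted \code{feature_retention}; if NULL it
#'   is fitted on \code{reference_ids}.
#' @param reference_ids subject names used to fit the redundancy screen
#'   (default all).
#' @param threshold redundancy cutoff passed to
#'   \code{\link{fit_feature_retention}}.
#' @return list with \code{edges} (subjects x edges matrix, rows named by
#'   subject, columns by canonical edge id) and \code{retention}.
#' @export
build_cohort_networks <- function(fms, retention = NULL,
                                  reference_ids = names(fms),
                                  threshold = 0.9) {
  stopifnot(is.list(fms), length(fms) >= 1L, !is.null(names(fms)))
  normed <- lapply(fms, minmax_normalize)
  if (is.null(retention)) {
    retention <- fit_feature_retention(normed[reference_ids],
                                       threshold = threshold,
                                       provenance = "cohort reference")
  }
  edges <- t(vapply(normed, function(m) vectorize_edges(build_r2sn(m, retention)),
                    numeric(nrow(fms[[1L]]) * (nrow(fms[[1L]]) - 1L) / 2L)))
  rownames(edges) <- names(fms)
  list(edges = edges, retention = retention)
}
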