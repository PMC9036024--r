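# MCI subtyping: map consistent-connection profiles to the nonnegative
# range, factorize with rank-2 NMF (multiplicative updates, Frobenius loss,
# random restarts), label the two components by proximity to the NC and AD
# mean profiles, and quantify cross-run reproducibility.

#' Map correlation-valued edges to the nonnegative range
#'
#' x -> (x + 1) / 2: invertible and order-preserving, so NMF sees the full
#' information of the [-1, 1] edge weights.
#'
#' @param x numeric values in [-1, 1].
#' @param tol tolerance for range checking (floating-point slack).
#' @return values in [0, 1], same shape.
#' @export
to_nonnegative <- function(x, tol = 1e-8) {
  if (any(x < -1 - tol | x > 1 + tol, na.rm = TRUE)) {
    stop("inputs outside [-1, 1]")
  }
  (pmin(pmax(x, -1), 1) + 1) / 2
}

#' Inverse of \code{\link{to_nonnegative}}
#' @param y values in [0, 1].
#' @return values in [-1, 1].
#' @export
from_nonnegative <- function(y) 2 * y - 1

# one multiplicative-update NMF run; returns factors and the relative-error
# trace (non-increasing for Frobenius MU updates)
nmf_run <- function(X, rank, max_iter, tol, eps = .Machine$double.eps) {
  n <- nrow(X)
  p <- ncol(X)
  W <- matrix(stats::runif(n * rank), n, rank)
  H <- matrix(stats::runif(rank * p), rank, p)
  nx <- norm(X, "F")
  trace <- numeric(0)
  err <- Inf
  for (it in seq_len(max_iter)) {
    W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    H <- H * (t(W) %*% X) / (crossprod(W) %*% H + eps)
    new_err <- norm(X - W %*% H, "F") / nx
    trace <- c(trace, new_err)
    if (is.finite(err) && abs(err - new_err) < tol * max(err, eps)) {
      err <- new_err
      break
    }
    err <- new_err
  }
  list(W = W, H = H, error = err, trace = trace)
}

#' Rank-2 NMF clustering of nonnegative edge profiles
#'
#' Factorizes the subjects x edges matrix X ~ W H with two nonnegative
#' components by Frobenius-loss multiplicative updates, keeping the best of
#' \code{n_restarts} random initializations. Each subject's pair of
#' coefficients (row of W) defines soft cluster membership; the hard label
#' is the argmax component.
#'
#' @param profiles subjects x edges matrix, all entries >= 0.
#' @param seed integer seed driving all initializations.
#' @param n_restarts number of random restarts; default 20.
#' @param max_iter update iteration cap per restart; default 500.
#' @param tol relative-error convergence tolerance; default 1e-6.
#' @return list of class \code{nmf_assignment}: \code{coefficients}
#'   (subjects x 2, rows named by subject), \code{basis} (2 x edges),
#'   \code{component} (argmax index per subject),
#'   \code{reconstruction_error} (relative Frobenius), \code{error_trace}
#'   of the winning run, \code{seed}, \code{n_restarts}.
#' @export
nmf_cluster <- function(profiles, seed = 1L, n_restarts = 20L,
                        max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(profiles)
  if (any(X < 0)) stop("profiles must be nonnegative")
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  if (all(X == 0)) stop("degenerate all-zero profile matrix")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      run <- nmf_run(X, rank = 2L, max_iter = max_iter, tol = tol)
      if (is.null(best) || run$error < best$error) best <- run
    }
  })
  comp <- max.col(best$W, ties.method = "first")
  structure(list(
    coefficients = structure(best$W, dimnames = list(rownames(X), NULL)),
    basis = best$H,
    component = stats::setNames(comp, rownames(X)),
    reconstruction_error = best$error,
    error_trace = best$trace,
    seed = seed,
    n_restarts = n_restarts
  ), class = "nmf_assignment")
}

#' Label NMF components as A-CI / N-CI
#'
#' The component whose coefficient-weighted mean member profile lies closer
#' (Euclidean) to the AD mean profile is labeled A-CI ("similar to AD");
#' the other N-CI. Also derives each subject's probability of belonging to
#' the A-CI group from the coefficient pair.
#'
#' @param assignment an \code{nmf_assignment}.
#' @param mci_profiles the subjects x edges matrix that was factorized
#'   (same edge space as the reference profiles).
#' @param nc_mean_profile mean edge profile of the NC group.
#' @param ad_mean_profile mean edge profile of the AD group.
#' @return data.frame of class \code{subtype_assignment} with columns
#'   subject_id, label ("A-CI"/"N-CI"), p_adlike, coef_adlike, coef_nclike;
#'   attribute \code{a_component} records which NMF component was A-like.
#' @export
label_components <- function(assignment, mci_profiles, nc_mean_profile,
                             ad_mean_profile) {
  X <- as.matrix(mci_profiles)
  W <- assignment$coefficients
  stopifnot(nrow(W) == nrow(X),
            length(nc_mean_profile) == ncol(X),
            length(ad_mean_profile) == ncol(X))
  centroid <- function(k) colSums(W[, k] * X) / sum(W[, k])
  d_ad <- vapply(1:2, function(k) sqrt(sum((centroid(k) - ad_mean_profile)^2)),
                 numeric(1))
  if (d_ad[1L] == d_ad[2L]) {
    stop("component labeling tie: both centroids equidistant from the AD profile")
  }
  a_comp <- which.min(d_ad)
  n_comp <- 3L - a_comp
  tot <- W[, a_comp] + W[, n_comp]
  p_adlike <- ifelse(tot > 0, W[, a_comp] / tot, 0.5)
  label <- ifelse(W[, a_comp] > W[, n_comp], "A-CI", "N-CI")
  out <- data.frame(
    subject_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    label = label,
    p_adlike = p_adlike,
    coef_adlike = W[, a_comp],
    coef_nclike = W[, n_comp],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "a_component") <- a_comp
  attr(out, "reconstruction_error") <- assignment$reconstruction_error
  class(out) <- c("subtype_assignment", "data.frame")
  out
}

# align two assignments on shared subject ids, preserving a's order
align_assignments <- function(a, b) {
  common <- intersect(a$subject_id, b$subject_id)
  if (length(common) < 2L) stop("assignments share fewer than 2 subjects")
  list(a = a[match(common, a$subject_id), ],
       b = b[match(common, b$subject_id), ])
}

#' Overlap AUC between two subtype assignments
#'
#' AUC of run B's A-CI probability against run A's hard labels, averaged
#' with the reverse direction (symmetrized). Used to quantify how well the
#' clustering reproduces across parcellations or perturbed inputs.
#'
#' @param assignment_a,assignment_b \code{subtype_assignment} data frames
#'   over the same subjects (matched by subject_id).
#' @return a proportion in [0, 1].
#' @export
clustering_overlap_auc <- function(assignment_a, assignment_b) {
  al <- align_assignments(assignment_a, assignment_b)
  if (length(unique(al$a$label)) < 2L || length(unique(al$b$label)) < 2L) {
    stop("overlap AUC undefined: an assignment has a single class")
  }
  auc_ab <- rank_auc(al$b$p_adlike, al$a$label == "A-CI")
  auc_ba <- rank_auc(al$a$p_adlike, al$b$label == "A-CI")
  (auc_ab + auc_ba) / 2
}

#' Correlation of A-CI membership probabilities between two runs
#'
#' @param assignment_a,assignment_b \code{subtype_assignment} data frames
#'   over the same subjects.
#' @return list with \code{r} and \code{p} (Pearson).
#' @export
probability_correlation <- function(assignment_a, assignment_b) {
  al <- align_assignments(assignment_a, assignment_b)
  ct <- stats::cor.test(al$a$p_adlike, al$b$p_adlike)
  list(r = unname(ct$estimate), p = ct$p.value)
}
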