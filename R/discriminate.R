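# NC-vs-AD discrimination on R2SN edges: vectorized edgewise two-sample
# t-tests with Bonferroni control, a cross-validated linear SVM, decision
# value / clinical correlations, and the "consistent connection" selection
# combining both routes.

#' Edgewise two-sample t-tests between two groups of edge profiles
#'
#' @param edges_a subjects x edges matrix for group A.
#' @param edges_b subjects x edges matrix for group B.
#' @param correction multiple-comparison correction; \code{"bonferroni"}
#'   (default) or anything accepted by \code{\link[stats]{p.adjust}}.
#' @param var_equal pooled-variance t (default TRUE); FALSE gives Welch.
#' @return list of class \code{edgewise_stats}: \code{t_values},
#'   \code{p_values}, \code{p_adjusted} (all named by edge),
#'   \code{group_sizes}, \code{correction}.
#' @export
edgewise_ttest <- function(edges_a, edges_b, correction = "bonferroni",
                           var_equal = TRUE) {
  edges_a <- as.matrix(edges_a)
  edges_b <- as.matrix(edges_b)
  stopifnot(ncol(edges_a) == ncol(edges_b))
  n1 <- nrow(edges_a)
  n2 <- nrow(edges_b)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  m1 <- colMeans(edges_a)
  m2 <- colMeans(edges_b)
  v1 <- apply(edges_a, 2L, stats::var)
  v2 <- apply(edges_b, 2L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  pp <- 2 * stats::pt(-abs(tt), df)
  degen <- !is.finite(tt)
  if (any(degen)) {
    warning(sum(degen), " edge(s) with zero pooled variance; t set to 0, p to 1")
    tt[degen] <- 0
    pp[degen] <- 1
  }
  names(tt) <- names(pp) <- colnames(edges_a)
  structure(list(t_values = tt, p_values = pp,
                 p_adjusted = stats::p.adjust(pp, method = correction),
                 group_sizes = c(n1, n2), correction = correction),
            class = "edgewise_stats")
}

# stratified k-fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# fit linear SVM and return decision values oriented so that `positive`
# class scores high, plus the primal weight vector in the same orientation
linear_svm_fit <- function(x, y, positive, cost = 1) {
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision function toward the first class it saw
  first <- as.character(fit$levels[1L])
  if (first == positive) list(w = w, b = b) else list(w = -w, b = -b)
}

#' Cross-validated linear classifier on edge profiles
#'
#' Linear support-vector machine (cost 1, no rescaling) separating two
#' groups of subjects from their canonical edge vectors, evaluated either
#' with stratified k-fold cross-validation or a stratified random split.
#' Metrics are computed from out-of-sample decision values; accuracy,
#' sensitivity and specificity use decision threshold 0; the reported edge
#' weights come from a final refit on all training data.
#'
#' @param edges subjects x edges matrix.
#' @param labels factor (or coercible) with exactly two levels.
#' @param scheme \code{"kfold"} (default) or \code{"split"}.
#' @param k number of folds for \code{"kfold"}; default 10.
#' @param train_frac training fraction for \code{"split"}; default 0.5.
#' @param positive label treated as the positive (disease) class; default
#'   the second factor level.
#' @param cost SVM regularization constant; default 1.
#' @param seed integer; drives fold/split assignment.
#' @return list of class \code{classifier_report}: \code{auc}, \code{acc},
#'   \code{sen}, \code{spe}, \code{scheme}, \code{fold_assignments},
#'   \code{decision_values} (named by subject, NA for training-only
#'   subjects under \code{"split"}), \code{weights} (per edge),
#'   \code{positive}.
#' @export
crossvalidated_classifier <- function(edges, labels,
                                      scheme = c("kfold", "split"),
                                      k = 10L, train_frac = 0.5,
                                      positive = NULL, cost = 1, seed = 1L) {
  scheme <- match.arg(scheme)
  edges <- as.matrix(edges)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2L]
  positive <- as.character(positive)
  if (!positive %in% levels(labels)) stop("positive class not in labels")
  pos <- labels == positive
  if (min(table(labels)) < 2L) stop("both classes need >= 2 subjects")

  dv <- rep(NA_real_, nrow(edges))
  names(dv) <- rownames(edges)
  if (scheme == "kfold") {
    if (k > min(table(labels))) stop("k exceeds the smaller class size")
    fold <- stratified_folds(labels, k, seed)
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- linear_svm_fit(edges[tr, , drop = FALSE], droplevels(labels[tr]),
                          positive, cost)
      dv[!tr] <- drop(edges[!tr, , drop = FALSE] %*% m$w) + m$b
    }
    eval_idx <- seq_len(nrow(edges))
    train_idx <- seq_len(nrow(edges))
  } else {
    fold <- with_seed(seed, {
      f <- integer(length(labels))
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        ntr <- max(1L, round(train_frac * length(idx)))
        f[idx] <- 2L
        f[sample(idx, ntr)] <- 1L
      }
      f
    })
    if (any(tapply(as.character(labels), fold,
                   function(z) length(unique(z))) < 2L)) {
      stop("degenerate split: a partition lost a class")
    }
    m <- linear_svm_fit(edges[fold == 1L, , drop = FALSE],
                        droplevels(labels[fold == 1L]), positive, cost)
    dv[fold == 2L] <- drop(edges[fold == 2L, , drop = FALSE] %*% m$w) + m$b
    eval_idx <- which(fold == 2L)
    train_idx <- which(fold == 1L)
  }

  pred_pos <- dv[eval_idx] > 0
  truth <- pos[eval_idx]
  final <- linear_svm_fit(edges[train_idx, , drop = FALSE],
                          droplevels(labels[train_idx]), positive, cost)
  structure(list(
    auc = rank_auc(dv[eval_idx], truth),
    acc = mean(pred_pos == truth),
    sen = mean(pred_pos[truth]),
    spe = mean(!pred_pos[!truth]),
    scheme = scheme,
    fold_assignments = fold,
    decision_values = dv,
    weights = stats::setNames(final$w, colnames(edges)),
    positive = positive,
    cost = cost,
    seed = seed
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Linear SVM (%s): AUC=%.3f ACC=%.3f SEN=%.3f SPE=%.3f (positive: %s)\n",
              x$scheme, x$auc, x$acc, x$sen, x$spe, x$positive))
  invisible(x)
}

#' Correlate classifier decision values with clinical measures
#'
#' Pearson correlation (pairwise-complete) between per-subject decision
#' values and each column of a clinical measures table.
#'
#' @param decision_values named numeric vector.
#' @param clinical data.frame of numeric measures, rows matching
#'   \code{decision_values}.
#' @return data.frame with columns measure, n, r, p (measures with fewer
#'   than 3 complete pairs are skipped with a warning).
#' @export
decision_value_correlations <- function(decision_values, clinical) {
  stopifnot(nrow(clinical) == length(decision_values))
  rows <- lapply(names(clinical), function(nm) {
    y <- clinical[[nm]]
    ok <- is.finite(decision_values) & is.finite(y)
    if (sum(ok) < 3L) {
      warning("measure ", nm, " skipped: fewer than 3 complete pairs")
      return(NULL)
    }
    ct <- stats::cor.test(decision_values[ok], y[ok])
    data.frame(measure = nm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Select disease-consistent connections
#'
#' Intersection of the edges that are significant after multiple-comparison
#' correction and the edges carrying the largest absolute classifier
#' weights.
#'
#' @param stats an \code{edgewise_stats}.
#' @param report a \code{classifier_report} over the same canonical edges.
#' @param alpha adjusted-p cutoff; default 0.05.
#' @param top_frac fraction of edges kept by absolute weight; default 0.05.
#' @return list of class \code{consistent_edges}: \code{edge_ids},
#'   \code{stat_rule}, \code{clf_rule}.
#' @export
select_consistent_edges <- function(stats, report, alpha = 0.05,
                                    top_frac = 0.05) {
  stopifnot(length(stats$p_adjusted) == length(report$weights))
  ids <- names(stats$p_adjusted) %||% seq_along(stats$p_adjusted)
  sig <- ids[stats$p_adjusted < alpha]
  n_top <- ceiling(top_frac * length(ids))
  top <- ids[order(abs(report$weights), decreasing = TRUE)][seq_len(n_top)]
  sel <- intersect(sig, top)
  if (length(sel) == 0L) {
    stop("empty consistent-edge selection: no edge is both significant (",
         stats$correction, " p < ", alpha, ") and in the top ",
         top_frac * 100, "% of |weight|")
  }
  structure(list(
    edge_ids = sel,
    stat_rule = sprintf("%s-adjusted p < %g (%d edges)",
                        stats$correction, alpha, length(sig)),
    clf_rule = sprintf("top %g%% of |SVM weight| (%d edges)",
                       top_frac * 100, n_top)
  ), class = "consistent_edges")
}

#' @export
print.consistent_edges <- function(x, ...) {
  cat("Consistent connections: ", length(x$edge_ids), " edges\n  [",
      x$stat_rule, "] x [", x$clf_rule, "]\n", sep = "")
  invisible(x)
}
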