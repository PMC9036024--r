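#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so library functions that need internal
#' randomness do not perturb user-level reproducibility.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve of a score against a binary truth, computed from
#' midranks. Equivalent to the Wilcoxon statistic scaled to [0, 1].
#'
#' @param score numeric scores (higher = more positive-like).
#' @param truth logical, TRUE for the positive class.
#' @return AUC in [0, 1].
#' @keywords internal
rank_auc <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: only one class present")
  }
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
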