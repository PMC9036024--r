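# Subtype characterization: clinical/biomarker contrasts with permutation
# robustness checks, CSF amyloid/tau categorization, windowed conversion
# proportions, Kaplan-Meier curves, a risk-set log-rank test, survival
# label permutations, covariate-adjusted longitudinal trajectories, and
# cross-cohort consistency of contrast maps.

#' Two-sample pooled-variance t-test on a clinical measure
#'
#' @param a,b numeric samples (NAs dropped).
#' @param var_equal pooled-variance t (default TRUE); FALSE gives Welch.
#' @return list with t, p, df, n (per-group sizes used).
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 observations per group")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n = c(length(a), length(b)))
}

# fast pooled two-sample t on a fixed sample with varying group indicator
pooled_t_stat <- function(x, in_a) {
  n1 <- sum(in_a)
  n2 <- length(x) - n1
  m1 <- mean(x[in_a])
  m2 <- mean(x[!in_a])
  sp2 <- ((n1 - 1) * stats::var(x[in_a]) + (n2 - 1) * stats::var(x[!in_a])) /
    (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Permutation test of a group difference in one measure
#'
#' Randomly permutes the binary group labels \code{n_perm} times and
#' compares the permuted absolute pooled-t statistics with the observed
#' one. Uses the add-one correction, so p is never 0.
#'
#' @param measure numeric per-subject values (NAs dropped with their label).
#' @param labels binary grouping (factor/character/logical).
#' @param n_perm number of permutations; default 1000.
#' @param seed integer seed.
#' @return list with p_perm, t_obs, n_perm.
#' @export
label_permutation_test <- function(measure, labels, n_perm = 1000L,
                                   seed = 1L) {
  ok <- is.finite(measure)
  measure <- measure[ok]
  labels <- labels[ok]
  groups <- unique(labels)
  if (length(groups) != 2L) stop("labels must have exactly two groups")
  if (stats::var(measure) == 0) stop("constant measure: permutation test undefined")
  in_a <- labels == groups[1L]
  t_obs <- pooled_t_stat(measure, in_a)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(pooled_t_stat(measure, sample(in_a))) >= abs(t_obs)
    }, logical(1)))
  })
  list(p_perm = (1 + exceed) / (n_perm + 1), t_obs = t_obs, n_perm = n_perm)
}

#' Categorize CSF amyloid/tau status
#'
#' Amyloid positivity: Abeta below \code{abeta_cut} pg/mL; tau positivity:
#' Tau above \code{tau_cut} pg/mL. The discordant combinations are pooled
#' into a single mixed category.
#'
#' @param abeta,tau CSF concentrations in pg/mL (vectors; NA propagates).
#' @param abeta_cut amyloid cutoff, default 980 pg/mL.
#' @param tau_cut tau cutoff, default 245 pg/mL.
#' @return factor with levels "Abeta+&Tau+", "Abeta-&Tau+/Abeta+&Tau-",
#'   "Abeta-&Tau-".
#' @export
csf_categorize <- function(abeta, tau, abeta_cut = 980, tau_cut = 245) {
  stopifnot(length(abeta) == length(tau))
  if (any(abeta <= 0 | tau <= 0, na.rm = TRUE)) {
    stop("CSF concentrations must be positive")
  }
  apos <- abeta < abeta_cut
  tpos <- tau > tau_cut
  lv <- c("Abeta+&Tau+", "Abeta-&Tau+/Abeta+&Tau-", "Abeta-&Tau-")
  out <- ifelse(apos & tpos, lv[1L],
                ifelse(!apos & !tpos, lv[3L], lv[2L]))
  factor(out, levels = lv)
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; df = (r-1)(c-1).
#'
#' @param counts matrix of nonnegative integer counts.
#' @return list with chi2, p, df.
#' @export
contingency_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row/column margin: chi-square undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Derive conversion survival data from per-visit diagnoses
#'
#' Conversion is the first follow-up visit with an AD diagnosis; its month
#' is the event time. Subjects never observed with AD are censored at their
#' last visit.
#'
#' @param visits long-format data.frame with columns subject_id, month,
#'   diagnosis.
#' @return data.frame with subject_id, time (months), event (logical).
#' @export
conversion_from_visits <- function(visits) {
  stopifnot(all(c("subject_id", "month", "diagnosis") %in% names(visits)))
  fu <- visits[visits$month > 0, ]
  rows <- lapply(split(fu, fu$subject_id), function(d) {
    d <- d[order(d$month), ]
    conv <- which(d$diagnosis == "AD")
    if (length(conv) > 0L) {
      data.frame(subject_id = d$subject_id[1L], time = d$month[conv[1L]],
                 event = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = d$subject_id[1L], time = max(d$month),
                 event = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of subjects converting within a follow-up window
#'
#' The at-risk denominator counts subjects who either converted within the
#' window or were followed (censored) to at least the window's end;
#' subjects lost before the window with no event are excluded.
#'
#' @param time months to conversion or censoring.
#' @param event logical, TRUE = converted.
#' @param window window length in months; default 36.
#' @return list with n_converted, n_at_risk, proportion.
#' @export
conversion_proportion <- function(time, event, window = 36) {
  stopifnot(length(time) == length(event), window > 0)
  event <- as.logical(event)
  converted <- event & time <= window
  at_risk <- converted | time >= window
  if (sum(at_risk) == 0L) stop("no subjects at risk within the window")
  list(n_converted = sum(converted), n_at_risk = sum(at_risk),
       proportion = sum(converted) / sum(at_risk))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring (via the survival package).
#'
#' @param time follow-up times (> 0).
#' @param event logical event indicator.
#' @return list of class \code{km_estimate}: \code{table} (data.frame
#'   time, n_risk, n_event, n_censor, surv) and \code{surv_fn}, a
#'   right-continuous step function t -> S(t) with S(0) = 1.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.logical(event)) ~ 1)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  fn <- stats::stepfun(fit$time, c(1, fit$surv))
  structure(list(table = tab, surv_fn = fn), class = "km_estimate")
}

#' Log-rank test from explicit risk-set sums
#'
#' Standard 1-df log-rank chi-square computed directly from the observed
#' and expected event counts over the pooled distinct event times.
#'
#' @param time_a,event_a follow-up times and event indicators, group A.
#' @param time_b,event_b same for group B.
#' @return list with chi2, p, observed (group-A events), expected
#'   (group-A expectation), variance.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  event_a <- as.logical(event_a)
  event_b <- as.logical(event_b)
  if (length(time_a) == 0L || length(time_b) == 0L) {
    stop("both groups must be nonempty")
  }
  if (!any(event_a) && !any(event_b)) {
    stop("log-rank undefined: no events in either group")
  }
  times <- sort(unique(c(time_a[event_a], time_b[event_b])))
  o1 <- e1 <- v <- 0
  for (t in times) {
    n1 <- sum(time_a >= t)
    n2 <- sum(time_b >= t)
    d1 <- sum(event_a & time_a == t)
    d2 <- sum(event_b & time_b == t)
    n <- n1 + n2
    d <- d1 + d2
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (v == 0) {
    if (o1 == e1) return(list(chi2 = 0, p = 1, observed = o1,
                              expected = e1, variance = 0))
    stop("log-rank variance is zero with nonzero observed-expected difference")
  }
  chi2 <- (o1 - e1)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = o1, expected = e1, variance = v)
}

#' Permutation check of the survival difference
#'
#' Permutes the subtype labels, recomputes the log-rank test each time, and
#' returns the permuted chi-square/p distribution together with the
#' empirical (add-one corrected) p-value.
#'
#' @param time,event pooled follow-up data.
#' @param group binary group labels.
#' @param n_perm number of permutations; default 1000.
#' @param seed integer seed.
#' @return list with p_empirical, chi2_obs, p_obs, perm_p (permuted
#'   log-rank p-values), n_perm.
#' @export
survival_label_permutation <- function(time, event, group, n_perm = 1000L,
                                       seed = 1L) {
  groups <- unique(group)
  if (length(groups) != 2L) stop("group must have exactly two levels")
  in_a <- group == groups[1L]
  obs <- logrank_test(time[in_a], event[in_a], time[!in_a], event[!in_a])
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pa <- sample(in_a)
      r <- logrank_test(time[pa], event[pa], time[!pa], event[!pa])
      c(r$chi2, r$p)
    }, numeric(2))
  })
  list(p_empirical = (1 + sum(perm[1L, ] >= obs$chi2)) / (n_perm + 1),
       chi2_obs = obs$chi2, p_obs = obs$p,
       perm_p = perm[2L, ], n_perm = n_perm)
}

#' Covariate-adjusted longitudinal trajectories by group
#'
#' Residualizes a longitudinal measure against age and sex using a linear
#' model fitted on the baseline (month 0) records of all subjects, then
#' averages the residuals per group per annual visit bin.
#'
#' @param visits long-format data.frame with columns subject_id, month and
#'   the measure column.
#' @param measure name of the measure column in \code{visits}.
#' @param covariates data.frame with subject_id, age, sex (baseline).
#' @param grouping named group labels (names = subject_id) or a data.frame
#'   with subject_id and label columns.
#' @param adjust residualize against age and sex (default TRUE).
#' @return data.frame: group, visit_year, n, mean, sd.
#' @export
adjusted_trajectories <- function(visits, measure, covariates, grouping,
                                  adjust = TRUE) {
  stopifnot(measure %in% names(visits))
  if (is.data.frame(grouping)) {
    grouping <- stats::setNames(grouping$label, grouping$subject_id)
  }
  d <- visits[is.finite(visits[[measure]]), ]
  d <- d[d$subject_id %in% names(grouping), ]
  d$group <- grouping[d$subject_id]
  cv <- covariates[match(d$subject_id, covariates$subject_id), ]
  d$age <- cv$age
  d$sex <- factor(cv$sex)
  if (adjust) {
    base <- d[d$month == 0, ]
    if (nrow(base) < 3L) stop("too few baseline records to fit covariates")
    fit <- stats::lm(stats::reformulate(c("age", "sex"), response = measure),
                     data = base)
    beta <- stats::coef(fit)[-1L]
    mm_base <- stats::model.matrix(~ age + sex, base)[, -1L, drop = FALSE]
    mm_all <- stats::model.matrix(~ age + sex, d)[, -1L, drop = FALSE]
    # remove only the centered covariate contribution, keeping the
    # measure on its original scale
    ctr <- sweep(mm_all, 2L, colMeans(mm_base), "-")
    d$value <- d[[measure]] - drop(ctr %*% beta)
  } else {
    d$value <- d[[measure]]
  }
  d$visit_year <- round(d$month / 12)
  agg <- do.call(rbind, lapply(split(d, list(d$group, d$visit_year),
                                     drop = TRUE), function(g) {
    data.frame(group = g$group[1L], visit_year = g$visit_year[1L],
               n = nrow(g), mean = mean(g$value),
               sd = stats::sd(g$value), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$group, agg$visit_year), ]
  rownames(agg) <- NULL
  agg
}

#' Consistency of contrast maps across cohorts
#'
#' Pearson correlation between two paired vectors of per-item t-statistics
#' (e.g. the same edgewise or measure-wise contrast computed in two
#' independent cohorts).
#'
#' @param stats_a,stats_b numeric vectors in the same item order.
#' @return list with r and p.
#' @export
cross_cohort_consistency <- function(stats_a, stats_b) {
  if (length(stats_a) != length(stats_b)) stop("vectors differ in length")
  if (length(stats_a) < 3L) stop("need at least 3 paired items")
  ct <- stats::cor.test(stats_a, stats_b)
  list(r = unname(ct$estimate), p = ct$p.value)
}
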