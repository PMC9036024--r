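# Subtype characterization: group contrasts, permutation tests, CSF
# categories, contingency tests, windowed conversion, Kaplan-Meier,
# log-rank against the survival package, and adjusted trajectories.

test_that("group comparison matches the pooled-t hand computation", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 * sqrt(1.5), tolerance = 1e-9)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)
  same <- rnorm(10)
  r0 <- compare_groups(same, same)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # missing values are dropped
  r_na <- compare_groups(c(1, 2, 3, NA), c(4, 5, NA, 6))
  expect_equal(r_na$t, r$t)
})

test_that("label permutation test attains the extreme p on perfect separation", {
  lab <- rep(c("A", "B"), each = 10)
  measure <- as.numeric(lab == "A") + rnorm(20, sd = 1e-6)
  r <- label_permutation_test(measure, lab, n_perm = 200, seed = 3)
  expect_equal(r$p_perm, 1 / 201)
  # determinism
  expect_identical(r,
                   label_permutation_test(measure, lab, n_perm = 200, seed = 3))
  expect_error(label_permutation_test(rep(1, 20), lab), "constant")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(15)
  lab <- rep(c("A", "B"), each = 12)
  ps <- replicate(200, label_permutation_test(rnorm(24), lab, n_perm = 99,
                                              seed = sample.int(1e6, 1))$p_perm)
  for (alpha in c(0.01, 0.05)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
  }
})

test_that("CSF categorization applies the published cutoffs", {
  expect_equal(as.character(csf_categorize(900, 300)), "Abeta+&Tau+")
  expect_equal(as.character(csf_categorize(1000, 200)), "Abeta-&Tau-")
  expect_equal(as.character(csf_categorize(900, 200)),
               "Abeta-&Tau+/Abeta+&Tau-")
  expect_equal(as.character(csf_categorize(1100, 300)),
               "Abeta-&Tau+/Abeta+&Tau-")
  expect_true(is.na(csf_categorize(NA, 300)))
  expect_error(csf_categorize(-5, 300), "positive")
})

test_that("contingency test is the uncorrected Pearson chi-square", {
  r0 <- contingency_test(matrix(10, 2, 2))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  tab <- matrix(c(20, 5, 10, 25), 2, 2)
  r <- contingency_test(tab)
  # doubling all cells doubles the statistic
  expect_equal(contingency_test(2 * tab)$chi2, 2 * r$chi2)
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("conversion events derive from the first AD visit", {
  visits <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 4),
    month = rep(c(0, 12, 24, 36), 2),
    diagnosis = c("MCI", "MCI", "AD", "AD",   # converts at month 24
                  "MCI", "MCI", "MCI", "MCI") # censored at 36
  )
  sv <- conversion_from_visits(visits)
  expect_equal(sv$time[sv$subject_id == "s1"], 24)
  expect_true(sv$event[sv$subject_id == "s1"])
  expect_equal(sv$time[sv$subject_id == "s2"], 36)
  expect_false(sv$event[sv$subject_id == "s2"])
})

test_that("windowed conversion proportions use the at-risk denominator", {
  # converted within the window, censored past it, lost before it
  time <- c(12, 24, 48, 20)
  event <- c(TRUE, TRUE, FALSE, FALSE)
  r <- conversion_proportion(time, event, window = 36)
  expect_equal(r$n_converted, 2)
  expect_equal(r$n_at_risk, 3)    # the early dropout is excluded
  expect_equal(r$proportion, 2 / 3)
  expect_error(conversion_proportion(c(10, 20), c(FALSE, FALSE), 36),
               "at risk")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_estimate(c(1, 2), c(TRUE, TRUE))
  expect_equal(km$surv_fn(1), 0.5)
  expect_equal(km$surv_fn(2), 0)
  expect_equal(km$surv_fn(0), 1)

  # all censored: survival stays at 1
  km1 <- km_estimate(c(3, 5, 7), c(FALSE, FALSE, FALSE))
  expect_true(all(km1$table$surv == 1))

  # mixed example against explicit risk-set products:
  # times 1(e) 2(c) 3(e) 4(e) 5(c): S = (1-1/5)(1-1/3)(1-1/2)
  km2 <- km_estimate(c(1, 2, 3, 4, 5), c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(km2$surv_fn(1), 4 / 5)
  expect_equal(km2$surv_fn(3), 4 / 5 * 2 / 3)
  expect_equal(km2$surv_fn(4.5), 4 / 5 * 2 / 3 * 1 / 2)
  # no censoring: equals the empirical survival function
  tt <- c(2, 4, 4, 7, 9)
  km3 <- km_estimate(tt, rep(TRUE, 5))
  for (t0 in c(2, 4, 8, 10)) {
    expect_equal(km3$surv_fn(t0), mean(tt > t0))
  }
})

test_that("log-rank from risk-set sums matches hand sums and survdiff", {
  # worked example: A = 1(e), 3(e); B = 2(e), 4(c)
  ta <- c(1, 3); ea <- c(TRUE, TRUE)
  tb <- c(2, 4); eb <- c(TRUE, FALSE)
  r <- logrank_test(ta, ea, tb, eb)
  # hand risk sets: t=1 (nA=2,nB=2,dA=1): e=0.5 v=0.25
  #                 t=2 (1,2,dB=1): e=1/3 v=2/9 ; t=3 (1,1,dA=1): e=.5 v=.25
  expect_equal(r$observed, 2)
  expect_equal(r$expected, 0.5 + 1 / 3 + 0.5, tolerance = 1e-12)
  expect_equal(r$variance, 0.25 + 2 / 9 + 0.25, tolerance = 1e-12)
  expect_equal(r$chi2, (2 - 4 / 3)^2 / (13 / 18), tolerance = 1e-12)

  # identical groups: no signal
  tt <- c(1, 2, 3, 4); ee <- c(TRUE, TRUE, FALSE, TRUE)
  r0 <- logrank_test(tt, ee, tt, ee)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # agreement with the survival package on random data
  set.seed(20)
  t1 <- rexp(40, 0.1); e1 <- runif(40) < 0.7
  t2 <- rexp(40, 0.25); e2 <- runif(40) < 0.7
  r1 <- logrank_test(t1, e1, t2, e2)
  sd1 <- survival::survdiff(
    survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, each = 40))
  expect_equal(r1$chi2, sd1$chisq, tolerance = 1e-9)
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c(3), c(FALSE)),
               "no events")
})

test_that("strongly separated hazards are detected with high power", {
  set.seed(33)
  detected <- replicate(40, {
    t1 <- pmin(rexp(100, 0.05), 60)
    t2 <- pmin(rexp(100, 0.25), 60)
    logrank_test(t1, t1 < 60, t2, t2 < 60)$p < 0.001
  })
  expect_gte(mean(detected), 0.95)
})

test_that("survival label permutation is calibrated and deterministic", {
  set.seed(41)
  time <- rexp(60, 0.1)
  event <- runif(60) < 0.8
  group <- rep(c("A", "B"), 30)
  r <- survival_label_permutation(time, event, group, n_perm = 99, seed = 5)
  expect_identical(r$p_empirical,
                   survival_label_permutation(time, event, group,
                                              n_perm = 99, seed = 5)$p_empirical)
  expect_gt(r$p_empirical, 0.05)  # null data: no signal
  # planted strong separation drives the empirical p to the floor
  t2 <- c(rexp(30, 0.5), rexp(30, 0.01))
  r2 <- survival_label_permutation(t2, rep(TRUE, 60),
                                   rep(c("A", "B"), each = 30),
                                   n_perm = 99, seed = 5)
  expect_equal(r2$p_empirical, 1 / 100)
})

test_that("trajectory adjustment leaves covariate-free data untouched", {
  subj <- sprintf("s%02d", 1:12)
  base_val <- 25
  visits <- expand.grid(subject_id = subj, month = c(0, 12, 24),
                        stringsAsFactors = FALSE)
  visits$MMSE <- base_val - visits$month / 12
  cov <- data.frame(subject_id = subj, age = rnorm(12, 70, 5),
                    sex = rep(c("M", "F"), 6))
  grp <- setNames(rep(c("A-CI", "N-CI"), each = 6), subj)
  adj <- adjusted_trajectories(visits, "MMSE", cov, grp)
  raw <- adjusted_trajectories(visits, "MMSE", cov, grp, adjust = FALSE)
  # baseline values are constant, so fitted covariate effects are exactly 0
  expect_equal(adj$mean, raw$mean, tolerance = 1e-9)
  # rows ordered by group then visit year
  expect_equal(raw$mean, rep(c(25, 24, 23), times = 2))

  # a constant measure yields a flat trajectory
  visits$flat <- 7
  flat <- adjusted_trajectories(visits, "flat", cov, grp, adjust = FALSE)
  expect_true(all(flat$mean == 7))

  # a planted faster decline in one group is recovered after adjustment
  set.seed(2)
  visits$decl <- ifelse(grp[visits$subject_id] == "A-CI",
                        28 - 2 * visits$month / 12,
                        28 - 0.3 * visits$month / 12) + rnorm(nrow(visits), 0, 0.1)
  tr <- adjusted_trajectories(visits, "decl", cov, grp)
  slope <- function(g) {
    d <- tr[tr$group == g, ]
    coef(lm(mean ~ visit_year, d))[2]
  }
  expect_lt(slope("A-CI"), slope("N-CI"))
})

test_that("cross-cohort consistency is the correlation of paired t-maps", {
  tv <- rnorm(50)
  expect_equal(cross_cohort_consistency(tv, tv)$r, 1)
  set.seed(5)
  expect_lt(abs(cross_cohort_consistency(rnorm(200), rnorm(200))$r), 0.2)
  expect_error(cross_cohort_consistency(1:2, 1:2), "3 paired")
  # split-half of a strong-effect cohort agrees across halves
  co <- toy_cohort(seed = 29, effect_size = 3, noise_sd = 0.4,
                   n = 60, n_mci = 10)
  nets <- build_cohort_networks(co$feature_matrices)
  nc <- co$truth$subject_id[co$truth$diagnosis == "NC"]
  ad <- co$truth$subject_id[co$truth$diagnosis == "AD"]
  st1 <- edgewise_ttest(nets$edges[nc[1:30], ], nets$edges[ad[1:30], ])
  st2 <- edgewise_ttest(nets$edges[nc[31:60], ], nets$edges[ad[31:60], ])
  cc <- cross_cohort_consistency(st1$t_values, st2$t_values)
  expect_gt(cc$r, 0.7)
})
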