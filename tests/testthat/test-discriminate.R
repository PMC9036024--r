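# Edgewise statistics, the cross-validated linear SVM, decision-value
# correlations, and the consistent-connection selection.

test_that("edgewise pooled t-tests match hand-computed values", {
  a <- matrix(c(1, 2, 3), 3, 2)   # both edges identical
  b <- matrix(c(4, 5, 6), 3, 2)
  st <- edgewise_ttest(a, b)
  expect_equal(unname(st$t_values[1]), -3 * sqrt(1.5), tolerance = 1e-9)
  expect_equal(unname(st$p_values[1]), 0.02131164, tolerance = 1e-6)
  expect_equal(st$p_adjusted, pmin(1, st$p_values * 2))
  expect_equal(st$group_sizes, c(3, 3))

  # identical groups: t = 0, p = 1 everywhere
  same <- matrix(rnorm(20), 5, 4)
  st0 <- edgewise_ttest(same, same)
  expect_true(all(st0$t_values == 0))
  expect_true(all(st0$p_values == 1))

  # zero-variance edge degenerates with a warning
  za <- cbind(rep(1, 4), rnorm(4))
  zb <- cbind(rep(1, 4), rnorm(4))
  expect_warning(stz <- edgewise_ttest(za, zb), "zero pooled variance")
  expect_equal(unname(stz$t_values[1]), 0)
  expect_equal(unname(stz$p_values[1]), 1)
})

test_that("Bonferroni control holds on null edges", {
  # 100 independent null edges, many replicates: family-wise error <= alpha
  set.seed(14)
  fp <- replicate(200, {
    st <- edgewise_ttest(matrix(rnorm(10 * 100), 10), matrix(rnorm(10 * 100), 10))
    any(st$p_adjusted < 0.05)
  })
  expect_lte(mean(fp), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  # adjusted p never below raw p
  st <- edgewise_ttest(matrix(rnorm(500), 5), matrix(rnorm(500), 5))
  expect_true(all(st$p_adjusted >= st$p_values))
})

test_that("the linear SVM separates separable groups and is seed-stable", {
  set.seed(2)
  xa <- matrix(rnorm(20 * 12, 0), 20, 12)
  xb <- matrix(rnorm(20 * 12, 4), 20, 12)
  edges <- rbind(xa, xb)
  rownames(edges) <- sprintf("s%02d", 1:40)
  colnames(edges) <- sprintf("e%02d", 1:12)
  y <- factor(rep(c("NC", "AD"), each = 20), levels = c("NC", "AD"))
  rep1 <- crossvalidated_classifier(edges, y, k = 5, seed = 9)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$acc, 1)
  expect_equal(rep1$sen, 1)
  expect_equal(rep1$spe, 1)
  expect_identical(rep1$positive, "AD")
  # decision values oriented toward the positive class
  expect_true(all(rep1$decision_values[y == "AD"] > 0))

  # determinism under the same seed
  rep2 <- crossvalidated_classifier(edges, y, k = 5, seed = 9)
  expect_identical(rep1$fold_assignments, rep2$fold_assignments)
  expect_equal(rep1[c("auc", "acc", "sen", "spe")],
               rep2[c("auc", "acc", "sen", "spe")])

  # metrics invariant to subject ordering
  perm <- sample(40)
  rep3 <- crossvalidated_classifier(edges[perm, ], y[perm], k = 5, seed = 9)
  expect_equal(rep3$auc, rep1$auc)

  # split scheme evaluates only the held-out half
  rep4 <- crossvalidated_classifier(edges, y, scheme = "split", seed = 9)
  expect_equal(sum(is.na(rep4$decision_values)), sum(rep4$fold_assignments == 1))
  expect_equal(rep4$auc, 1)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(31)
  edges <- matrix(rnorm(60 * 20), 60, 20)
  aucs <- vapply(1:20, function(i) {
    y <- factor(sample(rep(c("NC", "AD"), each = 30)), levels = c("NC", "AD"))
    crossvalidated_classifier(edges, y, k = 5, seed = i)$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.08)
})

test_that("decision-value correlations behave at the self and null limits", {
  set.seed(6)
  dv <- rnorm(60)
  clin <- data.frame(self = dv, anti = -dv, noise = rnorm(60),
                     sparse = c(dv[1:2], rep(NA, 58)))
  expect_warning(res <- decision_value_correlations(dv, clin), "sparse")
  expect_equal(res$r[res$measure == "self"], 1)
  expect_equal(res$r[res$measure == "anti"], -1)
  expect_lt(abs(res$r[res$measure == "noise"]), 0.35)
  expect_false("sparse" %in% res$measure)
})

test_that("consistent-edge selection intersects both rules and shrinks monotonically", {
  m <- 40
  ids <- sprintf("e%02d", 1:m)
  st <- structure(list(
    p_adjusted = setNames(c(rep(1e-4, 10), rep(0.5, 30)), ids),
    correction = "bonferroni"), class = "edgewise_stats")
  rp <- structure(list(
    weights = setNames(c(seq(40, 1)), ids)), class = "classifier_report")

  # all significant + top_frac 1: everything selected
  st_all <- st; st_all$p_adjusted[] <- 1e-4
  sel_all <- select_consistent_edges(st_all, rp, top_frac = 1)
  expect_setequal(sel_all$edge_ids, ids)

  sel <- select_consistent_edges(st, rp, alpha = 0.05, top_frac = 0.25)
  expect_setequal(sel$edge_ids, ids[1:10])
  # shrinks as top_frac shrinks
  sel_small <- select_consistent_edges(st, rp, alpha = 0.05, top_frac = 0.1)
  expect_true(all(sel_small$edge_ids %in% sel$edge_ids))

  # disjoint significant and top-weight sets: explicit error
  st_tail <- st
  st_tail$p_adjusted[] <- c(rep(0.5, 30), rep(1e-4, 10))
  expect_error(select_consistent_edges(st_tail, rp, top_frac = 0.25),
               "empty consistent-edge selection")
})

test_that("planted atrophy edges are recovered by the consistent set", {
  co <- toy_cohort(seed = 17, effect_size = 3, noise_sd = 0.4,
                   n = 40, n_mci = 20)
  pl <- run_subtype_pipeline(co$feature_matrices, co$phenotypes, seed = 5,
                             top_frac = 0.2)
  planted <- attr(co$truth, "planted_edges")
  # every planted edge clears the statistical screen ...
  expect_true(all(pl$stats$p_adjusted[planted] < 0.05))
  # ... and the intersection with the classifier rule is strongly
  # enriched for planted edges relative to its overall selection rate
  sel_rate <- length(pl$consistent$edge_ids) / ncol(pl$edges)
  expect_gt(mean(planted %in% pl$consistent$edge_ids), 3 * sel_rate)
})
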