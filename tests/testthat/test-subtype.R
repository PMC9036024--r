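# NMF subtyping: nonnegativity mapping, factorization quality and
# determinism, component labeling, and the reproducibility metrics.

test_that("the nonnegativity map is the affine endpoint-preserving bijection", {
  expect_equal(to_nonnegative(c(-1, 0, 1)), c(0, 0.5, 1))
  x <- seq(-1, 1, length.out = 21)
  expect_true(all(diff(to_nonnegative(x)) > 0))          # order-preserving
  expect_equal(from_nonnegative(to_nonnegative(x)), x)   # round trip
  expect_error(to_nonnegative(1.5), "outside")
})

test_that("rank-2 NMF reconstructs exact rank-2 nonnegative matrices", {
  set.seed(4)
  W0 <- matrix(runif(30 * 2), 30, 2)
  H0 <- matrix(runif(2 * 15), 2, 15)
  X <- W0 %*% H0
  fit <- nmf_cluster(X, seed = 2, n_restarts = 10)
  expect_lt(fit$reconstruction_error, 1e-3)
  # error trace is non-increasing (multiplicative updates, Frobenius loss)
  expect_true(all(diff(fit$error_trace) <= 1e-12))
  # determinism under the seed
  fit2 <- nmf_cluster(X, seed = 2, n_restarts = 10)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_error(nmf_cluster(matrix(0, 4, 3)), "all-zero")
  expect_error(nmf_cluster(matrix(-1, 4, 3)), "nonnegative")
})

test_that("well-separated planted blocks are recovered by argmax labels", {
  set.seed(9)
  n <- 60
  truth <- rep(c(1, 2), each = n / 2)
  basis <- rbind(c(rep(1, 10), rep(0.05, 10)),
                 c(rep(0.05, 10), rep(1, 10)))
  X <- 0.9 * basis[truth, ] + matrix(runif(n * 20, 0, 0.1), n, 20)
  fit <- nmf_cluster(X, seed = 3, n_restarts = 10)
  agree <- max(mean(fit$component == truth),
               mean(fit$component == 3 - truth))   # up to component swap
  expect_gte(agree, 0.95)

  # permuting subjects permutes the outputs identically
  perm <- sample(n)
  fit_p <- nmf_cluster(X[perm, ], seed = 3, n_restarts = 10)
  agree_p <- max(mean(fit_p$component == truth[perm]),
                 mean(fit_p$component == 3 - truth[perm]))
  expect_gte(agree_p, 0.95)
})

test_that("components are labeled by proximity to the AD and NC profiles", {
  set.seed(12)
  # two distinct nonnegative patterns: the AD-like one depressed on half
  # of the edges, intact elsewhere (mirroring lost connectivity)
  nc_mean <- runif(8, 0.5, 0.9)
  ad_mean <- nc_mean
  ad_mean[1:4] <- nc_mean[1:4] - 0.45
  memb <- c(runif(10, 0.85, 1), runif(10, 0, 0.15))  # mixture weights
  prof <- outer(memb, ad_mean) + outer(1 - memb, nc_mean) +
    matrix(rnorm(160, sd = 0.02), 20, 8)
  rownames(prof) <- sprintf("m%02d", 1:20)
  fit <- nmf_cluster(prof, seed = 1, n_restarts = 10)
  asg <- label_components(fit, prof, nc_mean, ad_mean)
  expect_setequal(asg$label[1:10], "A-CI")
  expect_setequal(asg$label[11:20], "N-CI")
  expect_true(min(asg$p_adlike[1:10]) > max(asg$p_adlike[11:20]))
  expect_equal(asg$p_adlike,
               asg$coef_adlike / (asg$coef_adlike + asg$coef_nclike))
  # A-CI members sit lower on the depressed edges than N-CI members
  expect_lt(mean(prof[asg$label == "A-CI", 1:4]),
            mean(prof[asg$label == "N-CI", 1:4]))

  # swapping the reference profiles swaps the labels
  asg_sw <- label_components(fit, prof, nc_mean_profile = ad_mean,
                             ad_mean_profile = nc_mean)
  expect_true(all((asg$label == "A-CI") == (asg_sw$label == "N-CI")))

  # identical coefficient columns give identical centroids: an exact tie
  tied <- fit
  tied$coefficients <- cbind(fit$coefficients[, 1], fit$coefficients[, 1])
  expect_error(label_components(tied, prof, nc_mean, ad_mean), "tie")
})

test_that("overlap AUC and probability correlation quantify reproducibility", {
  asg <- data.frame(subject_id = sprintf("m%02d", 1:30),
                    label = rep(c("A-CI", "N-CI"), c(18, 12)),
                    p_adlike = c(runif(18, 0.6, 1), runif(12, 0, 0.4)))
  expect_equal(clustering_overlap_auc(asg, asg), 1)
  expect_equal(probability_correlation(asg, asg)$r, 1)

  # symmetry in the arguments
  asg_b <- asg
  asg_b$p_adlike <- pmin(1, pmax(0, asg$p_adlike + rnorm(30, sd = 0.1)))
  asg_b$label <- ifelse(asg_b$p_adlike > 0.5, "A-CI", "N-CI")
  expect_equal(clustering_overlap_auc(asg, asg_b),
               clustering_overlap_auc(asg_b, asg))

  # affine transform of one probability vector keeps |r| = 1
  asg_c <- asg
  asg_c$p_adlike <- 0.2 + 0.5 * asg$p_adlike
  expect_equal(abs(probability_correlation(asg, asg_c)$r), 1)

  # an assignment independent of the first hovers near AUC 0.5
  set.seed(77)
  null_auc <- replicate(100, {
    asg_r <- asg
    asg_r$p_adlike <- runif(30)
    asg_r$label <- ifelse(asg_r$p_adlike > 0.5, "A-CI", "N-CI")
    clustering_overlap_auc(asg, asg_r)
  })
  expect_equal(mean(null_auc), 0.5, tolerance = 0.05)

  asg_one <- asg
  asg_one$label <- "A-CI"
  expect_error(clustering_overlap_auc(asg, asg_one), "single class")
})

test_that("end-to-end subtyping recovers the planted MCI patterns", {
  co <- toy_cohort(seed = 23, effect_size = 2, noise_sd = 0.5,
                   n = 50, n_mci = 60)
  pl <- run_subtype_pipeline(co$feature_matrices, co$phenotypes, seed = 8)
  tr <- co$truth[match(pl$assignment$subject_id, co$truth$subject_id), ]
  agree <- mean((pl$assignment$label == "A-CI") == (tr$pattern == "AD-like"))
  expect_gte(agree, 0.9)
})
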