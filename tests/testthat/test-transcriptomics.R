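# PLS imaging-transcriptomics: first-component extraction against a
# grid-search oracle and an established PLS implementation, permutation
# significance, per-gene correlations, and the ranked export.

test_that("PLS1 is exact in the single-gene and orthogonal limits", {
  set.seed(1)
  tmap <- rnorm(20)
  # single gene proportional to the map: perfect alignment, full variance
  ex1 <- matrix(2.5 * tmap, ncol = 1, dimnames = list(NULL, "g1"))
  r1 <- pls_first_component(ex1, tmap)
  expect_equal(r1$r_with_tmap, 1)
  expect_equal(r1$var_explained, 1)
  expect_equal(unname(r1$gene_weights), 1)

  # expression orthogonalized against the map: near-zero correlation
  X <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- tmap - mean(tmap)
  Xo <- apply(X, 2, function(col) {
    col <- col - mean(col)
    col - y * sum(col * y) / sum(y^2)
  })
  colnames(Xo) <- paste0("g", 1:5)
  ro <- pls_first_component(Xo, tmap)
  expect_lt(abs(ro$r_with_tmap), 1e-8)

  # sign convention: correlation with the map is never negative
  r_neg <- pls_first_component(matrix(-tmap, ncol = 1,
                                      dimnames = list(NULL, "g")), tmap)
  expect_gte(r_neg$r_with_tmap, 0)
  expect_true(r_neg$var_explained >= 0 && r_neg$var_explained <= 1)
})

test_that("PLS1 weights match a grid-search covariance maximizer on a toy", {
  set.seed(7)
  X <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(4)
  fit <- pls_first_component(X, y)
  Z <- scale(X)
  yc <- y - mean(y)
  grid <- oracle_pls_grid(Z, yc)
  # align orientation before comparing directions
  w_hat <- fit$gene_weights * sign(sum(fit$gene_weights * grid$w))
  expect_gt(sum(w_hat * grid$w), 0.9995)               # cosine similarity
  expect_equal(abs(sum((Z %*% w_hat) * yc)), grid$cov, tolerance = 1e-3)
})

test_that("PLS1 agrees with an established PLS implementation", {
  set.seed(19)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(30, sd = 0.5)
  fit <- pls_first_component(X, y)
  mo <- mixOmics::pls(X, y, ncomp = 1, scale = TRUE, mode = "regression")
  w_ref <- as.numeric(mo$loadings$X[, 1])
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  aligned <- sign(sum(fit$gene_weights * w_ref)) * w_ref
  expect_equal(unname(fit$gene_weights), aligned, tolerance = 1e-6)
})

test_that("zero-variance genes are dropped and degenerate input errors", {
  tmap <- rnorm(10)
  X <- cbind(g1 = tmap + rnorm(10, sd = 0.1), flat = rep(1, 10))
  expect_warning(fit <- pls_first_component(X, tmap), "zero-variance")
  expect_identical(fit$dropped_genes, "flat")
  expect_error(suppressWarnings(
    pls_first_component(cbind(flat = rep(1, 10)), tmap)), "nonzero variance")
})

test_that("permutation p is extreme for planted signal and seed-stable", {
  set.seed(3)
  tmap <- rnorm(40)
  ex <- generate_expression(tmap, n_genes = 50, n_signal = 10,
                            noise_sd = 0.3, seed = 5)
  r <- pls_permutation_p(ex, tmap, n_perm = 199, seed = 7)
  expect_equal(r$p_perm, 1 / 200)
  expect_identical(r, pls_permutation_p(ex, tmap, n_perm = 199, seed = 7))

  # null expression: p is unremarkable
  ex0 <- generate_expression(tmap, n_genes = 50, n_signal = 0, seed = 6)
  r0 <- pls_permutation_p(ex0, tmap, n_perm = 199, seed = 7)
  expect_gt(r0$p_perm, 0.05)
})

test_that("named-gene correlations are Bonferroni-corrected over the query", {
  set.seed(9)
  tmap <- rnorm(30)
  ex <- cbind(hit = tmap, miss1 = rnorm(30), miss2 = rnorm(30))
  res <- gene_tmap_correlations(ex, tmap, c("hit", "miss1", "miss2", "gone"))
  expect_equal(res$r[res$gene == "hit"], 1)
  expect_equal(res$p_adjusted, pmin(1, res$p * 3))
  expect_identical(attr(res, "missing_genes"), "gone")
  # querying a single gene leaves p unchanged
  one <- gene_tmap_correlations(ex, tmap, "miss1")
  expect_equal(one$p_adjusted, one$p)
  # 13 null genes at Bonferroni 0.05: false positives are rare
  fp <- replicate(100, {
    exn <- matrix(rnorm(30 * 13), 30, 13,
                  dimnames = list(NULL, paste0("n", 1:13)))
    sum(gene_tmap_correlations(exn, tmap, colnames(exn))$p_adjusted < 0.05)
  })
  expect_lte(mean(fp), 0.1)
})

test_that("ranked export sorts by weight with lexicographic ties", {
  w <- c(gene1 = 0.5, gene2 = -0.2, gene3 = 0.9)
  out <- export_ranked_genes(w)
  expect_identical(out$gene, c("gene3", "gene1", "gene2"))
  tied <- c(b = 0.5, a = 0.5, c = 0.1)
  expect_identical(export_ranked_genes(tied)$gene, c("a", "b", "c"))
  # round trip through the file preserves the order
  tf <- tempfile(fileext = ".txt")
  export_ranked_genes(w, tf)
  expect_identical(readLines(tf), c("gene3", "gene1", "gene2"))
  expect_error(export_ranked_genes(c(a = NaN)), "finite")
})

test_that("planted signal genes rank in the top decile of PLS weights", {
  set.seed(25)
  tmap <- rnorm(40)
  ex <- generate_expression(tmap, n_genes = 100, n_signal = 10,
                            noise_sd = 0.5, seed = 11)
  fit <- pls_first_component(ex, tmap)
  ranking <- export_ranked_genes(fit)$gene
  pos <- match(attr(ex, "signal_genes"), ranking)
  expect_lte(max(pos), 10)   # all ten planted genes in the top decile
})
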