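# Independent brute-force oracles used to validate the fast implementations.
# These are written as naive explicit loops on purpose.

# count co-occurring bin pairs by enumerating every voxel pair explicitly
oracle_glcm_counts <- function(bins, offset, n_bins, symmetric = TRUE) {
  d <- dim(bins)
  M <- matrix(0, n_bins, n_bins)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- bins[x, y, z]
    if (is.na(a)) next
    xx <- x + offset[1]; yy <- y + offset[2]; zz <- z + offset[3]
    if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
    b <- bins[xx, yy, zz]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
  }
  if (symmetric) M <- M + t(M)
  M
}

# enumerate runs by walking every line voxel-by-voxel
oracle_glrlm_counts <- function(bins, direction, n_bins) {
  d <- dim(bins)
  runs <- list()
  inside <- function(p) all(p >= 1) && all(p <= d)
  val <- function(p) bins[p[1], p[2], p[3]]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    v <- val(p)
    if (is.na(v)) next
    prev <- p - direction
    if (inside(prev) && !is.na(val(prev)) && val(prev) == v) next  # not a start
    len <- 1
    q <- p + direction
    while (inside(q) && !is.na(val(q)) && val(q) == v) {
      len <- len + 1
      q <- q + direction
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  lmax <- max(vapply(runs, `[`, numeric(1), 2))
  R <- matrix(0, n_bins, lmax)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

# naive GLCM feature formulas, explicit double loops over bin pairs
oracle_glcm_features <- function(P) {
  nb <- nrow(P)
  px <- numeric(nb); py <- numeric(nb)
  for (i in 1:nb) for (j in 1:nb) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mu_x <- 0; mu_y <- 0
  for (i in 1:nb) { mu_x <- mu_x + i * px[i]; mu_y <- mu_y + i * py[i] }
  sd_x <- 0; sd_y <- 0
  for (i in 1:nb) {
    sd_x <- sd_x + (i - mu_x)^2 * px[i]
    sd_y <- sd_y + (i - mu_y)^2 * py[i]
  }
  sd_x <- sqrt(sd_x); sd_y <- sqrt(sd_y)
  p_sum <- numeric(2 * nb); p_diff <- numeric(nb)  # p_diff[k+1] = P(|i-j|=k)
  for (i in 1:nb) for (j in 1:nb) {
    p_sum[i + j] <- p_sum[i + j] + P[i, j]
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + P[i, j]
  }
  ent <- function(p) { s <- 0; for (q in p) if (q > 0) s <- s - q * log2(q); s }
  da <- 0
  for (k in 0:(nb - 1)) da <- da + k * p_diff[k + 1]
  hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:nb) for (j in 1:nb) {
    if (P[i, j] > 0) hxy <- hxy - P[i, j] * log2(P[i, j])
    if (P[i, j] > 0 && px[i] * py[j] > 0) {
      hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j])
    }
    if (px[i] * py[j] > 0) {
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  hx <- ent(px); hy <- ent(py)
  ng <- 0
  for (i in 1:nb) if (px[i] > 0 || py[i] > 0) ng <- ng + 1
  acc <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; sosq <- 0
  id <- 0; idn <- 0; idm <- 0; idmn <- 0; iv <- 0
  for (i in 1:nb) for (j in 1:nb) {
    acc <- acc + i * j * P[i, j]
    cp <- cp + (i + j - mu_x - mu_y)^4 * P[i, j]
    cs <- cs + (i + j - mu_x - mu_y)^3 * P[i, j]
    ct <- ct + (i + j - mu_x - mu_y)^2 * P[i, j]
    con <- con + (i - j)^2 * P[i, j]
    sosq <- sosq + (i - mu_x)^2 * P[i, j]
    id <- id + P[i, j] / (1 + abs(i - j))
    idn <- idn + P[i, j] / (1 + abs(i - j) / ng)
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    idmn <- idmn + P[i, j] / (1 + (i - j)^2 / ng^2)
    if (i != j) iv <- iv + P[i, j] / (i - j)^2
  }
  dvar <- 0
  for (k in 0:(nb - 1)) dvar <- dvar + (k - da)^2 * p_diff[k + 1]
  je <- 0; mp <- 0
  for (i in 1:nb) for (j in 1:nb) {
    je <- je + P[i, j]^2
    if (P[i, j] > mp) mp <- P[i, j]
  }
  corr <- if (sd_x * sd_y > 0) (acc - mu_x * mu_y) / (sd_x * sd_y) else 1
  c(glcm_autocorrelation = acc, glcm_joint_average = mu_x,
    glcm_cluster_prominence = cp, glcm_cluster_shade = cs,
    glcm_cluster_tendency = ct, glcm_contrast = con,
    glcm_correlation = corr, glcm_difference_average = da,
    glcm_difference_entropy = ent(p_diff), glcm_difference_variance = dvar,
    glcm_joint_energy = je, glcm_joint_entropy = hxy,
    glcm_imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    glcm_imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    glcm_id = id, glcm_idn = idn, glcm_idm = idm, glcm_idmn = idmn,
    glcm_inverse_variance = iv, glcm_max_probability = mp,
    glcm_sum_entropy = ent(p_sum), glcm_sum_of_squares = sosq)
}

# naive GLRLM feature formulas with explicit loops
oracle_glrlm_features <- function(R, n_voxels) {
  nr <- sum(R)
  sre <- lre <- lglre <- hglre <- srlgle <- srhgle <- lrlgle <- lrhgle <- 0
  for (i in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    sre <- sre + R[i, l] / l^2
    lre <- lre + R[i, l] * l^2
    lglre <- lglre + R[i, l] / i^2
    hglre <- hglre + R[i, l] * i^2
    srlgle <- srlgle + R[i, l] / (i^2 * l^2)
    srhgle <- srhgle + R[i, l] * i^2 / l^2
    lrlgle <- lrlgle + R[i, l] * l^2 / i^2
    lrhgle <- lrhgle + R[i, l] * i^2 * l^2
  }
  gln <- 0
  for (i in seq_len(nrow(R))) gln <- gln + sum(R[i, ])^2
  rln <- 0
  for (l in seq_len(ncol(R))) rln <- rln + sum(R[, l])^2
  c(glrlm_sre = sre / nr, glrlm_lre = lre / nr, glrlm_gln = gln / nr,
    glrlm_rln = rln / nr, glrlm_rp = nr / n_voxels,
    glrlm_lglre = lglre / nr, glrlm_hglre = hglre / nr,
    glrlm_srlgle = srlgle / nr, glrlm_srhgle = srhgle / nr,
    glrlm_lrlgle = lrlgle / nr, glrlm_lrhgle = lrhgle / nr)
}

# texture part of the 47-feature vector computed entirely through the
# oracle counting + naive formulas, with the same direction-averaging rule
oracle_texture_features <- function(intensity, labels, region_id,
                                    n_bins = 32) {
  mask <- labels == region_id
  x <- intensity[mask]
  bins <- array(NA_integer_, dim = dim(intensity))
  lo <- min(x); hi <- max(x)
  b <- if (hi == lo) rep(1L, length(x)) else
    pmin(as.integer(floor((x - lo) / (hi - lo) * n_bins)) + 1L, n_bins)
  bins[which(mask)] <- b
  offs <- texture_offsets_3d()
  glcm_acc <- NULL; n_used <- 0
  for (r in seq_len(nrow(offs))) {
    M <- oracle_glcm_counts(bins, offs[r, ], n_bins)
    if (sum(M) > 0) {
      f <- oracle_glcm_features(M / sum(M))
      glcm_acc <- if (is.null(glcm_acc)) f else glcm_acc + f
      n_used <- n_used + 1
    }
  }
  glrlm_acc <- NULL
  for (r in seq_len(nrow(offs))) {
    R <- oracle_glrlm_counts(bins, offs[r, ], n_bins)
    f <- oracle_glrlm_features(R, sum(mask))
    glrlm_acc <- if (is.null(glrlm_acc)) f else glrlm_acc + f
  }
  c(glcm_acc / n_used, glrlm_acc / nrow(offs))
}

# maximize cov(Z w, y) over unit directions w on a dense spherical grid
# (3 genes only); returns the best grid direction
oracle_pls_grid <- function(Z, y, n_theta = 200, n_phi = 400) {
  best <- NULL; best_cov <- -Inf
  for (th in seq(0, pi, length.out = n_theta)) {
    st <- sin(th); cth <- cos(th)
    for (ph in seq(0, 2 * pi, length.out = n_phi)) {
      w <- c(st * cos(ph), st * sin(ph), cth)
      cv <- sum((Z %*% w) * y)
      if (cv > best_cov) { best_cov <- cv; best <- w }
    }
  }
  list(w = best, cov = best_cov)
}

# small helper: a toy cohort for pipeline-level tests
toy_cohort <- function(seed = 7, effect_size = 2, n = 40, n_mci = 50,
                       n_regions = 30, n_features = 15,
                       frac_mci_adlike = 514 / 766, noise_sd = 0.5) {
  generate_cohort(cohort_spec(
    n_nc = n, n_mci = n_mci, n_ad = n, n_regions = n_regions,
    n_features = n_features, effect_size = effect_size,
    frac_mci_adlike = frac_mci_adlike, noise_sd = noise_sd, seed = seed))
}
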