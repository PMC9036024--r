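# Regional radiomics feature extraction: 14 first-order intensity features,
# 22 grey-level co-occurrence (GLCM) features and 11 grey-level run-length
# (GLRLM) features per parcellation region of a 3D volume, 47 in total.
# Texture features use fixed-bin-count discretization over the region's own
# min-max range and are averaged over the 13 unique distance-1 3D directions.

#' Canonical radiomics feature names
#'
#' The 47 features computed per region, in the fixed order used throughout
#' the package: 14 first-order, 22 GLCM, 11 GLRLM. The set is a package
#' constant so that an alternative feature list can be swapped in at one
#' place.
#'
#' @return character vector of length 47.
#' @export
r2sn_feature_names <- function() {
  c(
    # first-order (14)
    "fo_mean", "fo_median", "fo_minimum", "fo_maximum", "fo_range",
    "fo_variance", "fo_stddev", "fo_skewness", "fo_kurtosis", "fo_energy",
    "fo_rms", "fo_mad", "fo_entropy", "fo_uniformity",
    # GLCM (22)
    "glcm_autocorrelation", "glcm_joint_average", "glcm_cluster_prominence",
    "glcm_cluster_shade", "glcm_cluster_tendency", "glcm_contrast",
    "glcm_correlation", "glcm_difference_average", "glcm_difference_entropy",
    "glcm_difference_variance", "glcm_joint_energy", "glcm_joint_entropy",
    "glcm_imc1", "glcm_imc2", "glcm_id", "glcm_idn", "glcm_idm", "glcm_idmn",
    "glcm_inverse_variance", "glcm_max_probability", "glcm_sum_entropy",
    "glcm_sum_of_squares",
    # GLRLM (11)
    "glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_rp",
    "glrlm_lglre", "glrlm_hglre", "glrlm_srlgle", "glrlm_srhgle",
    "glrlm_lrlgle", "glrlm_lrhgle"
  )
}

#' The 13 unique 3D displacement directions at distance 1
#'
#' One representative of each +/- pair of the 26-neighbourhood, i.e. the
#' standard isotropic offset set for 3D texture matrices.
#'
#' @return integer matrix, 13 rows x 3 columns.
#' @export
texture_offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # keep one of each antipodal pair: first nonzero component positive
  keep <- apply(g, 1L, function(v) v[which(v != 0)[1L]] > 0)
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Texture matrix configuration
#'
#' @param n_bins number of discretization bins (fixed bin count over the
#'   region's min-max range); default 32.
#' @param offsets integer matrix of 3D voxel displacements, one per row.
#' @param symmetric should co-occurrence counts be symmetrised; default TRUE.
#' @param normalization should co-occurrence counts be normalized to a joint
#'   probability distribution before computing features; default TRUE.
#' @return a list of class \code{texture_config}.
#' @export
texture_config <- function(n_bins = 32L, offsets = texture_offsets_3d(),
                           symmetric = TRUE, normalization = TRUE) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be >= 2")
  offsets <- as.matrix(offsets)
  if (nrow(offsets) < 1L || ncol(offsets) != 3L) {
    stop("offsets must be a nonempty matrix with 3 columns")
  }
  structure(list(n_bins = n_bins, offsets = offsets,
                 symmetric = isTRUE(symmetric),
                 normalization = isTRUE(normalization)),
            class = "texture_config")
}

#' Discretize intensities with a fixed bin count over their own range
#'
#' @param x numeric vector of intensities.
#' @param n_bins number of bins.
#' @return integer bins in 1..n_bins; all 1 when x is constant.
#' @keywords internal
discretize_fixed_bins <- function(x, n_bins) {
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) return(rep.int(1L, length(x)))
  b <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  pmin.int(as.integer(b), as.integer(n_bins))
}

#' Grey-level co-occurrence matrix of a masked region
#'
#' Counts co-occurring discretized-intensity pairs at a given voxel
#' displacement, restricted to voxel pairs that both lie inside the region
#' mask.
#'
#' @param bins 3D integer array of bin indices, NA outside the region.
#' @param offset integer displacement c(dx, dy, dz).
#' @param n_bins number of bins (matrix dimension).
#' @param symmetric if TRUE, add the transposed counts (pairs counted in both
#'   directions).
#' @param normalize if TRUE, divide by the total count so the matrix is a
#'   joint probability distribution (all-zero matrices are returned as is).
#' @return n_bins x n_bins numeric matrix.
#' @export
cooccurrence_matrix <- function(bins, offset, n_bins,
                                symmetric = TRUE, normalize = FALSE) {
  stopifnot(length(dim(bins)) == 3L, length(offset) == 3L)
  dims <- dim(bins)
  idx <- which(!is.na(bins), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty region: no voxels in mask")
  nb <- idx
  nb[, 1L] <- nb[, 1L] + offset[1L]
  nb[, 2L] <- nb[, 2L] + offset[2L]
  nb[, 3L] <- nb[, 3L] + offset[3L]
  ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
  m <- matrix(0, n_bins, n_bins)
  if (any(ok)) {
    a <- bins[idx[ok, , drop = FALSE]]
    b <- bins[nb[ok, , drop = FALSE]]
    keep <- !is.na(b)
    if (any(keep)) {
      k <- (a[keep] - 1L) * n_bins + b[keep]
      tab <- tabulate(k, nbins = n_bins * n_bins)
      m <- matrix(tab, n_bins, n_bins, byrow = TRUE)
    }
  }
  if (symmetric) m <- m + t(m)
  if (normalize && sum(m) > 0) m <- m / sum(m)
  m
}

# entropy helper, base-2 logs, 0 log 0 := 0
entropy2 <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

#' GLCM features from a joint probability matrix
#'
#' @param P n_bins x n_bins joint probability matrix (sums to 1).
#' @return named numeric vector of the 22 GLCM features.
#' @keywords internal
glcm_features <- function(P) {
  nb <- nrow(P)
  i <- seq_len(nb)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(i * px)
  mu_y <- sum(i * py)
  sd_x <- sqrt(sum((i - mu_x)^2 * px))
  sd_y <- sqrt(sum((i - mu_y)^2 * py))
  II <- matrix(i, nb, nb)
  JJ <- t(II)
  # distributions of i+j and |i-j|
  sums <- 2:(2 * nb)
  p_sum <- vapply(sums, function(k) sum(P[II + JJ == k]), numeric(1))
  diffs <- 0:(nb - 1L)
  p_diff <- vapply(diffs, function(k) sum(P[abs(II - JJ) == k]), numeric(1))
  da <- sum(diffs * p_diff)

  hxy <- entropy2(P)
  hx <- entropy2(px)
  hy <- entropy2(py)
  pxpy <- outer(px, py)
  sel <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[sel] * log2(pxpy[sel]))
  hxy2 <- entropy2(pxpy)

  corr <- if (sd_x * sd_y > 0) {
    (sum(II * JJ * P) - mu_x * mu_y) / (sd_x * sd_y)
  } else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  ng <- sum(px > 0 | py > 0)    # number of grey levels present
  off_diag <- abs(II - JJ) > 0

  c(
    glcm_autocorrelation = sum(II * JJ * P),
    glcm_joint_average = mu_x,
    glcm_cluster_prominence = sum((II + JJ - mu_x - mu_y)^4 * P),
    glcm_cluster_shade = sum((II + JJ - mu_x - mu_y)^3 * P),
    glcm_cluster_tendency = sum((II + JJ - mu_x - mu_y)^2 * P),
    glcm_contrast = sum((II - JJ)^2 * P),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = entropy2(p_diff),
    glcm_difference_variance = sum((diffs - da)^2 * p_diff),
    glcm_joint_energy = sum(P^2),
    glcm_joint_entropy = hxy,
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_id = sum(P / (1 + abs(II - JJ))),
    glcm_idn = sum(P / (1 + abs(II - JJ) / ng)),
    glcm_idm = sum(P / (1 + (II - JJ)^2)),
    glcm_idmn = sum(P / (1 + (II - JJ)^2 / ng^2)),
    glcm_inverse_variance = sum(P[off_diag] / (II - JJ)[off_diag]^2),
    glcm_max_probability = max(P),
    glcm_sum_entropy = entropy2(p_sum),
    glcm_sum_of_squares = sum((II - mu_x)^2 * P)
  )
}

#' Grey-level run-length matrix of a masked region along one direction
#'
#' A run is a maximal sequence of consecutive in-mask voxels along the
#' direction sharing the same bin; voxels outside the mask break runs.
#'
#' @param bins 3D integer array of bin indices, NA outside the region.
#' @param direction integer displacement c(dx, dy, dz).
#' @param n_bins number of bins.
#' @return n_bins x L counts matrix, L = longest observed run.
#' @export
runlength_matrix <- function(bins, direction, n_bins) {
  stopifnot(length(dim(bins)) == 3L, length(direction) == 3L)
  dims <- dim(bins)
  idx <- which(!is.na(bins), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty region: no voxels in mask")

  shift_ok <- function(coord, d) {
    nb <- coord
    nb[, 1L] <- nb[, 1L] + d[1L]
    nb[, 2L] <- nb[, 2L] + d[2L]
    nb[, 3L] <- nb[, 3L] + d[3L]
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    list(coord = nb, ok = ok)
  }

  v <- bins[idx]
  # run starts: predecessor out of grid, out of mask, or different bin
  prev <- shift_ok(idx, -direction)
  pv <- rep(NA_integer_, nrow(idx))
  pv[prev$ok] <- bins[prev$coord[prev$ok, , drop = FALSE]]
  starts <- is.na(pv) | pv != v

  start_coord <- idx[starts, , drop = FALSE]
  start_bin <- v[starts]
  run_len <- rep.int(1L, nrow(start_coord))
  cur <- start_coord
  active <- seq_len(nrow(start_coord))
  while (length(active) > 0L) {
    nxt <- shift_ok(cur[active, , drop = FALSE], direction)
    nv <- rep(NA_integer_, length(active))
    nv[nxt$ok] <- bins[nxt$coord[nxt$ok, , drop = FALSE]]
    cont <- !is.na(nv) & nv == start_bin[active]
    run_len[active[cont]] <- run_len[active[cont]] + 1L
    cur[active[cont], ] <- nxt$coord[cont, , drop = FALSE]
    active <- active[cont]
  }

  lmax <- max(run_len)
  R <- matrix(0, n_bins, lmax)
  k <- (start_bin - 1L) * lmax + run_len
  tab <- tabulate(k, nbins = n_bins * lmax)
  matrix(tab, n_bins, lmax, byrow = TRUE)
}

#' GLRLM features from a run-length counts matrix
#'
#' @param R n_bins x L run counts.
#' @param n_voxels number of voxels in the region.
#' @return named numeric vector of the 11 GLRLM features.
#' @keywords internal
glrlm_features <- function(R, n_voxels) {
  nr <- sum(R)
  i <- seq_len(nrow(R))
  l <- seq_len(ncol(R))
  I2 <- matrix(i^2, nrow(R), ncol(R))
  L2 <- matrix(l^2, nrow(R), ncol(R), byrow = TRUE)
  c(
    glrlm_sre = sum(R / L2) / nr,
    glrlm_lre = sum(R * L2) / nr,
    glrlm_gln = sum(rowSums(R)^2) / nr,
    glrlm_rln = sum(colSums(R)^2) / nr,
    glrlm_rp = nr / n_voxels,
    glrlm_lglre = sum(R / I2) / nr,
    glrlm_hglre = sum(R * I2) / nr,
    glrlm_srlgle = sum(R / (I2 * L2)) / nr,
    glrlm_srhgle = sum(R * I2 / L2) / nr,
    glrlm_lrlgle = sum(R * L2 / I2) / nr,
    glrlm_lrhgle = sum(R * I2 * L2) / nr
  )
}

first_order_features <- function(x, n_bins) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)           # population moments
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  b <- discretize_fixed_bins(x, n_bins)
  p <- tabulate(b, nbins = n_bins)
  p <- p / sum(p)
  c(
    fo_mean = mu,
    fo_median = stats::median(x),
    fo_minimum = min(x),
    fo_maximum = max(x),
    fo_range = max(x) - min(x),
    fo_variance = m2,
    fo_stddev = sqrt(m2),
    fo_skewness = skew,
    fo_kurtosis = kurt,
    fo_energy = sum(x^2),
    fo_rms = sqrt(mean(x^2)),
    fo_mad = mean(abs(x - mu)),
    fo_entropy = entropy2(p),
    fo_uniformity = sum(p^2)
  )
}

#' Extract the 47 radiomics features of one parcellation region
#'
#' First-order features are computed on the raw intensities; GLCM and GLRLM
#' features on intensities discretized with a fixed bin count over the
#' region's min-max range, averaged over the configured directions. A
#' constant-intensity region falls back to a single-bin texture matrix
#' (entropy 0, variance 0).
#'
#' @param intensity 3D numeric array.
#' @param labels 3D integer array, same dimensions, region labels.
#' @param region_id the label to extract.
#' @param cfg a \code{\link{texture_config}}.
#' @return named numeric vector of length 47 with attributes
#'   \code{region_id} and \code{n_voxels}.
#' @export
extract_region_features <- function(intensity, labels, region_id,
                                    cfg = texture_config()) {
  if (!identical(dim(intensity), dim(labels))) {
    stop("intensity and labels must have identical dimensions")
  }
  mask <- which(labels == region_id)
  if (length(mask) == 0L) {
    stop("empty region: label ", region_id, " has no voxels")
  }
  x <- intensity[mask]
  fo <- first_order_features(x, cfg$n_bins)

  bins <- array(NA_integer_, dim = dim(intensity))
  bins[mask] <- discretize_fixed_bins(x, cfg$n_bins)

  # GLCM: average features over directions with at least one voxel pair
  glcm_acc <- NULL
  n_used <- 0L
  for (r in seq_len(nrow(cfg$offsets))) {
    M <- cooccurrence_matrix(bins, cfg$offsets[r, ], cfg$n_bins,
                             symmetric = cfg$symmetric, normalize = FALSE)
    if (sum(M) > 0) {
      P <- if (cfg$normalization) M / sum(M) else M
      f <- glcm_features(P)
      glcm_acc <- if (is.null(glcm_acc)) f else glcm_acc + f
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) {
    # no in-mask voxel pairs at any offset (e.g. single voxel): single-bin
    P1 <- matrix(0, cfg$n_bins, cfg$n_bins)
    P1[1L, 1L] <- 1
    glcm_acc <- glcm_features(P1)
    n_used <- 1L
  }
  glcm <- glcm_acc / n_used

  glrlm_acc <- NULL
  for (r in seq_len(nrow(cfg$offsets))) {
    R <- runlength_matrix(bins, cfg$offsets[r, ], cfg$n_bins)
    f <- glrlm_features(R, length(mask))
    glrlm_acc <- if (is.null(glrlm_acc)) f else glrlm_acc + f
  }
  glrlm <- glrlm_acc / nrow(cfg$offsets)

  out <- c(fo, glcm, glrlm)
  stopifnot(identical(names(out), r2sn_feature_names()))
  attr(out, "region_id") <- region_id
  attr(out, "n_voxels") <- length(mask)
  out
}

#' Extract the regional feature matrix of one subject
#'
#' @param intensity 3D numeric array.
#' @param labels 3D integer array of region labels (same grid).
#' @param atlas_regions ordered region labels defining the row order;
#'   defaults to the sorted nonzero labels present.
#' @param cfg a \code{\link{texture_config}}.
#' @param subject_id identifier stored as an attribute.
#' @param missing_action what to do when an atlas region has no voxels:
#'   \code{"error"} (default) or \code{"nan"} for an all-NaN row.
#' @return regions x 47 numeric matrix, rows named by region label, columns
#'   by \code{\link{r2sn_feature_names}}.
#' @export
extract_subject_features <- function(intensity, labels,
                                     atlas_regions = NULL,
                                     cfg = texture_config(),
                                     subject_id = NA_character_,
                                     missing_action = c("error", "nan")) {
  missing_action <- match.arg(missing_action)
  if (is.null(atlas_regions)) {
    atlas_regions <- sort(unique(as.vector(labels)))
    atlas_regions <- atlas_regions[atlas_regions != 0]
  }
  fn <- r2sn_feature_names()
  out <- matrix(NA_real_, length(atlas_regions), length(fn),
                dimnames = list(as.character(atlas_regions), fn))
  for (k in seq_along(atlas_regions)) {
    rid <- atlas_regions[k]
    if (!any(labels == rid)) {
      if (missing_action == "error") {
        stop("atlas region ", rid, " missing from label volume")
      }
      out[k, ] <- NaN
      next
    }
    out[k, ] <- extract_region_features(intensity, labels, rid, cfg)
  }
  attr(out, "subject_id") <- subject_id
  out
}
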