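# Synthetic cohorts with the statistical structure the pipeline assumes:
# three diagnostic groups whose regional feature profiles make AD-like
# networks separable from NC-like ones, an MCI mixture of the two latent
# patterns, annual follow-up visits with pattern-dependent cognitive
# decline and conversion hazard, and regional gene expression with a
# planted subset spatially correlated to a group-difference map.

#' Specification of a synthetic cohort
#'
#' Defaults encode the study conditions the generator emulates: the
#' AD-like fraction of MCI matches the reported subtype split (514/766);
#' the NC-like monthly conversion hazard gives a 21.77% three-year
#' conversion and the default hazard ratio raises the AD-like pattern to
#' 61.54%; follow-up is six annual visits.
#'
#' @param n_nc,n_mci,n_ad group sizes (all > 0).
#' @param n_regions number of atlas regions; default 246.
#' @param n_features number of radiomics features; default 47.
#' @param effect_size magnitude of the shift subtracted from the
#'   atrophy-region feature means of AD-pattern subjects (each atrophy
#'   region loses its own fixed nonnegative mix of features); default 2.
#' @param frac_mci_adlike probability an MCI subject carries the AD
#'   pattern; default 514/766.
#' @param noise_sd sd of i.i.d. measurement noise on every feature entry;
#'   default 0.5.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @param n_visits number of annual follow-up visits; default 6.
#' @param hazard_ratio_adlike conversion-hazard ratio of the AD-like
#'   pattern (> 1); default log(1-0.6154)/log(1-0.2177) ~= 3.89.
#' @return a validated list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_nc, n_mci, n_ad, n_regions = 246L,
                        n_features = 47L, effect_size = 2,
                        frac_mci_adlike = 514 / 766, noise_sd = 0.5,
                        seed = 1L, n_visits = 6L,
                        hazard_ratio_adlike = log(1 - 0.6154) / log(1 - 0.2177)) {
  counts <- c(n_nc = n_nc, n_mci = n_mci, n_ad = n_ad,
              n_regions = n_regions, n_features = n_features,
              n_visits = n_visits)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("all counts must be positive integers")
  }
  if (frac_mci_adlike < 0 || frac_mci_adlike > 1) {
    stop("frac_mci_adlike must be in [0, 1]")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (hazard_ratio_adlike <= 1) stop("hazard_ratio_adlike must be > 1")
  structure(list(n_nc = as.integer(n_nc), n_mci = as.integer(n_mci),
                 n_ad = as.integer(n_ad), n_regions = as.integer(n_regions),
                 n_features = as.integer(n_features),
                 effect_size = effect_size,
                 frac_mci_adlike = frac_mci_adlike, noise_sd = noise_sd,
                 seed = as.integer(seed), n_visits = as.integer(n_visits),
                 hazard_ratio_adlike = hazard_ratio_adlike),
            class = "cohort_spec")
}

# baseline mean/sd of each clinical measure per stratum
# (NC, NC-like MCI, AD-like MCI, AD); values emulate typical aging-cohort
# magnitudes with AD-like MCI intermediate between NC-like MCI and AD
measure_params <- function() {
  list(
    MMSE      = rbind(c(29.1, 1.1), c(27.7, 1.8), c(26.5, 1.8), c(23.2, 2.1)),
    ADAS_cog11 = rbind(c(6, 3), c(9, 4), c(12, 4.5), c(19, 6)),
    ADAS_cog13 = rbind(c(9, 4), c(14, 6), c(19, 6.5), c(29, 8)),
    AVLT1     = rbind(c(45, 10), c(38, 10), c(30, 9), c(23, 8)),
    AVLT2     = rbind(c(6, 2), c(5, 2.2), c(3.5, 2.2), c(1.8, 1.8)),
    PHS       = rbind(c(0, 1), c(0.1, 1), c(0.4, 1), c(0.6, 1)),
    FDG       = rbind(c(1.3, 0.11), c(1.25, 0.12), c(1.15, 0.12), c(1.05, 0.12)),
    CSF_Abeta = rbind(c(1200, 300), c(1050, 280), c(800, 230), c(700, 200)),
    CSF_Tau   = rbind(c(230, 85), c(250, 95), c(330, 120), c(370, 130)),
    CSF_Ptau  = rbind(c(21, 9), c(24, 11), c(33, 14), c(37, 15))
  )
}

# annual change of the longitudinal measures per stratum (same order)
trajectory_rates <- function() {
  list(MMSE = c(-0.05, -0.3, -1.2, -2.0),
       ADAS_cog13 = c(0.2, 0.8, 2.5, 4.0),
       CDR_SB = c(0.02, 0.2, 0.9, 1.6))
}

feature_names_for <- function(n_features) {
  if (n_features == 47L) r2sn_feature_names()
  else sprintf("f%03d", seq_len(n_features))
}

# observed feature matrices = latent means + fresh noise
observe_features <- function(latent, noise_sd) {
  lapply(latent$means, function(m) {
    m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m), ncol(m),
               dimnames = dimnames(m))
  })
}

#' Generate a synthetic three-group cohort
#'
#' NC subjects are drawn from a base regional feature template plus noise;
#' AD subjects from the template with \code{effect_size} subtracted on a
#' fixed 20% subset of "atrophy" regions, each region losing its own fixed
#' nonnegative mix of features; MCI subjects carry the AD pattern with
#' probability
#' \code{frac_mci_adlike}. Annual follow-up visits decline at a
#' pattern-dependent rate; MCI conversion times are exponential with the
#' spec's hazard ratio and administratively censored at the last visit.
#' Latent pattern labels and true conversion times are emitted only in the
#' truth table.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list of class \code{synthetic_cohort}: \code{feature_matrices}
#'   (named list of regions x features matrices), \code{phenotypes}
#'   (baseline data.frame), \code{visits} (long-format per-visit table),
#'   \code{truth} (latent pattern, true conversion time), \code{latent}
#'   (template/shift internals, used for re-observation), \code{spec}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- spec$n_regions
  Fn <- spec$n_features
  fnames <- feature_names_for(Fn)
  rnames <- sprintf("R%03d", seq_len(R))
  n <- spec$n_nc + spec$n_mci + spec$n_ad
  ids <- sprintf("S%04d", seq_len(n))
  diagnosis <- rep(c("NC", "MCI", "AD"),
                   c(spec$n_nc, spec$n_mci, spec$n_ad))

  with_seed(spec$seed, {
    template <- matrix(stats::rnorm(R * Fn), R, Fn,
                       dimnames = list(rnames, fnames))
    atrophy <- sort(sample.int(R, max(1L, ceiling(0.2 * R))))
    # region-specific nonnegative shift directions: each atrophy region
    # loses a different mix of features, so edges between atrophy regions
    # (and to their neighbours) decorrelate focally
    delta <- matrix(abs(stats::rnorm(length(atrophy) * Fn)),
                    length(atrophy), Fn)
    shift <- matrix(0, R, Fn)
    shift[atrophy, ] <- spec$effect_size * delta

    pattern <- ifelse(diagnosis == "AD", 1L,
               ifelse(diagnosis == "NC", 0L,
                      stats::rbinom(n, 1L, spec$frac_mci_adlike)))

    means <- lapply(seq_len(n), function(s) {
      template - pattern[s] * shift
    })
    names(means) <- ids
    latent <- list(means = means, template = template, atrophy = atrophy,
                   delta = delta, pattern = stats::setNames(pattern, ids))
    fms <- observe_features(latent, spec$noise_sd)

    # stratum index: NC=1, NC-like MCI=2, AD-like MCI=3, AD=4
    stratum <- ifelse(diagnosis == "NC", 1L,
               ifelse(diagnosis == "AD", 4L,
                      ifelse(pattern == 1L, 3L, 2L)))
    age_par <- rbind(c(73, 6), c(68.6, 7.3), c(75.1, 7.0), c(75, 7.8))
    pheno <- data.frame(
      subject_id = ids, diagnosis = diagnosis,
      age = round(pmax(55, stats::rnorm(n, age_par[stratum, 1L],
                                        age_par[stratum, 2L])), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (m in names(measure_params())) {
      par <- measure_params()[[m]]
      v <- stats::rnorm(n, par[stratum, 1L], par[stratum, 2L])
      if (m == "MMSE") v <- pmin(30, v)
      if (m %in% c("CSF_Abeta", "CSF_Tau", "CSF_Ptau", "FDG", "AVLT1")) {
        v <- pmax(v, 1e-3)
      }
      pheno[[m]] <- round(v, 2)
    }

    # conversion: exponential hazard, NC-like calibrated to 21.77% at 36 mo
    lambda_nc <- -log(1 - 0.2177) / 36
    hazard <- lambda_nc * ifelse(pattern == 1L, spec$hazard_ratio_adlike, 1)
    true_time <- stats::rexp(n, rate = hazard)
    horizon <- 12 * spec$n_visits
    conv_month <- 12 * ceiling(true_time / 12)
    converts <- diagnosis == "MCI" & conv_month <= horizon

    rates <- trajectory_rates()
    cdr_base <- c(0, 0.5, 0.5, 1)[stratum] +
      round(stats::rnorm(n, 0, 0.1), 2)
    months <- seq(0, horizon, by = 12)
    visits <- do.call(rbind, lapply(seq_len(n), function(s) {
      yr <- months / 12
      dx <- rep(diagnosis[s], length(months))
      if (diagnosis[s] == "MCI" && converts[s]) {
        dx[months >= conv_month[s]] <- "AD"
      }
      data.frame(
        subject_id = ids[s], month = months, diagnosis = dx,
        MMSE = round(pmin(30, pheno$MMSE[s] + rates$MMSE[stratum[s]] * yr +
                            stats::rnorm(length(yr), 0, 1)), 1),
        ADAS_cog13 = round(pheno$ADAS_cog13[s] +
                             rates$ADAS_cog13[stratum[s]] * yr +
                             stats::rnorm(length(yr), 0, 2), 1),
        CDR_SB = round(pmax(0, cdr_base[s] + rates$CDR_SB[stratum[s]] * yr +
                              stats::rnorm(length(yr), 0, 0.2)), 2),
        stringsAsFactors = FALSE
      )
    }))

    truth <- data.frame(
      subject_id = ids, diagnosis = diagnosis,
      pattern = ifelse(pattern == 1L, "AD-like", "NC-like"),
      true_conversion_months = true_time,
      stringsAsFactors = FALSE
    )
    attr(truth, "atrophy_regions") <- rnames[atrophy]
    # edges between two shifted regions: the focally perturbed connections
    ei <- edge_index(rnames)
    attr(truth, "planted_edges") <- ei$id[ei$i %in% atrophy & ei$j %in% atrophy]

    structure(list(feature_matrices = fms, phenotypes = pheno,
                   visits = visits, truth = truth, latent = latent,
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d NC / %d MCI / %d AD; %d regions x %d features\n",
    x$spec$n_nc, x$spec$n_mci, x$spec$n_ad, x$spec$n_regions,
    x$spec$n_features))
  invisible(x)
}

#' Re-observe a cohort with fresh measurement noise
#'
#' Draws a new noise realization around the same latent subject means —
#' the same anatomy seen through a second, perturbed measurement (e.g. a
#' different parcellation's sampling). Phenotypes, visits and truth are
#' unchanged.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param seed integer seed for the new observation.
#' @param noise_sd noise level; defaults to the cohort spec's.
#' @return a \code{synthetic_cohort} with new \code{feature_matrices}.
#' @export
reobserve_cohort <- function(cohort, seed, noise_sd = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  noise_sd <- noise_sd %||% cohort$spec$noise_sd
  cohort$feature_matrices <- with_seed(seed, {
    observe_features(cohort$latent, noise_sd)
  })
  cohort
}

# split n into k contiguous chunk sizes as evenly as possible
even_chunks <- function(n, k) {
  base <- n %/% k
  sizes <- rep.int(base, k)
  extra <- n - base * k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate a labeled synthetic volume
#'
#' Partitions a compact voxel grid into \code{n_regions} contiguous boxes
#' (slabs along z, rows along y, columns along x) labeled 1..n_regions, and
#' draws each region's intensities from a region-specific distribution
#' (its own mean, spread and spatial gradient) so that intensity and
#' texture features differ between regions.
#'
#' @param n_regions number of regions (>= 2).
#' @param shape integer grid dimensions c(nx, ny, nz).
#' @param seed integer seed.
#' @param min_voxels minimum region size; default 27.
#' @return list with \code{intensity} (3D numeric array) and \code{labels}
#'   (3D integer array).
#' @export
generate_labeled_volume <- function(n_regions, shape = c(24L, 24L, 24L),
                                    seed = 1L, min_voxels = 27L) {
  n_regions <- as.integer(n_regions)
  shape <- as.integer(shape)
  if (n_regions < 2L) stop("n_regions must be >= 2")
  if (prod(shape) < n_regions * min_voxels) {
    stop("grid too small: ", prod(shape), " voxels for ", n_regions,
         " regions of >= ", min_voxels, " voxels")
  }
  k3 <- max(1L, min(shape[3L], round(n_regions^(1 / 3))))
  per_slab <- even_chunks(n_regions, k3)
  z_sizes <- even_chunks(shape[3L], k3)
  labels <- array(0L, dim = shape)
  lab <- 0L
  z0 <- 0L
  for (s in seq_len(k3)) {
    zr <- (z0 + 1L):(z0 + z_sizes[s])
    z0 <- z0 + z_sizes[s]
    m <- per_slab[s]
    k2 <- max(1L, min(shape[2L], round(sqrt(m))))
    per_row <- even_chunks(m, k2)
    y_sizes <- even_chunks(shape[2L], k2)
    y0 <- 0L
    for (r in seq_len(k2)) {
      yr <- (y0 + 1L):(y0 + y_sizes[r])
      y0 <- y0 + y_sizes[r]
      q <- per_row[r]
      if (q > shape[1L]) stop("grid too small along x for the region count")
      x_sizes <- even_chunks(shape[1L], q)
      x0 <- 0L
      for (cidx in seq_len(q)) {
        xr <- (x0 + 1L):(x0 + x_sizes[cidx])
        x0 <- x0 + x_sizes[cidx]
        lab <- lab + 1L
        labels[xr, yr, zr] <- lab
      }
    }
  }
  counts <- tabulate(labels, nbins = n_regions)
  if (any(counts < min_voxels)) {
    stop("grid too small: smallest region has ", min(counts),
         " voxels (need >= ", min_voxels, ")")
  }
  intensity <- with_seed(seed, {
    mu <- stats::runif(n_regions, 50, 150)
    sdv <- stats::runif(n_regions, 5, 25)
    grad_axis <- sample.int(3L, n_regions, replace = TRUE)
    grad_amp <- stats::runif(n_regions, -20, 20)
    coords <- list(
      slice.index(labels, 1L) / shape[1L],
      slice.index(labels, 2L) / shape[2L],
      slice.index(labels, 3L) / shape[3L]
    )
    out <- array(0, dim = shape)
    for (g in seq_len(n_regions)) {
      w <- labels == g
      out[w] <- mu[g] + grad_amp[g] * coords[[grad_axis[g]]][w] +
        stats::rnorm(sum(w), 0, sdv[g])
    }
    out
  })
  list(intensity = intensity, labels = labels)
}

#' Generate a regional gene expression matrix with planted signal genes
#'
#' \code{n_signal} gene columns are a positive multiple of the supplied
#' per-region statistic plus noise; the remaining columns are pure noise.
#'
#' @param tvals per-region statistic vector (the spatial signal).
#' @param n_genes total number of genes.
#' @param n_signal number of signal genes (<= n_genes).
#' @param noise_sd sd of the additive noise on signal genes.
#' @param seed integer seed.
#' @return regions x genes matrix with gene column names; attributes
#'   \code{signal_genes} (names) and \code{slopes} (the positive
#'   multipliers).
#' @export
generate_expression <- function(tvals, n_genes, n_signal, noise_sd = 1,
                                seed = 1L) {
  if (n_signal > n_genes) stop("n_signal must be <= n_genes")
  R <- length(tvals)
  gnames <- sprintf("gene%04d", seq_len(n_genes))
  with_seed(seed, {
    expr <- matrix(stats::rnorm(R * n_genes), R, n_genes,
                   dimnames = list(names(tvals) %||% sprintf("R%03d", 1:R),
                                   gnames))
    sig <- integer(0)
    slopes <- numeric(0)
    if (n_signal > 0L) {
      sig <- sort(sample.int(n_genes, n_signal))
      slopes <- stats::runif(n_signal, 0.5, 1.5)
      for (k in seq_along(sig)) {
        expr[, sig[k]] <- slopes[k] * tvals +
          stats::rnorm(R, 0, noise_sd)
      }
    }
    attr(expr, "signal_genes") <- gnames[sig]
    attr(expr, "slopes") <- stats::setNames(slopes, gnames[sig])
    expr
  })
}
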