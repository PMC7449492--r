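#' Normalization configuration
#'
#' Parameters of the four-step normalization: LOESS GC correction, PCA
#' residualization against a euploid cohort, bin filtering, per-bin mean
#' subtraction.
#'
#' @param k number of principal components removed (default 15)
#' @param mu_min minimum per-bin cross-cohort mean at the canonical scale;
#'   bins below are filtered (default 3.0, roughly half the ideal mean of
#'   ~6.5 reads per 20 kb bin at the 1M-read-equivalent scale)
#' @param v_max maximum per-bin cross-cohort variance at the canonical
#'   scale (default 1.5)
#' @param span LOESS smoother span for the GC curve (default 0.3)
#' @export
norm_config <- function(k = 15L, mu_min = 3.0, v_max = 1.5, span = 0.3) {
  stopifnot(k >= 1, mu_min >= 0, v_max > 0, span > 0, span <= 1)
  structure(list(k = as.integer(k), mu_min = mu_min, v_max = v_max,
                 span = span), class = "norm_config")
}

#' LOESS-based GC correction
#'
#' Fits a smooth curve of bin count against bin GC fraction over the
#' mappable bins of the sample itself and multiplies each bin by
#' (global mean bin count) / (smoothed expected count at the bin's GC).
#' Bins with GC outside the observed fitting range are corrected with the
#' nearest-edge smoother value and reported in a message.
#'
#' @param profile raw-state [bin_profile()]
#' @param span smoother span
#' @return profile advanced to `gc_corrected` state
#' @export
gc_correct <- function(profile, span = 0.3) {
  require_state(profile, "raw")
  genome <- profile$genome
  gc <- genome$bins$gc
  fit_idx <- genome$bins$mappable & !is.na(gc)
  if (sum(fit_idx) < 100)
    stop("fewer than 100 mappable bins with GC values; smoother underdetermined")
  x <- gc[fit_idx]
  y <- profile$values[fit_idx]
  if (diff(range(x)) < 1e-8) {
    # constant GC: the smoother is flat, correction factor is 1
    expected <- rep(mean(y), genome$n_bins)
  } else {
    lo <- stats::lowess(x, y, f = span)
    outside <- fit_idx & (gc < min(x) | gc > max(x))
    if (any(outside))
      message(sprintf("gc_correct: %d bins outside fitted GC range, using edge value",
                      sum(outside)))
    expected <- stats::approx(lo$x, lo$y, xout = gc, rule = 2,
                              ties = mean)$y
  }
  expected <- pmax(expected, 1e-8)
  v <- profile$values
  v[fit_idx] <- v[fit_idx] * mean(y) / expected[fit_idx]
  profile$values <- v
  advance_state(profile, "gc_corrected")
}

# internal: rescale a gc-corrected value vector to the canonical scale.
# Autosomes are scaled to their share of the canonical total; each sex
# chromosome is rescaled independently (fetal sex and fetal fraction make
# its depth incommensurable with the autosomes). Returns list(values at
# canonical scale, per-group factors).
rescale_canonical <- function(values, genome, S) {
  map <- genome$bins$mappable
  auto <- autosomal_bins(genome)
  groups <- c(list(.auto = which(auto & map)),
              stats::setNames(
                lapply(genome$sex_chroms,
                       function(ch) intersect(chrom_bins(genome, ch), which(map))),
                genome$sex_chroms))
  n_map <- sum(map)
  out <- values
  factors <- numeric(0)
  for (g in names(groups)) {
    idx <- groups[[g]]
    target <- S * length(idx) / n_map
    tot <- sum(values[idx])
    f <- if (tot > 0) target / tot else 0
    out[idx] <- values[idx] * f
    factors[g] <- f
  }
  list(values = out, factors = factors)
}

#' Train a normalization model from a euploid cohort
#'
#' Per training sample: GC correction, rescaling to the canonical read
#' scale, stacking. PCA is fitted on mappable autosomal bins only and the
#' first `k` components stored. Per-bin means and cross-cohort variances
#' are computed at the canonical scale; the bin filter retains mappable
#' bins with mean >= `mu_min` and variance <= `v_max`.
#'
#' @param cohort list of raw-state [bin_profile()]s on a common genome
#' @param config a [norm_config()]
#' @return a `norm_model` with elements `genome`, `config`, `S`
#'   (canonical scale), `auto_idx` (mappable autosomal bin indices),
#'   `pca_mean`, `basis` (bins x k orthonormal), `bin_mean`, `bin_var`,
#'   `mask` (retained bins), `n_train`
#' @export
fit_reference <- function(cohort, config = norm_config()) {
  stopifnot(length(cohort) >= 1)
  genome <- cohort[[1]]$genome
  for (p in cohort)
    if (!same_genome(p$genome, genome))
      stop("cohort profiles have differing genome models")
  if (length(cohort) < 2 * config$k)
    stop(sprintf("need at least 2*k = %d training samples, got %d",
                 2 * config$k, length(cohort)))
  S <- canonical_scale(genome)
  map <- genome$bins$mappable
  auto_idx <- which(autosomal_bins(genome) & map)

  scaled <- matrix(NA_real_, nrow = length(cohort), ncol = genome$n_bins)
  for (i in seq_along(cohort)) {
    gcp <- gc_correct(cohort[[i]], span = config$span)
    scaled[i, ] <- rescale_canonical(gcp$values, genome, S)$values
  }
  M <- scaled[, auto_idx, drop = FALSE]
  pca_mean <- colMeans(M)
  Xc <- sweep(M, 2, pca_mean)
  sv <- svd(Xc, nu = 0, nv = config$k)
  basis <- sv$v  # n_auto x k, orthonormal columns

  bin_mean <- rep(NA_real_, genome$n_bins)
  bin_var <- rep(NA_real_, genome$n_bins)
  bin_mean[map] <- colMeans(scaled[, map, drop = FALSE])
  bin_var[map] <- apply(scaled[, map, drop = FALSE], 2, stats::var)
  mask <- map & !is.na(bin_mean) & bin_mean >= config$mu_min &
    bin_var <= config$v_max
  mask[is.na(mask)] <- FALSE

  structure(
    list(genome = genome, config = config, S = S, auto_idx = auto_idx,
         pca_mean = pca_mean, basis = basis, bin_mean = bin_mean,
         bin_var = bin_var, mask = mask, n_train = length(cohort)),
    class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("norm_model: %d training samples, k=%d, canonical scale %.0f reads\n",
              x$n_train, x$config$k, x$S))
  cat(sprintf("  retained %d / %d mappable bins (%.1f%%)\n",
              sum(x$mask), sum(x$genome$bins$mappable),
              100 * retained_fraction(x)))
  invisible(x)
}

#' Fraction of mappable bins retained by the filter
#' @param model a fitted `norm_model`
#' @export
retained_fraction <- function(model) {
  stopifnot(inherits(model, "norm_model"))
  sum(model$mask) / sum(model$genome$bins$mappable)
}

#' Remove cohort principal components from a sample
#'
#' The autosomal value vector is rescaled to the canonical scale, offset
#' by the training mean, has its projection onto the stored `k`
#' components subtracted, and is returned to the sample's own scale. Sex
#' chromosome bins pass through unchanged.
#'
#' @param profile gc_corrected-state [bin_profile()]
#' @param model a fitted `norm_model`
#' @return profile advanced to `pca_normalized` state
#' @export
pca_normalize <- function(profile, model) {
  require_state(profile, "gc_corrected")
  if (!same_genome(profile$genome, model$genome))
    stop("profile and model genomes differ")
  v <- profile$values
  idx <- model$auto_idx
  tot <- sum(v[idx])
  if (tot <= 0) stop("no autosomal signal to normalize")
  target <- model$S * length(idx) / sum(model$genome$bins$mappable)
  f <- target / tot
  y <- v[idx] * f - model$pca_mean
  proj <- model$basis %*% crossprod(model$basis, y)
  v[idx] <- (model$pca_mean + y - as.numeric(proj)) / f
  profile$values <- v
  advance_state(profile, "pca_normalized")
}

#' Subtract stored per-bin means
#'
#' Per-bin means are stored at the canonical scale; they are rescaled to
#' the sample's own depth before subtraction so the centered values stay
#' on the sample's count scale (the scale the calling thresholds use).
#' Each sex chromosome is rescaled independently of the autosomes. Bins
#' outside the filter mask are set to `NA` (absent from segmentation).
#'
#' @param profile pca_normalized-state [bin_profile()]
#' @param model a fitted `norm_model`
#' @return profile advanced to `centered` state with attributes
#'   `mb` (the sample's mean retained autosomal bin count at its own
#'   scale) and `scale_factors`
#' @export
center_profile <- function(profile, model) {
  require_state(profile, "pca_normalized")
  if (!same_genome(profile$genome, model$genome))
    stop("profile and model genomes differ")
  genome <- model$genome
  v <- profile$values
  map <- genome$bins$mappable
  auto <- autosomal_bins(genome)
  centered <- rep(NA_real_, genome$n_bins)
  groups <- c(list(.auto = which(auto & map)),
              stats::setNames(
                lapply(genome$sex_chroms,
                       function(ch) intersect(chrom_bins(genome, ch), which(map))),
                genome$sex_chroms))
  factors <- numeric(0)
  for (g in names(groups)) {
    idx <- groups[[g]]
    denom <- sum(model$bin_mean[idx])
    phi <- if (denom > 0) sum(v[idx]) / denom else NA_real_
    centered[idx] <- v[idx] - phi * model$bin_mean[idx]
    factors[g] <- phi
  }
  centered[!model$mask] <- NA_real_
  ra <- model$mask & auto
  mb <- factors[".auto"] * mean(model$bin_mean[ra])
  profile$values <- centered
  profile <- advance_state(profile, "centered")
  attr(profile, "mb") <- unname(mb)
  attr(profile, "scale_factors") <- factors
  profile
}
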