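# Fixture: cohort profiles with hand-controlled per-bin structure, built
# directly from value matrices (bypassing the generator) so filter
# behaviour can be pinned exactly.

flat_gc_genome <- function(n_per_chrom = c(chr1 = 150, chr2 = 100), gc = NULL) {
  lens <- n_per_chrom * 2e4
  n <- sum(n_per_chrom)
  if (is.null(gc)) gc <- rep(0.45, n)
  genome_model(lens, bin_size = 2e4, gc = gc)
}

test_that("gc_correct is a no-op for flat GC and removes an imposed GC slope", {
  # flat GC: smoother is constant, ratio 1
  g <- flat_gc_genome()
  set.seed(21)
  p <- bin_profile(g, rpois(g$n_bins, 100))
  out <- gc_correct(p)
  expect_equal(out$values, p$values, tolerance = 1e-8)
  expect_equal(out$state, "gc_corrected")

  # sloped rate ~ (1 + 0.5*(GC - 0.4)): slope of value/mean on GC drops
  # from ~0.5 to ~0 after correction
  set.seed(22)
  gc <- runif(6000, 0.3, 0.6)
  g2 <- genome_model(c(chr1 = 6000 * 2e4), bin_size = 2e4, gc = gc)
  rate <- 1000 * (1 + 0.5 * (gc - 0.4))
  p2 <- bin_profile(g2, rpois(6000, rate))
  before <- coef(lm(I(p2$values / mean(p2$values)) ~ gc))[2]
  corr <- gc_correct(p2)
  after <- coef(lm(I(corr$values / mean(corr$values)) ~ gc))[2]
  expect_gt(abs(before), 0.4)
  expect_lt(abs(after), 0.02)
})

test_that("gc_correct is idempotent within smoother tolerance", {
  set.seed(23)
  gc <- runif(3000, 0.3, 0.6)
  g <- genome_model(c(chr1 = 3000 * 2e4), bin_size = 2e4, gc = gc)
  p <- bin_profile(g, rpois(3000, 500 * exp(-2 * (gc - 0.45)^2)))
  once <- gc_correct(p)
  twice <- gc_correct(structure(modifyList(once, list(state = "raw")),
                                class = "bin_profile"))
  expect_lt(max(abs(twice$values - once$values) / pmax(once$values, 1)), 0.01)
})

test_that("gc_correct refuses underdetermined fits", {
  g <- tiny_genome()
  p <- bin_reads(list(chr1 = c(1)), g)
  expect_error(gc_correct(p), "fewer than 100 mappable bins")
})

test_that("fit_reference masks bins by the mean and variance thresholds", {
  # cohort built at exactly the canonical scale so thresholds act on the
  # raw numbers: bin 5 forced to scaled mean 2.9 (< 3.0), bin 9 given
  # cross-cohort variance ~1.6 (> 1.5); a degenerate identical cohort
  # keeps every bin
  g <- flat_gc_genome()
  S <- canonical_scale(g)
  mu <- S / g$n_bins
  n <- 32
  set.seed(31)
  base <- rep(mu, g$n_bins)
  vals <- matrix(rep(base, each = n), nrow = n)
  vals[, 5] <- mu * 2.9 / 6.45
  vals[, 9] <- mu + rep(c(-1, 1), length.out = n) * sqrt(1.75)
  cohort <- lapply(seq_len(n), function(i)
    bin_profile(g, round(vals[i, ] * 50)))  # high depth, rescaled later
  # scale so that rescale_canonical maps to ~vals: totals differ per sample,
  # but bin 5 mean and bin 9 relative variance survive the affine rescale
  m <- fit_reference(cohort, norm_config(k = 15))
  expect_false(m$mask[5])   # mean 2.9 < 3.0 -> dropped
  expect_false(m$mask[9])   # variance > 1.5 -> dropped
  expect_gt(retained_fraction(m), 0.95)

  # degenerate identical cohort: all variances 0, PCA residual ~0
  cohort2 <- lapply(1:30, function(i) bin_profile(g, round(base * 20)))
  m2 <- fit_reference(cohort2, norm_config(k = 15))
  expect_equal(retained_fraction(m2), 1.0)
  q <- center_profile(pca_normalize(gc_correct(
    bin_profile(g, round(base * 20))), m2), m2)
  expect_lt(max(abs(q$values), na.rm = TRUE), 1e-6)
})

test_that("fit_reference rejects bad cohorts", {
  g <- flat_gc_genome()
  p <- function() bin_profile(g, rpois(g$n_bins, 50))
  set.seed(33)
  expect_error(fit_reference(replicate(10, p(), simplify = FALSE)),
               "at least 2\\*k")
  g2 <- flat_gc_genome(c(chr1 = 100, chr2 = 100))
  mixed <- c(replicate(20, p(), simplify = FALSE),
             list(bin_profile(g2, rpois(g2$n_bins, 50))))
  expect_error(fit_reference(mixed, norm_config(k = 10)), "differing genome")
})

test_that("pca_normalize is a projection: identity, null case, contraction, linearity", {
  w <- trained_world()
  m <- w$model
  idx <- m$auto_idx
  target <- m$S * length(idx) / sum(m$genome$bins$mappable)

  # profile lying in the span of the basis (plus training mean): residual ~ 0
  set.seed(40)
  coefs <- rnorm(m$config$k, sd = 3)
  v <- rep(0, m$genome$n_bins)
  v[idx] <- (m$pca_mean + as.numeric(m$basis %*% coefs)) / 1.7  # arbitrary scale
  p <- bin_profile(m$genome, v, state = "gc_corrected", total_reads = sum(v))
  out <- pca_normalize(p, m)
  f <- target / sum(v[idx])
  resid <- out$values[idx] * f - m$pca_mean  # residual at canonical scale
  expect_lt(max(abs(resid)) / mean(m$pca_mean), 0.02)

  # orthogonal profile (to the basis and to rescaling): unchanged
  set.seed(41)
  Q <- qr.Q(qr(cbind(m$basis, 1)))
  y <- rnorm(length(idx))
  y <- y - as.numeric(Q %*% crossprod(Q, y))
  v2 <- rep(0, m$genome$n_bins)
  v2[idx] <- (m$pca_mean + y) * 0.8  # arbitrary sample scale
  p2 <- bin_profile(m$genome, v2, state = "gc_corrected", total_reads = sum(v2))
  out2 <- pca_normalize(p2, m)
  expect_equal(out2$values[idx], v2[idx], tolerance = 1e-8)

  # contraction: autosomal deviation norm never increases
  held <- w$held[[1]]
  gcp <- gc_correct(held)
  sc3 <- target / sum(gcp$values[idx])
  before <- gcp$values[idx] * sc3 - m$pca_mean
  out3 <- pca_normalize(gcp, m)
  after <- out3$values[idx] * sc3 - m$pca_mean
  expect_lte(sqrt(sum(after^2)), sqrt(sum(before^2)) * (1 + 1e-12))

  # linearity on equal-total inputs: normalize(a*x + (1-a)*y)
  held2 <- gc_correct(w$held[[2]])
  tot <- sum(gcp$values[idx])
  y2 <- held2$values
  y2[idx] <- y2[idx] * tot / sum(y2[idx])
  held2e <- bin_profile(m$genome, y2, state = "gc_corrected",
                        total_reads = sum(y2))
  a <- 0.3
  mix <- gcp
  mix$values <- a * gcp$values + (1 - a) * held2e$values
  nm <- pca_normalize(mix, m)
  n1 <- pca_normalize(gcp, m)
  n2 <- pca_normalize(held2e, m)
  expect_equal(nm$values[idx],
               a * n1$values[idx] + (1 - a) * n2$values[idx],
               tolerance = 1e-6)
})

test_that("center_profile subtracts stored means and drops masked bins", {
  w <- trained_world()
  m <- w$model
  # the training mean profile itself centers to ~0 on retained autosomes;
  # mean + delta on one bin centers to ~delta there
  v <- ifelse(is.na(m$bin_mean), 0, m$bin_mean)
  auto <- autosomal_bins(m$genome) & m$genome$bins$mappable
  target_bin <- which(m$mask & auto)[100]
  delta <- 2.5
  v2 <- v
  v2[target_bin] <- v2[target_bin] + delta
  for (vv in list(v, v2)) {
    p <- bin_profile(m$genome, vv, state = "pca_normalized",
                     total_reads = sum(vv))
    cen <- center_profile(p, m)
    expect_true(all(is.na(cen$values[!m$mask])))
    if (identical(vv, v)) {
      expect_lt(max(abs(cen$values[m$mask & auto])), 1e-8)
    } else {
      # small global offset from the self-calibrating scale factor
      expect_equal(cen$values[target_bin], delta, tolerance = 0.01)
      expect_lt(stats::median(abs(cen$values[m$mask & auto])), 0.01)
    }
  }
})

test_that("held-out residual variance shrinks through PCA removal", {
  # noise reduction on held-out samples: deviation variance around the
  # training mean, on retained autosomal bins, before vs after removing
  # the projection onto the stored components
  w <- trained_world()
  m <- w$model
  idx <- m$auto_idx
  keep <- m$mask[idx]
  target <- m$S * length(idx) / sum(m$genome$bins$mappable)
  vars <- vapply(w$held[1:4], function(h) {
    gcp <- gc_correct(h)
    sc <- target / sum(gcp$values[idx])
    before <- gcp$values[idx] * sc - m$pca_mean
    after <- pca_normalize(gcp, m)$values[idx] * sc - m$pca_mean
    c(before = var(before[keep]), after = var(after[keep]))
  }, c(before = 0.0, after = 0.0))
  # strictly smaller on average, never much larger per sample
  expect_lt(mean(vars["after", ]), mean(vars["before", ]))
  expect_true(all(vars["after", ] < vars["before", ] * 1.05))
})

test_that("filter mask depends only on the training cohort", {
  w <- trained_world()
  m <- w$model
  mask_before <- m$mask
  invisible(call_cnvs(w$held[[3]], m, ff = 0.1, chromosomes = "chr3"))
  expect_identical(m$mask, mask_before)
})

test_that("retained_fraction reflects forced near-zero bins (~0.90) and edge cases", {
  cfg <- test_synth_config(frac_low = 0.10, frac_hyper = 0)
  g <- make_genome(cfg, seed = 55)
  co <- make_cohort(g, 30, equivalent_reads(g, 10e6), seed = 56)
  m <- fit_reference(co)
  # 10% of mappable bins near-zero rate; Y bins also drop (mixed fetal sex)
  y_frac <- sum(g$bins$mappable[chrom_bins(g, "chrY")]) / sum(g$bins$mappable)
  expect_equal(retained_fraction(m), 0.90 - y_frac, tolerance = 0.035)
  # empty mask -> 0
  m0 <- m
  m0$mask[] <- FALSE
  expect_equal(retained_fraction(m0), 0)
})
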