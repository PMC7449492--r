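test_that("cbs_segment finds a planted shift at the right breakpoints", {
  # 2000 bins, bins 801..1000 shifted by -10 SD: three segments with
  # change-points at 800 and 1000 (the planted arc dominates all others)
  set.seed(61)
  x <- rnorm(2000)
  x[801:1000] <- x[801:1000] - 10
  segs <- cbs_segment(x)
  expect_equal(nrow(segs), 3)
  expect_lte(abs(segs$bin_to[1] - 800), 1)
  expect_lte(abs(segs$bin_to[2] - 1000), 1)
  expect_lt(segs$mean[2], -9)
  expect_lt(abs(segs$mean[1]), 0.2)
})

test_that("cbs_segment returns a single segment on null and constant input", {
  # null case: splits occur at ~ rate alpha; over 12 seeds expect mostly 1
  splits <- vapply(1:12, function(s) {
    set.seed(s)
    nrow(cbs_segment(rnorm(400)))
  }, 0L)
  expect_gte(sum(splits == 1), 10)
  # constant non-zero profile: one segment with mean c
  segs <- cbs_segment(rep(2.5, 50))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$mean, 2.5)
  expect_equal(segs$n_bins, 50)
  # single bin
  expect_equal(nrow(cbs_segment(c(1.0))), 1)
})

test_that("segmentation of a centered profile maps segments to genome coordinates", {
  w <- trained_world()
  m <- w$model
  prof <- pca_normalize(gc_correct(w$held[[5]]), m)
  truth <- spike_spec("chr2", 10e6, 16e6, "deletion", "fetal", ff = 0.15)
  cen <- center_profile(spike_in(prof, truth), m)
  segs <- cbs_segment(cen, chromosomes = "chr2")
  expect_true(all(segs$chrom == "chr2"))
  # contiguous over retained bins, non-overlapping
  expect_true(all(diff(segs$bin_from) > 0))
  expect_true(all(segs$bin_from[-1] == segs$bin_to[-nrow(segs)] + 1))
  hit <- segs$start < 16e6 & segs$end > 10e6 & segs$mean < -0.2
  expect_true(any(hit))
})

test_that("classify_segments reproduces the threshold formulas and length gates", {
  seg <- function(mean, len) {
    data.frame(chrom = "chr1", start = 1e6, end = 1e6 + len,
               bin_from = 1, bin_to = max(1, len / 2e4),
               n_bins = max(1, len / 2e4), mean = mean)
  }
  cfg <- caller_config()
  # mb = 6.45, ff = 0.10: fetal threshold 0.75*6.45*0.05 = 0.2419,
  # maternal threshold 0.75*6.45*0.45 = 2.1769
  calls <- classify_segments(seg(-0.30, 1e6), mb = 6.45, ff = 0.10, cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$origin, "fetal")
  expect_equal(calls$type, "deletion")
  expect_equal(calls$th_fetal, 0.75 * 6.45 * 0.05)
  expect_equal(calls$th_maternal, 0.75 * 6.45 * 0.45)
  # same mean but 400 kb: below the 600 kb fetal length gate -> no call
  expect_equal(nrow(classify_segments(seg(-0.30, 4e5), 6.45, 0.10, cfg)), 0)
  # strong 300 kb segment: maternal deletion (maternal gate is 200 kb)
  calls2 <- classify_segments(seg(-2.5, 3e5), 6.45, 0.10, cfg)
  expect_equal(calls2$origin, "maternal")
  expect_equal(calls2$type, "deletion")
  # duplication mirrors deletion with positive mean
  calls3 <- classify_segments(seg(0.30, 1e6), 6.45, 0.10, cfg)
  expect_equal(calls3$type, "duplication")
  expect_equal(calls3$origin, "fetal")
  # tie at exactly the threshold counts as significant
  calls4 <- classify_segments(seg(-0.75 * 6.45 * 0.05, 1e6), 6.45, 0.10, cfg)
  expect_equal(nrow(calls4), 1)
  # errors and default-ff fallback
  expect_error(classify_segments(seg(-1, 1e6), mb = 0, ff = 0.1), "mb")
  expect_error(classify_segments(seg(-1, 1e6), mb = 6, ff = 1.2), "ff")
  calls5 <- classify_segments(seg(-0.30, 1e6), 6.45, ff = NULL, cfg)
  expect_true(attr(calls5, "default_ff"))
  expect_equal(attr(calls5, "ff"), 0.05)
})

test_that("classification is scale-equivariant and monotone in tau and ff", {
  set.seed(71)
  segs <- data.frame(chrom = "chr1",
                     start = seq(0, 9e6, by = 1e6),
                     end = seq(0, 9e6, by = 1e6) + c(7e5, 3e5, rep(8e5, 8)),
                     bin_from = 1, bin_to = 2, n_bins = 35,
                     mean = c(-0.3, -2.5, runif(8, -0.4, 0.4)))
  base <- classify_segments(segs, mb = 6.45, ff = 0.10)
  # scale equivariance: common factor on means and mb leaves calls unchanged
  segs2 <- segs
  segs2$mean <- segs2$mean * 20
  scaled <- classify_segments(segs2, mb = 6.45 * 20, ff = 0.10)
  expect_equal(scaled[c("chrom", "start", "type", "origin")],
               base[c("chrom", "start", "type", "origin")])
  # raising tau never increases the number of calls
  n_calls <- vapply(c(0.5, 0.75, 0.9, 1.0), function(tau)
    nrow(classify_segments(segs, 6.45, 0.10, caller_config(tau = tau))), 0L)
  expect_true(all(diff(n_calls) <= 0))
  # raising ff narrows the fetal band from both sides (the fetal
  # threshold tau*mb*ff/2 grows, the maternal threshold tau*mb*(1-ff)/2
  # shrinks): fetal calls never increase, maternal calls never decrease
  counts <- vapply(c(0.05, 0.1, 0.15, 0.2), function(ff) {
    calls <- classify_segments(segs, 6.45, ff)
    c(fetal = sum(calls$origin == "fetal"),
      maternal = sum(calls$origin == "maternal"))
  }, c(fetal = 0L, maternal = 0L))
  expect_true(all(diff(counts["fetal", ]) <= 0))
  expect_true(all(diff(counts["maternal", ]) >= 0))
})

test_that("a spike at the theoretical level clears the 75% threshold with margin", {
  # fetal deletion at exactly mb*ff/2 oversteps tau = 0.75 by construction
  mb <- 6.45; ff <- 0.12
  seg <- data.frame(chrom = "chr1", start = 0, end = 2e6, bin_from = 1,
                    bin_to = 100, n_bins = 100, mean = -mb * ff / 2)
  calls <- classify_segments(seg, mb, ff)
  expect_equal(calls$origin, "fetal")
  expect_equal(abs(calls$mean) / calls$th_fetal, 1 / 0.75)
})

test_that("segment_zscore follows the m/(sigma/sqrt(n)) formula", {
  g <- genome_model(c(chr1 = 400 * 2e4), bin_size = 2e4, gc = rep(0.45, 400))
  set.seed(81)
  v <- rnorm(400)
  v[101:200] <- v[101:200] - 1
  p <- bin_profile(g, v, state = "centered", total_reads = 0)
  seg <- list(chrom = "chr1", start = 100 * 2e4, end = 200 * 2e4,
              mean = -1, n_bins = 100)
  sigma <- mad(v[-(101:200)])
  expect_equal(segment_zscore(seg, p), -1 / (sigma / sqrt(100)))
  # zero mean -> zero z; n scaling by sqrt(2)
  seg0 <- modifyList(seg, list(mean = 0))
  expect_equal(segment_zscore(seg0, p), 0)
  seg2 <- modifyList(seg, list(n_bins = 200))
  expect_equal(segment_zscore(seg2, p) / segment_zscore(seg, p), sqrt(2))
  # sigma = 0 -> NA with warning
  pz <- bin_profile(g, c(rep(0, 100), rep(1, 100), rep(0, 200)),
                    state = "centered", total_reads = 0)
  expect_warning(z <- segment_zscore(seg, pz), "zero robust SD")
  expect_true(is.na(z))
})

test_that("estimate_ff_y interpolates the chrY read fraction linearly", {
  g <- genome_model(c(chr1 = 10e5, chrY = 2e5), bin_size = 1e5,
                    gc = rep(0.45, 12))
  mk <- function(y_frac) {
    v <- c(rep(1000, 10), rep(0, 2))
    v[11] <- round(y_frac * 10000 / (1 - y_frac))
    bin_profile(g, v)
  }
  fb <- 0.001; mr <- 0.003
  expect_equal(estimate_ff_y(mk(fb), mr, fb), 0, tolerance = 0.02)
  expect_equal(estimate_ff_y(mk(mr), mr, fb), 1, tolerance = 0.02)
  expect_equal(estimate_ff_y(mk(0.002), mr, fb), 0.5, tolerance = 0.03)
  expect_error(estimate_ff_y(mk(0.002), 0.001, 0.003), "must exceed")
})

test_that("call_cnvs end-to-end: spiked deletion found, unspiked sample clean, ff flagged", {
  w <- trained_world()
  m <- w$model
  # spiked fetal deletion at ff = 0.15, 20M-read scale: exactly one fetal
  # deletion call overlapping the truth interval
  truth <- spike_spec("chr1", 15e6, 20e6, "deletion", "fetal", ff = 0.15)
  prof <- pca_normalize(gc_correct(w$held[[6]]), m)
  calls <- call_cnvs_normalized(spike_in(prof, truth), m, ff = 0.15,
                                chromosomes = "chr1")
  fet <- calls[calls$origin == "fetal" & calls$type == "deletion", ]
  expect_equal(nrow(fet), 1)
  expect_true(fet$start < 20e6 && fet$end > 15e6)
  expect_lt(fet$z, -5)
  # unspiked sample: no call overlapping the target region
  calls0 <- call_cnvs(w$held[[7]], m, ff = 0.15, chromosomes = "chr1")
  ov0 <- calls0$start < 20e6 & calls0$end > 15e6
  expect_false(any(ov0))
  # missing ff falls back to the 5% default and flags the output
  calls5 <- call_cnvs(w$held[[8]], m, chromosomes = "chr3")
  expect_true(attr(calls5, "default_ff"))
  expect_equal(attr(calls5, "ff"), 0.05)
})
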