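#' Synthetic-data generator configuration
#'
#' Describes the statistical world the pipeline assumes: Poisson-sampled
#' 20 kb bin counts with a smooth GC bias, shared low-rank cohort noise,
#' unmappable centromere-like gaps, a sprinkling of pathological bins
#' (near-zero rate, hypervariable), and fetal/maternal CNVs entering at
#' the count-generation level. The default mini-genome (three autosomes
#' plus X and Y, 310 Mb, 15,500 bins of 20 kb) keeps a full study
#' desk-scale; read counts quoted "at the NM-read scale" refer to the
#' depth-equivalent on a 3.1 Gb genome (see [equivalent_reads()]).
#'
#' @param chrom_lengths named chromosome lengths (bp)
#' @param bin_size bin width (bp)
#' @param gap_frac fraction of each chromosome occupied by a contiguous
#'   unmappable centromere-like gap
#' @param frac_low fraction of mappable bins with near-zero read rate
#'   (poorly mappable bins; filtered by the mean threshold)
#' @param frac_hyper fraction of mappable bins with strong extra
#'   per-sample rate jitter (filtered by the variance threshold)
#' @param low_rate relative rate of the near-zero bins
#' @param hyper_cv coefficient of variation of the hypervariable jitter
#' @param component_sd magnitudes of the shared low-rank noise
#'   components (per-bin multiplicative CV per component)
#' @param loading_window correlation length of the shared-noise loadings
#'   in bins. Shared artifacts track mappability/GC micro-structure, so
#'   the default (9 bins, ~180 kb) is sub-CNV-scale; multi-megabase
#'   coherent noise would be indistinguishable from real CNVs and is not
#'   what cohort normalization targets.
#' @param gc_bias_strength curvature of the shared GC bias
#' @param gc_sample_sd per-sample spread of the linear GC-bias tilt
#' @param gc_range range of per-bin GC fractions
#' @param y_background chrY read rate of a fully female sample relative
#'   to the autosomal level (mismapping background)
#' @export
synth_config <- function(chrom_lengths = c(chr1 = 120e6, chr2 = 100e6,
                                           chr3 = 60e6, chrX = 20e6,
                                           chrY = 10e6),
                         bin_size = 20000L, gap_frac = 0.05,
                         frac_low = 0.06, frac_hyper = 0.04,
                         low_rate = 0.05, hyper_cv = 0.5,
                         component_sd = c(0.03, 0.02, 0.015),
                         loading_window = 9,
                         gc_bias_strength = 3, gc_sample_sd = 0.5,
                         gc_range = c(0.3, 0.6), y_background = 0.01) {
  stopifnot(all(chrom_lengths > 0), gap_frac >= 0, gap_frac < 0.5,
            frac_low >= 0, frac_hyper >= 0, all(is.finite(component_sd)))
  structure(list(chrom_lengths = chrom_lengths, bin_size = bin_size,
                 gap_frac = gap_frac, frac_low = frac_low,
                 frac_hyper = frac_hyper, low_rate = low_rate,
                 hyper_cv = hyper_cv, component_sd = component_sd,
                 loading_window = loading_window,
                 gc_bias_strength = gc_bias_strength,
                 gc_sample_sd = gc_sample_sd, gc_range = gc_range,
                 y_background = y_background),
            class = "synth_config")
}

# smooth spatially autocorrelated series in [0, 1], length n
smooth_series <- function(n, window = 41) {
  z <- stats::rnorm(n + window)
  sm <- stats::filter(z, rep(1 / window, window), sides = 2)
  sm <- sm[!is.na(sm)][seq_len(n)]
  sm <- (sm - mean(sm)) / stats::sd(sm)
  stats::pnorm(sm)
}

#' Generate a synthetic genome model
#'
#' Per-bin GC is drawn from a smooth spatially autocorrelated process in
#' `gc_range`; one contiguous centromere-like gap per chromosome is
#' flagged unmappable. Population structure (bin weights, hypervariable
#' flags, low-rank noise loadings, shared GC-bias curve) is attached as
#' attribute `synth_population` so cohorts and cases generated from the
#' same genome share it. Pure function of (config, seed).
#'
#' @param config a [synth_config()]
#' @param seed RNG seed (mandatory)
#' @export
make_genome <- function(config = synth_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (sum(config$chrom_lengths) <= 0) stop("zero-length genome")
  set.seed(seed)
  gcs <- list()
  maps <- list()
  for (ch in names(config$chrom_lengths)) {
    n <- length(seq(0, config$chrom_lengths[[ch]] - 1, by = config$bin_size))
    u <- smooth_series(n)
    gcs[[ch]] <- config$gc_range[1] + diff(config$gc_range) * u
    mp <- rep(TRUE, n)
    gap_len <- round(config$gap_frac * n)
    if (gap_len > 0) {
      gap_start <- floor(n * stats::runif(1, 0.4, 0.6 - config$gap_frac))
      mp[seq(gap_start + 1, length.out = gap_len)] <- FALSE
    }
    maps[[ch]] <- mp
  }
  genome <- genome_model(config$chrom_lengths, bin_size = config$bin_size,
                         gc = unlist(gcs, use.names = FALSE),
                         mappable = unlist(maps, use.names = FALSE))
  n_bins <- genome$n_bins
  map <- genome$bins$mappable
  weight <- rep(1, n_bins)
  low <- map & stats::runif(n_bins) < config$frac_low
  weight[low] <- config$low_rate
  hyper <- map & !low & stats::runif(n_bins) < config$frac_hyper
  K <- length(config$component_sd)
  loadings <- matrix(0, n_bins, K)
  for (k in seq_len(K)) {
    s <- smooth_series(n_bins, window = config$loading_window)
    s <- stats::qnorm(pmin(pmax(s, 1e-6), 1 - 1e-6))
    loadings[, k] <- s / stats::sd(s)
  }
  attr(genome, "synth_population") <- list(
    weight = weight, hyper = hyper, loadings = loadings, config = config)
  genome
}

# shared + per-sample GC bias factor on the rate scale
gc_bias_factor <- function(gc, config, beta) {
  exp(-config$gc_bias_strength * (gc - 0.45)^2) * (1 + beta * (gc - 0.45))
}

# internal: expected per-bin rates for one sample (before normalization
# to total reads). cnv: optional spike_spec applied on the rate scale.
sample_rates <- function(genome, config, ff, fetal_male, cnv = NULL) {
  pop <- attr(genome, "synth_population")
  if (is.null(pop)) stop("genome lacks synth_population; use make_genome()")
  n <- genome$n_bins
  map <- genome$bins$mappable
  gc <- genome$bins$gc
  beta <- stats::rnorm(1, 0, config$gc_sample_sd)
  f <- stats::rnorm(ncol(pop$loadings))
  lowrank <- 1 + as.numeric(pop$loadings %*% (config$component_sd * f))
  r <- pop$weight * gc_bias_factor(gc, config, beta) * pmax(lowrank, 0.05)
  if (any(pop$hyper))
    r[pop$hyper] <- r[pop$hyper] *
      exp(stats::rnorm(sum(pop$hyper), -config$hyper_cv^2 / 2, config$hyper_cv))
  for (ch in genome$sex_chroms) {
    idx <- chrom_bins(genome, ch)
    if (grepl("Y$", ch)) {
      r[idx] <- r[idx] * (config$y_background + if (fetal_male) 0.5 * ff else 0)
    } else {
      # maternal XX plus fetal contribution (male fetus carries one X)
      r[idx] <- r[idx] * (if (fetal_male) 1 - ff / 2 else 1)
    }
  }
  if (!is.null(cnv)) {
    idx <- bins_in_interval(genome, cnv$chrom, cnv$start, cnv$end)
    r[idx] <- r[idx] * spike_factor(cnv)
  }
  r[!map] <- 0
  r
}

#' Generate a cohort of euploid maternal-plasma profiles
#'
#' Per-bin expected rates combine bin weight, a smooth GC bias with a
#' per-sample tilt, and shared low-rank noise with sample-specific
#' factors; counts are Poisson with the given total read budget. Fetal
#' sex is random and the per-sample fetal fraction uniform in
#' `[0.05, 0.2]` (it affects sex-chromosome dosage only). Pure function
#' of (genome, n_samples, reads, seed).
#'
#' @param genome a genome from [make_genome()]
#' @param n_samples cohort size
#' @param reads expected total read count per sample
#' @param seed RNG seed (mandatory)
#' @return list of raw-state [bin_profile()]s
#' @export
make_cohort <- function(genome, n_samples, reads, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  pop <- attr(genome, "synth_population")
  if (is.null(pop)) stop("genome lacks synth_population; use make_genome()")
  config <- pop$config
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    ff <- stats::runif(1, 0.05, 0.2)
    male <- stats::runif(1) < 0.5
    r <- sample_rates(genome, config, ff, male)
    counts <- stats::rpois(genome$n_bins, r / sum(r) * reads)
    out[[s]] <- bin_profile(genome, counts, state = "raw", ff = ff,
                            sample_id = sprintf("synth%03d", s))
  }
  out
}

#' Generate an aberrated case sample
#'
#' As one [make_cohort()] sample, but the expected rates inside the CNV
#' interval are multiplied by the aberration factor (fetal deletion
#' `1 - ff/2`, fetal duplication `1 + ff/2`, maternal deletion
#' `1 - (1-ff)/2`, ...) before Poisson sampling, so the signal enters at
#' the count-generation level. The `ff = 1` limit reproduces a pure
#' affected genomic DNA sample (hemizygous deletion factor 0.5).
#'
#' @param genome a genome from [make_genome()]
#' @param cnv a [spike_spec()] (its `ff` is the sample's fetal fraction)
#' @param reads expected total read count
#' @param seed RNG seed (mandatory)
#' @param fetal_male logical fetal sex (default FALSE)
#' @return list(profile = raw [bin_profile()], truth = `cnv`)
#' @export
make_case <- function(genome, cnv, reads, seed, fetal_male = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  pop <- attr(genome, "synth_population")
  if (is.null(pop)) stop("genome lacks synth_population; use make_genome()")
  r <- sample_rates(genome, pop$config, cnv$ff, fetal_male, cnv = cnv)
  counts <- stats::rpois(genome$n_bins, r / sum(r) * reads)
  profile <- bin_profile(genome, counts, state = "raw", ff = cnv$ff,
                         sample_id = "case")
  list(profile = profile, truth = cnv)
}

#' Generate an ISCA-like labelled deletion record set
#'
#' Every pathogenic record contains the given core region with
#' exponentially distributed flanks on both sides (spanning the 0-1 Mb
#' to 10-40 Mb size classes as `flank_scale` grows); benign records are
#' placed uniformly, rejecting placements that contain the core. By
#' construction [derive_region()] recovers a region containing the core
#' whenever `n_pathogenic` reaches the coverage cutoff.
#'
#' @param core list with `chrom`, `start`, `end` — the planted critical
#'   region
#' @param n_pathogenic,n_benign record counts
#' @param flank_scale mean flank length in bp (exponential)
#' @param chrom_length chromosome length bound
#' @param seed RNG seed (mandatory)
#' @return deletion-record data.frame (chrom, start, end,
#'   classification, id)
#' @export
make_isca_like <- function(core, n_pathogenic, n_benign = 0,
                           flank_scale = 1e6, chrom_length, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  recs <- list()
  if (n_pathogenic > 0) {
    lf <- stats::rexp(n_pathogenic, rate = 1 / max(flank_scale, 1))
    rf <- stats::rexp(n_pathogenic, rate = 1 / max(flank_scale, 1))
    if (flank_scale <= 0) lf <- rf <- rep(0, n_pathogenic)
    start <- pmax(0, round(core$start - lf))
    end <- pmin(chrom_length, round(core$end + rf))
    recs$path <- data.frame(
      chrom = core$chrom, start = start, end = end,
      classification = sample(pathogenic_classes(), n_pathogenic,
                              replace = TRUE, prob = c(0.7, 0.3)),
      id = sprintf("P%04d", seq_len(n_pathogenic)))
  }
  if (n_benign > 0) {
    bs <- numeric(n_benign)
    be <- numeric(n_benign)
    for (i in seq_len(n_benign)) {
      repeat {
        w <- stats::rexp(1, 1 / max(flank_scale, 1)) + 1e4
        s <- stats::runif(1, 0, max(chrom_length - w, 1))
        e <- min(chrom_length, s + w)
        if (!(s <= core$start && e >= core$end)) break  # must not contain core
      }
      bs[i] <- round(s)
      be[i] <- round(e)
    }
    recs$ben <- data.frame(
      chrom = core$chrom, start = bs, end = be,
      classification = sample(benign_classes(), n_benign, replace = TRUE),
      id = sprintf("B%04d", seq_len(n_benign)))
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), classification = character(0),
                      id = character(0))
  rownames(out) <- NULL
  out
}
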