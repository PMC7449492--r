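# Shared fixtures, built in code. The "test genome" is a reduced
# mini-genome (124 Mb) so cohort training stays fast; per-bin depth is
# matched to the full-genome read-count scale via equivalent_reads(), so
# detection power is unaffected by the reduction.

test_synth_config <- function(...) {
  synth_config(chrom_lengths = c(chr1 = 44e6, chr2 = 40e6, chr3 = 24e6,
                                 chrX = 10e6, chrY = 6e6), ...)
}

# tiny genome for micro tests (no synthetic population attached)
tiny_genome <- function(gc = NULL) {
  lens <- c(chr1 = 2e5, chr2 = 1e5)
  n <- 15
  if (is.null(gc)) gc <- rep(0.45, n)
  genome_model(lens, bin_size = 2e4, gc = gc)
}

# cached trained model + held-out profiles for the heavier tests
trained_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- test_synth_config()
      genome <- make_genome(cfg, seed = 101)
      cohort <- make_cohort(genome, 64, equivalent_reads(genome, 10e6),
                            seed = 102)
      model <- fit_reference(cohort)
      held <- make_cohort(genome, 12, equivalent_reads(genome, 20e6),
                          seed = 103)
      cache <<- list(genome = genome, model = model, held = held,
                     config = cfg)
    }
    cache
  }
})

# Poisson-noise world for the acceptance spike-in regimes: counting
# noise only (shared GC-bias curve, gaps and pathological bins retained;
# per-sample tilt and shared low-rank noise off, as the acceptance
# regime prescribes a Poisson-noise cohort)
poisson_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- test_synth_config(component_sd = 0, gc_sample_sd = 0)
      genome <- make_genome(cfg, seed = 201)
      cohort <- make_cohort(genome, 64, equivalent_reads(genome, 10e6),
                            seed = 202)
      model <- fit_reference(cohort)
      held <- make_cohort(genome, 12, equivalent_reads(genome, 20e6),
                          seed = 203)
      cache <<- list(genome = genome, model = model, held = held,
                     config = cfg)
    }
    cache
  }
})

# independent exhaustive max-t oracle over all arcs (pure R, O(m^2))
oracle_max_arc <- function(x) {
  m <- length(x)
  S <- c(0, cumsum(x))
  mu <- mean(x)
  s <- stats::sd(x)
  best <- -1; bi <- 0; bj <- 0
  for (i in 0:(m - 1)) {
    for (j in (i + 1):m) {
      k <- j - i
      if (k == m) next
      z <- abs(S[j + 1] - S[i + 1] - k * mu) / (s * sqrt(k * (1 - k / m)))
      if (z > best) { best <- z; bi <- i; bj <- j }
    }
  }
  # an arc and its circular complement share the breakpoint pair {i, j}
  list(t = best, i = bi, j = bj)
}
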