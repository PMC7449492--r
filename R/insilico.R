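#' Specification of an artificial CNV spike-in
#'
#' @param chrom,start,end target interval (0-based half-open)
#' @param kind `"deletion"` or `"duplication"`
#' @param origin `"fetal"` or `"maternal"`
#' @param ff fetal fraction in (0, 1)
#' @export
spike_spec <- function(chrom, start, end, kind = c("deletion", "duplication"),
                       origin = c("fetal", "maternal"), ff) {
  kind <- match.arg(kind)
  origin <- match.arg(origin)
  stopifnot(start < end, ff > 0, ff < 1)
  structure(list(chrom = chrom, start = start, end = end, kind = kind,
                 origin = origin, ff = ff), class = "spike_spec")
}

# multiplicative factor of a spike on the count scale
spike_factor <- function(spec) {
  shift <- if (spec$origin == "fetal") spec$ff / 2 else (1 - spec$ff) / 2
  if (spec$kind == "deletion") 1 - shift else 1 + shift
}

#' Inject an artificial CNV into a normalized profile
#'
#' All bins between the start and the end of the target interval are
#' multiplied by the aberration factor: fetal deletion `1 - ff/2`, fetal
#' duplication `1 + ff/2`, maternal (mother-only) deletion
#' `1 - (1-ff)/2`, maternal duplication `1 + (1-ff)/2`. The
#' multiplication is applied after GC and PCA normalization but before
#' mean subtraction, i.e. on count-scale values, because fetal fraction
#' is not constant along the genome and the factor is defined relative
#' to the normalized within-sample level.
#'
#' @param profile pca_normalized-state [bin_profile()]
#' @param spec a [spike_spec()]
#' @return the modified profile with the truth stored in attribute
#'   `truth`
#' @export
spike_in <- function(profile, spec) {
  require_state(profile, "pca_normalized")
  genome <- profile$genome
  check_interval(genome, spec$chrom, spec$start, spec$end)
  idx <- bins_in_interval(genome, spec$chrom, spec$start, spec$end)
  idx <- idx[genome$bins$mappable[idx]]
  if (length(idx) == 0)
    stop("spike region contains no mappable bins; nothing to spike")
  profile$values[idx] <- profile$values[idx] * spike_factor(spec)
  attr(profile, "truth") <- spec
  profile
}

#' Binomial downsampling of a raw profile
#'
#' Each bin count is replaced by a binomial draw with success probability
#' `target_reads / total_reads`, so expected per-bin counts scale
#' proportionally. Reproducible under `set.seed()`.
#'
#' @param profile raw-state [bin_profile()]
#' @param target_reads desired total (must not exceed the current total)
#' @export
downsample_profile <- function(profile, target_reads) {
  require_state(profile, "raw")
  if (target_reads > profile$total_reads)
    stop("target_reads exceeds current total read count")
  p <- target_reads / profile$total_reads
  if (p == 1) return(profile)
  v <- profile$values
  nz <- which(v > 0)
  v[nz] <- stats::rbinom(length(nz), size = as.integer(v[nz]), prob = p)
  profile$values <- v
  profile$total_reads <- sum(v)
  profile
}

#' Score a call set against a spike-in truth
#'
#' `correct` is true when some call with matching type and origin
#' overlaps the truth interval by at least one bin; `false_positive` is
#' true when some call overlaps no truth interval at all.
#'
#' @param calls calls data.frame from [call_cnvs()]
#' @param truth a [spike_spec()]
#' @export
score_detection <- function(calls, truth) {
  if (nrow(calls) == 0)
    return(list(correct = FALSE, false_positive = FALSE))
  ov <- calls$chrom == truth$chrom &
    calls$start < truth$end & calls$end > truth$start
  correct <- any(ov & calls$type == truth$kind & calls$origin == truth$origin)
  list(correct = correct, false_positive = any(!ov))
}

#' Planned simulation count of a study grid
#'
#' The grid is full-factorial: one simulation per
#' (region x background x level).
#' @param n_regions,n_backgrounds,n_levels axis cardinalities
#' @export
study_plan <- function(n_regions, n_backgrounds, n_levels) {
  n_regions * n_backgrounds * n_levels
}

#' Sensitivity in percent from detection counts
#' @param correct,total detection and simulation counts
#' @export
sensitivity_percent <- function(correct, total) 100 * correct / total

size_class_breaks <- function() c(0, 1, 2, 3, 4, 5, 10, 40) * 1e6

size_class_labels <- function() {
  b <- size_class_breaks() / 1e6
  sprintf("%g-%gMb", b[-length(b)], b[-1])
}

size_class_of <- function(len) {
  cut(len, breaks = size_class_breaks(), labels = size_class_labels(),
      right = TRUE, include.lowest = TRUE)
}

#' One spike-in simulation: normalize, inject, call, score
#'
#' Building block of the study grids and the acceptance evaluation. The
#' background profile may be downsampled first; it is then GC-corrected,
#' PCA-normalized, spiked, centered, segmented and classified with the
#' true fetal fraction, and the calls scored against the truth.
#'
#' @param model fitted `norm_model`
#' @param background raw-state [bin_profile()]
#' @param region list/row with `chrom`, `start`, `end`
#' @param ff fetal fraction of the simulated aberration
#' @param kind,origin aberration type (defaults: fetal deletion)
#' @param reads optional downsampling target (raw reads)
#' @param config a [caller_config()]
#' @param chromosomes optional segmentation restriction (e.g. the
#'   affected chromosome)
#' @return list(correct, false_positive, n_calls, truth)
#' @export
simulate_detection <- function(model, background, region, ff,
                               kind = "deletion", origin = "fetal",
                               reads = NULL, config = caller_config(),
                               chromosomes = NULL) {
  prof <- background
  # a Poisson-generated background can fall just short of a nominal target
  # equal to its own budget; run such levels at the full available depth
  if (!is.null(reads))
    prof <- downsample_profile(prof, min(reads, prof$total_reads))
  truth <- spike_spec(region$chrom, region$start, region$end,
                      kind = kind, origin = origin, ff = ff)
  pca <- pca_normalize(gc_correct(prof, span = model$config$span), model)
  spiked <- spike_in(pca, truth)
  calls <- call_cnvs_normalized(spiked, model, ff = ff, config = config,
                                chromosomes = chromosomes)
  sc <- score_detection(calls, truth)
  list(correct = sc$correct, false_positive = sc$false_positive,
       n_calls = nrow(calls), truth = truth)
}

# internal: shared full-factorial study runner
run_spike_study <- function(model, backgrounds, regions, levels, mode,
                            ff_fixed = NULL, config = caller_config(),
                            seed, restrict_chrom = TRUE) {
  stopifnot(mode %in% c("ff", "reads"))
  if (nrow(regions) == 0) stop("no regions supplied")
  if (length(backgrounds) == 0) stop("no background profiles supplied")
  set.seed(seed)
  genome <- model$genome
  lab <- size_class_labels()
  dims <- list(size_class = lab, level = as.character(levels))
  sims <- matrix(0L, length(lab), length(levels), dimnames = dims)
  correct <- sims
  fp_free <- sims
  skipped <- 0L
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    ok <- tryCatch({
      check_interval(genome, reg$chrom, reg$start, reg$end)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      warning(sprintf("region %s:%s-%s outside genome; skipped",
                      reg$chrom, reg$start, reg$end))
      skipped <- skipped + 1L
      next
    }
    cls <- as.character(size_class_of(reg$end - reg$start))
    for (b in seq_along(backgrounds)) {
      for (l in seq_along(levels)) {
        ff <- if (mode == "ff") levels[l] else ff_fixed
        reads <- if (mode == "reads") levels[l] else NULL
        res <- simulate_detection(
          model, backgrounds[[b]], reg, ff = ff, reads = reads,
          config = config,
          chromosomes = if (restrict_chrom) reg$chrom else NULL)
        sims[cls, l] <- sims[cls, l] + 1L
        correct[cls, l] <- correct[cls, l] + res$correct
        fp_free[cls, l] <- fp_free[cls, l] + !res$false_positive
      }
    }
  }
  expected <- study_plan(nrow(regions) - skipped, length(backgrounds),
                         length(levels))
  if (sum(sims) != expected)
    stop("simulation bookkeeping mismatch: ran ", sum(sims),
         ", expected ", expected)
  structure(list(mode = mode, levels = levels, sims = sims,
                 correct = correct, fp_free = fp_free,
                 sensitivity = ifelse(sims > 0, correct / sims, NA),
                 specificity = ifelse(sims > 0, fp_free / sims, NA),
                 n_simulations = sum(sims), seed = seed),
            class = "study_result")
}

#' Fetal-fraction sensitivity grid
#'
#' One simulation per (region x background x fetal-fraction level) at a
#' fixed read depth; tabulates sensitivity and specificity per
#' (deletion-size class, fetal fraction) cell. Deterministic given
#' `seed`.
#'
#' @param model fitted `norm_model`
#' @param backgrounds list of raw euploid [bin_profile()]s
#' @param regions data.frame with chrom, start, end
#' @param ff_levels fetal fractions (default 5% to 20% in steps of 2.5%)
#' @param config a [caller_config()]
#' @param seed RNG seed (mandatory)
#' @param restrict_chrom segment only the affected chromosome (default
#'   TRUE; the aberration is simulated on that chromosome only)
#' @export
run_ff_grid <- function(model, backgrounds, regions,
                        ff_levels = c(0.05, 0.075, 0.1, 0.125, 0.15, 0.175, 0.2),
                        config = caller_config(), seed,
                        restrict_chrom = TRUE) {
  run_spike_study(model, backgrounds, regions, levels = ff_levels,
                  mode = "ff", config = config, seed = seed,
                  restrict_chrom = restrict_chrom)
}

#' Read-count sensitivity grid
#'
#' As [run_ff_grid()] with the axes swapped: fetal fraction fixed
#' (default 10%), read count varied by binomial downsampling of each
#' background.
#'
#' @inheritParams run_ff_grid
#' @param read_levels downsampling targets in raw reads
#' @param ff fixed fetal fraction (default 0.10)
#' @export
run_readcount_grid <- function(model, backgrounds, regions, read_levels,
                               ff = 0.10, config = caller_config(), seed,
                               restrict_chrom = TRUE) {
  run_spike_study(model, backgrounds, regions, levels = read_levels,
                  mode = "reads", ff_fixed = ff, config = config,
                  seed = seed, restrict_chrom = restrict_chrom)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result [%s]: %d simulations, overall sensitivity %.1f%%\n",
              x$mode, x$n_simulations,
              sensitivity_percent(sum(x$correct), sum(x$sims))))
  cat("sensitivity by (size class x level):\n")
  print(round(x$sensitivity, 3))
  invisible(x)
}

#' Write a study result as TSV matrices
#'
#' Rows are deletion-size classes, columns the grid levels; one file per
#' quantity (simulations, detections, sensitivity, specificity).
#'
#' @param result a `study_result`
#' @param dir output directory (created if needed)
#' @export
write_study_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (what in c("sims", "correct", "sensitivity", "specificity")) {
    utils::write.table(
      cbind(size_class = rownames(result[[what]]),
            as.data.frame(result[[what]])),
      file.path(dir, paste0(what, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
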