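#' Caller configuration
#'
#' @param tau significance fraction of the theoretical aberration level a
#'   segment mean must overstep (default 0.75)
#' @param ff_default fetal fraction assumed when none is supplied
#'   (default 0.05, the lowest value at which long aberrations are still
#'   reliably detected)
#' @param min_len_fetal minimum genomic length of a fetal call in bp
#'   (default 600,000)
#' @param min_len_maternal minimum genomic length of a maternal call in bp
#'   (default 200,000)
#' @param alpha significance level of the CBS permutation test
#' @param nperm number of permutations per split test. Permutations stop
#'   early once non-significance is certain; splits whose Bonferroni
#'   bound over all arcs is already below `alpha / 10` skip the
#'   permutation entirely.
#' @export
caller_config <- function(tau = 0.75, ff_default = 0.05,
                          min_len_fetal = 6e5, min_len_maternal = 2e5,
                          alpha = 0.01, nperm = 1000L) {
  stopifnot(tau > 0, tau <= 1, ff_default > 0, ff_default < 1,
            alpha > 0, alpha < 1, nperm >= 100)
  structure(list(tau = tau, ff_default = ff_default,
                 min_len_fetal = min_len_fetal,
                 min_len_maternal = min_len_maternal,
                 alpha = alpha, nperm = as.integer(nperm)),
            class = "caller_config")
}

# internal: is the best split of xseg significant?
# Hybrid decision: a Bonferroni upper bound over all arcs that already
# clears alpha/10 is accepted without permutation; otherwise the
# permutation test (early-stopping) decides.
split_significant <- function(xseg, tobs, config) {
  m <- length(xseg)
  if (!is.finite(tobs) || tobs <= 0) return(FALSE)
  n_arcs <- m * (m - 1) / 2
  bonf <- n_arcs * 2 * stats::pnorm(-tobs)
  if (bonf < config$alpha / 10) return(TRUE)
  p <- cbs_perm_pvalue(xseg, tobs, config$nperm, config$alpha)
  p < config$alpha
}

# internal: recursive CBS on a numeric vector; returns sorted breakpoints
# (positions b meaning a cut between x[b] and x[b+1])
cbs_breakpoints <- function(x, config) {
  m <- length(x)
  if (m < 2) return(integer(0))
  st <- cbs_max_stat(x)
  if (!split_significant(x, st$t, config)) return(integer(0))
  bps <- setdiff(c(st$i, st$j), c(0L, m))
  if (length(bps) == 0) return(integer(0))
  bounds <- c(0L, sort(bps), m)
  out <- sort(bps)
  for (s in seq_len(length(bounds) - 1)) {
    lo <- bounds[s] + 1L
    hi <- bounds[s + 1L]
    if (hi - lo + 1L >= 2L) {
      sub <- cbs_breakpoints(x[lo:hi], config)
      out <- c(out, sub + lo - 1L)
    }
  }
  sort(unique(out))
}

#' Circular binary segmentation of a centered profile
#'
#' Recursively splits each chromosome's retained-bin values at the
#' maximal circular arc statistic until no split is significant at level
#' `alpha` under the permutation test. Returns one or more contiguous,
#' non-overlapping segments per chromosome covering all retained bins.
#'
#' @param x a centered-state [bin_profile()] or a plain numeric vector
#'   (treated as a single pseudo-chromosome of unit-width bins)
#' @param config a [caller_config()]
#' @param chromosomes optional character vector restricting segmentation
#'   to these chromosomes
#' @return data.frame with columns chrom, start, end (bp, 0-based
#'   half-open), bin_from, bin_to (indices into the retained-bin vector
#'   of that chromosome), n_bins, mean
#' @export
cbs_segment <- function(x, config = caller_config(), chromosomes = NULL) {
  UseMethod("cbs_segment")
}

#' @export
cbs_segment.numeric <- function(x, config = caller_config(), chromosomes = NULL) {
  segs <- segment_vector(x, config)
  data.frame(chrom = "region", start = segs$from - 1, end = segs$to,
             bin_from = segs$from, bin_to = segs$to,
             n_bins = segs$to - segs$from + 1L, mean = segs$mean,
             stringsAsFactors = FALSE)
}

# internal: segments of a numeric vector as from/to/mean
segment_vector <- function(x, config) {
  m <- length(x)
  if (m == 0) return(data.frame(from = integer(0), to = integer(0), mean = numeric(0)))
  bps <- if (m >= 2) cbs_breakpoints(x, config) else integer(0)
  bounds <- c(0L, bps, m)
  from <- bounds[-length(bounds)] + 1L
  to <- bounds[-1]
  data.frame(from = from, to = to,
             mean = vapply(seq_along(from),
                           function(i) mean(x[from[i]:to[i]]), 0.0))
}

#' @export
cbs_segment.bin_profile <- function(x, config = caller_config(),
                                    chromosomes = NULL) {
  if (x$state != "centered")
    stop("cbs_segment requires a centered profile")
  genome <- x$genome
  chroms <- chromosomes %||% genome$chroms
  out <- list()
  for (ch in chroms) {
    idx <- chrom_bins(genome, ch)
    keep <- idx[!is.na(x$values[idx])]
    if (length(keep) == 0) next
    v <- x$values[keep]
    segs <- segment_vector(v, config)
    if (nrow(segs) == 0) next
    out[[ch]] <- data.frame(
      chrom = ch,
      start = genome$bins$start[keep[segs$from]],
      end = genome$bins$end[keep[segs$to]],
      bin_from = segs$from, bin_to = segs$to,
      n_bins = segs$to - segs$from + 1L,
      mean = segs$mean, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               bin_from = integer(0), bin_to = integer(0),
               n_bins = integer(0), mean = numeric(0))
  rownames(res) <- NULL
  res
}

#' Classify segments as fetal/maternal deletions or duplications
#'
#' A heterozygous fetal CNV shifts the mean bin count by `mb * ff / 2`, a
#' mother-only CNV by `mb * (1 - ff) / 2`. A segment whose absolute mean
#' oversteps `tau` times the maternal level (and is at least 200 kb) is
#' called maternal; otherwise, overstepping `tau` times the fetal level
#' (and at least 600 kb) yields a fetal call. Ties at exactly the
#' threshold count as significant. The sign of the segment mean selects
#' deletion (negative) versus duplication (positive).
#'
#' @param segments data.frame as returned by [cbs_segment()]
#' @param mb mean bin count at the working scale (must be positive)
#' @param ff fetal fraction in (0, 1); if `NULL`, `config$ff_default` is
#'   used and the result is flagged with attribute `default_ff = TRUE`
#' @param config a [caller_config()]
#' @return data.frame of calls (chrom, start, end, length, type, origin,
#'   mean, z, th_fetal, th_maternal, n_bins, bin_from, bin_to) with
#'   attribute `candidates`: sub-threshold segments at >= 50% of the
#'   fetal level, annotated `possibly_fetal` (a non-standard
#'   intermediate class, reported for review only)
#' @export
classify_segments <- function(segments, mb, ff = NULL,
                              config = caller_config()) {
  if (!is.null(ff) && (ff >= 1 || ff <= 0)) stop("ff must be in (0, 1)")
  if (mb <= 0) stop("mb must be positive")
  default_ff <- is.null(ff)
  if (default_ff) ff <- config$ff_default
  th_fet <- config$tau * mb * ff / 2
  th_mat <- config$tau * mb * (1 - ff) / 2
  d <- abs(segments$mean)
  len <- segments$end - segments$start
  maternal <- d >= th_mat & len >= config$min_len_maternal
  fetal <- !maternal & d >= th_fet & len >= config$min_len_fetal
  candidate <- !maternal & !fetal & d >= 0.5 * th_fet &
    len >= config$min_len_fetal
  sel <- maternal | fetal
  calls <- segments[sel, , drop = FALSE]
  calls$length <- len[sel]
  calls$type <- ifelse(calls$mean < 0, "deletion", "duplication")
  calls$origin <- ifelse(maternal[sel], "maternal", "fetal")
  calls$z <- rep(NA_real_, nrow(calls))
  calls$th_fetal <- rep(th_fet, nrow(calls))
  calls$th_maternal <- rep(th_mat, nrow(calls))
  rownames(calls) <- NULL
  cand <- segments[candidate, , drop = FALSE]
  if (nrow(cand)) {
    cand$note <- "possibly_fetal"
    rownames(cand) <- NULL
  }
  attr(calls, "candidates") <- cand
  attr(calls, "default_ff") <- default_ff
  attr(calls, "ff") <- ff
  attr(calls, "mb") <- mb
  calls
}

#' Approximate z-score of a segment
#'
#' `z = mean / (sigma / sqrt(n_bins))` with `sigma` the robust
#' (MAD-scaled) standard deviation of retained centered values outside
#' the segment.
#'
#' @param segment one row of a [cbs_segment()] data.frame (or a list with
#'   `chrom`, `start`, `end`, `mean`, `n_bins`)
#' @param profile centered-state [bin_profile()]
#' @return numeric z-score; `NA` with a warning when sigma is zero
#' @export
segment_zscore <- function(segment, profile) {
  if (profile$state != "centered") stop("profile must be centered")
  genome <- profile$genome
  inside <- bins_in_interval(genome, segment$chrom, segment$start, segment$end)
  v <- profile$values
  outside <- v[setdiff(which(!is.na(v)), inside)]
  sigma <- stats::mad(outside, na.rm = TRUE)
  if (!is.finite(sigma) || sigma == 0) {
    warning("z-score undefined: zero robust SD outside segment")
    return(NA_real_)
  }
  segment$mean / (sigma / sqrt(segment$n_bins))
}

#' End-to-end CNV calling on a raw profile
#'
#' Runs GC correction, PCA normalization, centering, circular binary
#' segmentation and threshold classification. `mb` is the sample's mean
#' retained autosomal bin count at its own read depth (genome-wide).
#'
#' @param profile raw-state [bin_profile()]
#' @param model a fitted `norm_model`
#' @param ff fetal fraction; `NULL` falls back to `config$ff_default`
#'   with the output flagged
#' @param config a [caller_config()]
#' @param chromosomes optional restriction of segmentation (e.g. the
#'   single chromosome of interest in a simulation)
#' @return calls data.frame as from [classify_segments()] with z-scores
#'   filled in; attributes `segments` (full segmentation) and
#'   `centered` (the centered profile)
#' @export
call_cnvs <- function(profile, model, ff = NULL, config = caller_config(),
                      chromosomes = NULL) {
  gcp <- gc_correct(profile, span = model$config$span)
  pca <- pca_normalize(gcp, model)
  call_cnvs_normalized(pca, model, ff = ff, config = config,
                       chromosomes = chromosomes)
}

#' CNV calling from an already normalized (pre-centering) profile
#'
#' Entry point used by the in-silico spike-in engine, where artificial
#' aberrations are injected into `pca_normalized` profiles.
#'
#' @inheritParams call_cnvs
#' @param profile pca_normalized-state [bin_profile()]
#' @export
call_cnvs_normalized <- function(profile, model, ff = NULL,
                                 config = caller_config(),
                                 chromosomes = NULL) {
  require_state(profile, "pca_normalized")
  cen <- center_profile(profile, model)
  segs <- cbs_segment(cen, config, chromosomes = chromosomes)
  mb <- attr(cen, "mb")
  calls <- classify_segments(segs, mb = mb, ff = ff, config = config)
  if (nrow(calls))
    calls$z <- vapply(seq_len(nrow(calls)), function(i)
      segment_zscore(calls[i, ], cen), 0.0)
  sexy <- calls$chrom %in% model$genome$sex_chroms
  if (any(sexy))
    message("call_cnvs: calls on sex chromosomes are lower-confidence (no PCA normalization)")
  attr(calls, "segments") <- segs
  attr(calls, "centered") <- cen
  calls
}

#' Fetal fraction from chromosome Y read fraction
#'
#' Linear interpolation between a female (non-pregnant) background chrY
#' read fraction and a pure male reference fraction, clipped to `[0, 1]`.
#'
#' @param profile raw-state [bin_profile()]
#' @param male_ref_y chrY read fraction of a pure male plasma-equivalent
#' @param female_baseline_y chrY read fraction of female background
#' @export
estimate_ff_y <- function(profile, male_ref_y, female_baseline_y) {
  if (male_ref_y <= female_baseline_y)
    stop("male_ref_y must exceed female_baseline_y")
  ych <- intersect(c("chrY", "Y"), profile$genome$chroms)
  if (length(ych) == 0) stop("genome has no Y chromosome")
  idx <- chrom_bins(profile$genome, ych[1])
  y_frac <- sum(profile$values[idx]) / profile$total_reads
  min(1, max(0, (y_frac - female_baseline_y) / (male_ref_y - female_baseline_y)))
}

#' Write calls as BED and a 1-based TSV report
#'
#' The BED file uses the internal 0-based half-open convention; the
#' report renders coordinates 1-based inclusive.
#'
#' @param calls a calls data.frame from [call_cnvs()]
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`
#' @export
write_calls <- function(calls, prefix) {
  bed <- data.frame(chrom = calls$chrom,
                    start = format(calls$start, scientific = FALSE, trim = TRUE),
                    end = format(calls$end, scientific = FALSE, trim = TRUE),
                    name = paste(calls$origin, calls$type, sep = "_"),
                    score = round(abs(calls$z %||% 0), 2),
                    strand = ".")
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  rep <- data.frame(chromosome = calls$chrom,
                    start_1based = format(calls$start + 1, scientific = FALSE, trim = TRUE),
                    end_1based = format(calls$end, scientific = FALSE, trim = TRUE),
                    type = calls$type, origin = calls$origin,
                    segment_mean = signif(calls$mean, 6),
                    z = signif(calls$z, 4),
                    th_fetal = signif(calls$th_fetal, 6),
                    th_maternal = signif(calls$th_maternal, 6))
  utils::write.table(rep, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}
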