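#' Genome model: fixed-width bin tiling with GC content and mappability
#'
#' A `genome_model` tiles each chromosome left-to-right with non-overlapping
#' bins of `bin_size` base pairs (the last bin of a chromosome may be short).
#' Coordinates are 0-based half-open internally; report output is rendered
#' 1-based inclusive. A terminal bin shorter than half the bin size is
#' flagged unmappable to avoid systematic edge undercounting.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 20,000).
#' @param gc per-bin GC fraction in `[0, 1]`, length equal to the total
#'   number of bins, or `NA` to leave undefined (required before GC
#'   correction).
#' @param mappable per-bin logical flag; defaults to all mappable.
#' @param sex_chroms names of the sex chromosomes; defaults to any of
#'   `"chrX"`, `"chrY"`, `"X"`, `"Y"` present in `chrom_lengths`.
#' @return an object of class `genome_model` with elements `chroms`,
#'   `lengths`, `bin_size`, `bins` (data.frame: chrom, start, end, gc,
#'   mappable), `offsets` (0-based first-bin index per chromosome),
#'   `sex_chroms`, `n_bins`.
#' @export
genome_model <- function(chrom_lengths, bin_size = 20000L, gc = NA,
                         mappable = NULL, sex_chroms = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (bin_size <= 0) stop("bin_size must be positive")
  chroms <- names(chrom_lengths)
  per_chrom <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq(0, len - 1, by = bin_size)
    end <- pmin(start + bin_size, len)
    data.frame(chrom = ch, start = start, end = end,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_chrom)
  n_bins <- nrow(bins)
  if (length(gc) == 1 && is.na(gc)) gc <- rep(NA_real_, n_bins)
  if (length(gc) != n_bins) stop("gc must have one value per bin")
  bad_gc <- !is.na(gc) & (gc < 0 | gc > 1)
  if (any(bad_gc)) stop("gc fractions must lie in [0, 1]")
  if (is.null(mappable)) mappable <- rep(TRUE, n_bins)
  if (length(mappable) != n_bins) stop("mappable must have one flag per bin")
  # terminal short bins: unmappable if shorter than half a bin
  short <- (bins$end - bins$start) < bin_size / 2
  mappable <- mappable & !short
  bins$gc <- gc
  bins$mappable <- mappable
  if (is.null(sex_chroms))
    sex_chroms <- intersect(c("chrX", "chrY", "X", "Y"), chroms)
  offsets <- cumsum(c(0, vapply(per_chrom, nrow, integer(1))))
  names(offsets) <- c(chroms, ".end")
  structure(
    list(chroms = chroms, lengths = chrom_lengths, bin_size = bin_size,
         bins = bins, offsets = offsets, sex_chroms = sex_chroms,
         n_bins = n_bins),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.1f Mb, %d bins of %d bp (%d mappable)\n",
              length(x$chroms), sum(x$lengths) / 1e6, x$n_bins, x$bin_size,
              sum(x$bins$mappable)))
  invisible(x)
}

#' Bin index range of a chromosome
#' @param genome a `genome_model`
#' @param chrom chromosome name
#' @return integer vector of (1-based) bin indices
#' @export
chrom_bins <- function(genome, chrom) {
  if (!chrom %in% genome$chroms) stop("unknown chromosome: ", chrom)
  i <- match(chrom, genome$chroms)
  seq.int(genome$offsets[[i]] + 1L, genome$offsets[[i + 1L]])
}

#' Logical autosome indicator over bins
#' @param genome a `genome_model`
#' @return logical vector, TRUE for bins on non-sex chromosomes
#' @export
autosomal_bins <- function(genome) {
  !(genome$bins$chrom %in% genome$sex_chroms)
}

#' 1-based bin indices overlapping a genomic interval
#'
#' Interval is 0-based half-open, matching the internal convention.
#' @param genome a `genome_model`
#' @param chrom,start,end interval coordinates
#' @export
bins_in_interval <- function(genome, chrom, start, end) {
  idx <- chrom_bins(genome, chrom)
  b <- genome$bins[idx, ]
  idx[b$start < end & b$end > start]
}

#' Canonical read scale of a genome
#'
#' The normalization thresholds (minimum per-bin mean 3.0, maximum variance
#' 1.5) are anchored to the scale at which a 3.1 Gb genome sequenced to one
#' million reads has on average about 6.5 reads per 20 kb bin. For a
#' smaller genome the canonical scale shrinks proportionally, keeping the
#' per-bin anchor identical.
#' @param genome a `genome_model`
#' @param ref_length reference genome length the 1M-read anchor refers to
#' @return canonical total read count (numeric)
#' @export
canonical_scale <- function(genome, ref_length = 3.1e9) {
  1e6 * sum(genome$lengths) / ref_length
}

#' Read count equivalent to a full-genome read count
#'
#' Depth-matched conversion: `reads` on a `ref_length` genome corresponds
#' to proportionally fewer reads on a mini-genome at the same coverage.
#' @inheritParams canonical_scale
#' @param reads full-genome read count (e.g. 20e6)
#' @export
equivalent_reads <- function(genome, reads, ref_length = 3.1e9) {
  reads * sum(genome$lengths) / ref_length
}

#' Validate a genomic interval against a genome model
#' @param genome a `genome_model`
#' @param chrom,start,end 0-based half-open interval
#' @return invisibly TRUE; errors on violation
#' @export
check_interval <- function(genome, chrom, start, end) {
  if (!chrom %in% genome$chroms) stop("unknown chromosome: ", chrom)
  if (!(start >= 0 && start < end && end <= genome$lengths[[chrom]]))
    stop(sprintf("invalid interval %s:%.0f-%.0f (chromosome length %.0f)",
                 chrom, start, end, genome$lengths[[chrom]]))
  invisible(TRUE)
}

#' Write / read a genome model as a plain-text bin table
#'
#' TSV columns: chrom, start, end, gc, mappable; header comment lines carry
#' bin size and sex-chromosome names so the round trip is exact.
#' @param genome a `genome_model`
#' @param path output file
#' @export
write_genome_model <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#bin_size=%d", genome$bin_size),
               sprintf("#sex_chroms=%s", paste(genome$sex_chroms, collapse = ","))),
             con)
  utils::write.table(genome$bins, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_model
#' @export
read_genome_model <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  bins <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
  lens <- tapply(bins$end, bins$chrom, max)
  chroms <- unique(bins$chrom)
  lens <- stats::setNames(as.numeric(lens[chroms]), chroms)
  sex <- strsplit(meta[["sex_chroms"]], ",", fixed = TRUE)[[1]]
  genome_model(lens, bin_size = as.integer(meta[["bin_size"]]),
               gc = bins$gc, mappable = bins$mappable,
               sex_chroms = sex[nzchar(sex)])
}

# internal: quick structural identity check between two genomes
same_genome <- function(a, b) {
  identical(a$chroms, b$chroms) && identical(a$bin_size, b$bin_size) &&
    isTRUE(all.equal(unname(a$lengths), unname(b$lengths)))
}
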