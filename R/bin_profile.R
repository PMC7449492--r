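#' Per-bin read-count profile of one sample
#'
#' A `bin_profile` carries one numeric value per genome bin plus a state
#' tag recording how far through the normalization pipeline the values
#' have moved. States advance strictly forward:
#' raw -> gc_corrected -> pca_normalized -> centered.
#'
#' @param genome a [genome_model()]
#' @param values numeric vector, one value per bin
#' @param state one of `"raw"`, `"gc_corrected"`, `"pca_normalized"`,
#'   `"centered"`
#' @param ff optional fetal fraction in (0, 1]
#' @param sample_id optional sample identifier
#' @param total_reads total read count; defaults to `sum(values)` for raw
#'   profiles
#' @param complete FALSE marks a profile read from a file missing
#'   chromosomes; downstream operations refuse incomplete profiles
#' @export
bin_profile <- function(genome, values, state = "raw", ff = NULL,
                        sample_id = NULL, total_reads = NULL,
                        complete = TRUE) {
  stopifnot(inherits(genome, "genome_model"))
  if (length(values) != genome$n_bins)
    stop("values must have one entry per bin (", genome$n_bins, ")")
  state <- match.arg(state, profile_states())
  if (state == "raw") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(v != floor(v)))
      stop("raw values must be non-negative integers")
    if (is.null(total_reads)) total_reads <- sum(v)
  }
  if (!is.null(ff) && (ff <= 0 || ff > 1)) stop("ff must be in (0, 1]")
  structure(
    list(genome = genome, values = as.numeric(values), state = state,
         total_reads = total_reads, ff = ff, sample_id = sample_id,
         complete = complete),
    class = "bin_profile")
}

profile_states <- function() c("raw", "gc_corrected", "pca_normalized", "centered")

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("bin_profile [%s]%s: %d bins, %.0f reads%s%s\n",
              x$state, if (x$complete) "" else " (incomplete)",
              x$genome$n_bins, x$total_reads %||% NA,
              if (is.null(x$ff)) "" else sprintf(", ff=%.3f", x$ff),
              if (is.null(x$sample_id)) "" else paste0(", ", x$sample_id)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: state machine guard
require_state <- function(profile, state) {
  if (!inherits(profile, "bin_profile")) stop("not a bin_profile")
  if (!isTRUE(profile$complete))
    stop("profile is incomplete (missing chromosomes); refusing to proceed")
  if (profile$state != state)
    stop(sprintf("profile must be in state '%s' (is '%s')", state, profile$state))
  invisible(TRUE)
}

advance_state <- function(profile, to) {
  states <- profile_states()
  if (match(to, states) != match(profile$state, states) + 1L)
    stop(sprintf("illegal state transition %s -> %s", profile$state, to))
  profile$state <- to
  profile
}

#' Count read starts into genome bins
#'
#' Each read is assigned to the bin containing its leftmost mapped
#' position: bin index `floor(start / bin_size)` within its chromosome
#' (0-based positions, half-open bins).
#'
#' @param positions named list of per-chromosome 0-based read start
#'   positions
#' @param genome a [genome_model()]
#' @param sample_id optional sample identifier
#' @return a raw-state [bin_profile()]; the total read count equals the
#'   number of input positions
#' @export
bin_reads <- function(positions, genome, sample_id = NULL) {
  stopifnot(is.list(positions))
  counts <- numeric(genome$n_bins)
  for (ch in names(positions)) {
    pos <- positions[[ch]]
    if (length(pos) == 0) next
    if (!ch %in% genome$chroms) stop("unknown chromosome: ", ch)
    len <- genome$lengths[[ch]]
    bad <- pos < 0 | pos >= len
    if (any(bad))
      stop(sprintf("read position out of bounds on %s: %d (chromosome length %d)",
                   ch, as.integer(pos[which(bad)[1]]), as.integer(len)))
    idx <- chrom_bins(genome, ch)
    b <- floor(pos / genome$bin_size) + 1L
    tb <- tabulate(b, nbins = length(idx))
    counts[idx] <- counts[idx] + tb
  }
  bin_profile(genome, counts, state = "raw", sample_id = sample_id)
}

#' Read and write bin-count tables
#'
#' TSV with header `chromosome  bin_start  bin_end  value`; metadata
#' (state, total reads, fetal fraction, sample id) stored in `#key=value`
#' comment lines so `write_bin_table` then `read_bin_table` is the
#' identity on values and metadata. Chromosomes present in the genome but
#' absent from the file yield an incomplete profile which downstream
#' operations refuse.
#'
#' @param path file path
#' @param genome a [genome_model()] the table must be consistent with
#' @export
read_bin_table <- function(path, genome) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                          vapply(kv, `[`, "", 1))
  body <- which(!startsWith(lines, "#"))
  if (length(body) < 1) stop("empty bin table: ", path)
  header <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  need <- c("chromosome", "bin_start", "bin_end", "value")
  if (!identical(header, need))
    stop("bin table header must be: ", paste(need, collapse = ", "))
  values <- rep(NA_real_, genome$n_bins)
  seen <- character(0)
  for (li in body[-1]) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      stop(sprintf("line %d: expected 4 fields, got %d", li, length(f)))
    ch <- f[1]
    st <- suppressWarnings(as.numeric(f[2]))
    en <- suppressWarnings(as.numeric(f[3]))
    va <- suppressWarnings(as.numeric(f[4]))
    if (anyNA(c(st, en, va)))
      stop(sprintf("line %d: non-numeric field", li))
    if (!ch %in% genome$chroms)
      stop(sprintf("line %d: unknown chromosome %s", li, ch))
    k <- st %/% genome$bin_size + 1L
    gi <- chrom_bins(genome, ch)
    if (k < 1 || k > length(gi) || genome$bins$start[gi[k]] != st ||
        genome$bins$end[gi[k]] != en)
      stop(sprintf("line %d: bin %s:%s-%s inconsistent with genome model (bin size %d)",
                   li, ch, f[2], f[3], genome$bin_size))
    values[gi[k]] <- va
    seen <- c(seen, ch)
  }
  missing_ch <- setdiff(genome$chroms, unique(seen))
  complete <- length(missing_ch) == 0
  if (!complete) {
    warning("bin table missing chromosomes: ", paste(missing_ch, collapse = ", "),
            "; profile marked incomplete")
    values[is.na(values)] <- 0
  } else if (anyNA(values)) {
    values[is.na(values)] <- 0
  }
  getm <- function(k) if (k %in% names(meta)) meta[[k]] else NULL
  ff <- if (!is.null(getm("ff"))) as.numeric(getm("ff")) else NULL
  tr <- if (!is.null(getm("total_reads"))) as.numeric(getm("total_reads")) else NULL
  bin_profile(genome, values,
              state = getm("state") %||% "raw",
              ff = ff,
              sample_id = getm("sample_id"),
              total_reads = tr,
              complete = complete)
}

#' @rdname read_bin_table
#' @param profile a [bin_profile()]
#' @export
write_bin_table <- function(profile, path) {
  stopifnot(inherits(profile, "bin_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#state=%s", profile$state), con)
  if (!is.null(profile$total_reads))
    writeLines(sprintf("#total_reads=%.10g", profile$total_reads), con)
  if (!is.null(profile$ff)) writeLines(sprintf("#ff=%.10g", profile$ff), con)
  if (!is.null(profile$sample_id))
    writeLines(sprintf("#sample_id=%s", profile$sample_id), con)
  df <- data.frame(chromosome = profile$genome$bins$chrom,
                   bin_start = profile$genome$bins$start,
                   bin_end = profile$genome$bins$end,
                   value = profile$values)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bin a coordinate-sorted indexed BAM file
#'
#' Convenience wrapper equivalent to [bin_reads()] applied to the leftmost
#' mapped position of each primary, uniquely mapped read. Secondary,
#' supplementary, unmapped and duplicate-flagged reads are skipped and
#' reported in a message. Requires the Rsamtools package.
#'
#' @param bam_path path to an indexed BAM
#' @param genome a [genome_model()]
#' @param sample_id optional sample identifier
#' @export
bin_bam <- function(bam_path, genome, sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("bin_bam requires the Rsamtools package")
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM file must be indexed: ", bam_path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos"))
  res <- Rsamtools::scanBam(bam_path, param = par)[[1]]
  keep <- !is.na(res$pos) & as.character(res$rname) %in% genome$chroms
  n_total <- Rsamtools::countBam(bam_path)$records
  n_used <- sum(keep)
  if (n_used < n_total)
    message(sprintf("bin_bam: skipped %d of %d records (unmapped/secondary/duplicate/off-model)",
                    n_total - n_used, n_total))
  pos <- split(as.numeric(res$pos[keep]) - 1, as.character(res$rname[keep]))
  bin_reads(pos, genome, sample_id = sample_id)
}
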