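#' Deletion records with pathogenicity labels
#'
#' Records are plain data.frames with columns `chrom`, `start`, `end`
#' (0-based half-open), `classification` (one of pathogenic,
#' likely_pathogenic, benign, likely_benign) and `id`.
#'
#' @param path TSV/BED-style file with columns chrom, start, end,
#'   classification and optionally id (header required)
#' @export
read_deletion_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "classification")
  if (!all(need %in% names(df)))
    stop("deletion record file must have columns: ", paste(need, collapse = ", "))
  if (!"id" %in% names(df)) df$id <- sprintf("rec%04d", seq_len(nrow(df)))
  validate_records(df)
  df
}

validate_records <- function(records) {
  ok <- c("pathogenic", "likely_pathogenic", "benign", "likely_benign")
  bad <- setdiff(unique(records$classification), ok)
  if (length(bad))
    stop("unknown classification: ", paste(bad, collapse = ", "))
  if (any(records$start >= records$end))
    stop("deletion records must have start < end")
  invisible(records)
}

pathogenic_classes <- function() c("pathogenic", "likely_pathogenic")
benign_classes <- function() c("benign", "likely_benign")

#' Per-base deletion coverage as a step function
#'
#' Coverage at position p is the number of filtered records with
#' `start <= p < end`, computed by a sweep over interval endpoints.
#'
#' @param records deletion records on a single chromosome
#' @param classes classification labels to include (default: pathogenic
#'   and likely pathogenic)
#' @return data.frame (start, end, coverage) of maximal constant pieces
#'   with positive extent, ordered by position; zero rows when no record
#'   matches
#' @export
coverage_profile <- function(records, classes = pathogenic_classes()) {
  r <- records[records$classification %in% classes, , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), coverage = numeric(0)))
  if (length(unique(r$chrom)) > 1)
    stop("coverage_profile expects records on a single chromosome")
  pts <- sort(unique(c(r$start, r$end)))
  ev <- stats::aggregate(delta ~ pos,
                         data = rbind(data.frame(pos = r$start, delta = 1),
                                      data.frame(pos = r$end, delta = -1)),
                         FUN = sum)
  ev <- ev[order(ev$pos), ]
  cov <- cumsum(ev$delta)
  data.frame(start = ev$pos[-nrow(ev)], end = ev$pos[-1],
             coverage = cov[-length(cov)])
}

#' Maximal intervals where coverage meets a cutoff
#'
#' @param coverage step function from [coverage_profile()]
#' @param cutoff minimum coverage `c >= 1`
#' @return data.frame (start, end, peak) of maximal intervals with
#'   coverage >= cutoff; `peak` is the maximum coverage inside each
#' @export
region_at_cutoff <- function(coverage, cutoff) {
  stopifnot(cutoff >= 1)
  keep <- coverage$coverage >= cutoff
  if (!any(keep))
    return(data.frame(start = numeric(0), end = numeric(0), peak = numeric(0)))
  cc <- coverage[keep, , drop = FALSE]
  # merge adjacent pieces
  brk <- c(TRUE, cc$start[-1] != cc$end[-nrow(cc)])
  grp <- cumsum(brk)
  out <- do.call(rbind, lapply(split(cc, grp), function(g)
    data.frame(start = g$start[1], end = g$end[nrow(g)],
               peak = max(g$coverage))))
  rownames(out) <- NULL
  out[order(out$start), ]
}

#' Pathogenic records (nearly) outside a region
#'
#' A record is an outlier when its overlap with the region is at most
#' `min_overlap` bp; with `min_overlap = 0` this is exactly "entirely
#' outside". The 20 kb setting reproduces the manual exclusion rule used
#' for distal-deletion records abutting the DiGeorge region's 3' end.
#'
#' @param records deletion records (already filtered to pathogenic
#'   classes by the caller, or mixed; all rows are tested)
#' @param region list or one-row data.frame with `start`, `end`
#' @param min_overlap maximum overlap in bp still counted as an outlier
#' @return the outlier rows of `records`
#' @export
find_outliers <- function(records, region, min_overlap = 0) {
  stopifnot(min_overlap >= 0)
  ov <- pmax(0, pmin(records$end, region$end) - pmax(records$start, region$start))
  records[ov <= min_overlap, , drop = FALSE]
}

#' Derive a syndrome critical region by iterative cutoff lowering
#'
#' Starting from `initial_cutoff` (lowered first to the maximum observed
#' coverage if that is smaller), the region is the maximal interval of
#' pathogenic coverage >= cutoff containing the global coverage maximum.
#' While any non-excluded pathogenic record has overlap <= `min_overlap`
#' with the region, the cutoff is decremented by one and the region
#' recomputed. Manual curation is expressed as an explicit, reproducible
#' `exclude` id list.
#'
#' @param records deletion records (pathogenic classes are selected
#'   internally)
#' @param initial_cutoff starting coverage cutoff (default 45)
#' @param exclude character vector of record ids excluded from both the
#'   coverage profile and the outlier audit
#' @param min_overlap outlier overlap tolerance in bp (default 0)
#' @return list of class `critical_region`: `chrom`, `start`, `end`,
#'   `cutoff` (final), `initial_cutoff`, `n_support` (records overlapping
#'   the region by more than `min_overlap`), `excluded`
#' @export
derive_region <- function(records, initial_cutoff = 45, exclude = NULL,
                          min_overlap = 0) {
  validate_records(records)
  path <- records[records$classification %in% pathogenic_classes() &
                    !(records$id %in% exclude), , drop = FALSE]
  if (nrow(path) == 0)
    stop("no pathogenic records after exclusions")
  cov <- coverage_profile(path)
  cmax <- max(cov$coverage)
  cutoff <- min(initial_cutoff, cmax)
  repeat {
    regions <- region_at_cutoff(cov, cutoff)
    # take the interval containing the global coverage maximum
    reg <- regions[which.max(regions$peak), ]
    out <- find_outliers(path, reg, min_overlap)
    if (nrow(out) == 0) break
    cutoff <- cutoff - 1
    if (cutoff < 1)
      stop("cutoff reached zero with outliers remaining; ",
           "manual exclusion of distinct-entity records is required (ids: ",
           paste(utils::head(out$id, 5), collapse = ", "), ")")
  }
  structure(list(chrom = path$chrom[1], start = reg$start, end = reg$end,
                 cutoff = cutoff, initial_cutoff = initial_cutoff,
                 n_support = nrow(path) - nrow(find_outliers(path, reg, min_overlap)),
                 excluded = exclude %||% character(0)),
            class = "critical_region")
}

#' @export
print.critical_region <- function(x, ...) {
  cat(sprintf("critical_region %s:%s-%s (1-based: %s-%s), cutoff %d, %d supporting records\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","),
              format(x$start + 1, big.mark = ","),
              format(x$end, big.mark = ","),
              x$cutoff, x$n_support))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write a 1-based critical-region report and the coverage step function
#'
#' @param regions named list of `critical_region` objects (names are
#'   syndrome labels)
#' @param path output TSV (columns Syndrome, Chromosome, Start position,
#'   End position, Coverage cutoff; 1-based inclusive coordinates)
#' @export
write_region_report <- function(regions, path) {
  df <- do.call(rbind, lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    data.frame(Syndrome = nm, Chromosome = r$chrom,
               Start.position = format(r$start + 1, scientific = FALSE, trim = TRUE),
               End.position = format(r$end, scientific = FALSE, trim = TRUE),
               Coverage.cutoff = r$cutoff)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shipped critical-region preset
#'
#' ISCA-derived critical regions for the five screened microdeletion
#' syndromes (hg19, 1-based inclusive) with the final coverage cutoff
#' that produced each. Reproducing them requires an ISCA database
#' snapshot, which is external; they ship as a documented preset for use
#' as spike-in targets and report annotation.
#'
#' @return data.frame (syndrome, chrom, start_1based, end_1based, cutoff)
#' @export
critical_region_preset <- function() {
  path <- system.file("extdata", "syndrome_critical_regions.tsv",
                      package = "niptcnv", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
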