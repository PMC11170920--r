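#' Test whether two intervals overlap
#'
#' Two intervals overlap when they share a chromosome and at least `min_bp`
#' bases. Half-open coordinates mean book-ended intervals ([0,10) and
#' [10,20)) do not overlap.
#'
#' @param a,b single-row interval data frames (or lists with chrom/start/end).
#' @param min_bp minimum overlap in bases (default 1).
#' @return Logical scalar.
#' @export
overlaps <- function(a, b, min_bp = 1) {
  stop_if(min_bp < 1, "min_bp must be a positive integer")
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  (min(a$end[1], b$end[1]) - max(a$start[1], b$start[1])) >= min_bp
}

#' Vectorized any-overlap test
#'
#' For each interval in `query`, whether it overlaps at least `min_bp`
#' bases of any interval in `subject`.
#'
#' @param query,subject interval data frames.
#' @param min_bp minimum overlap in bases.
#' @return Logical vector along the rows of `query`.
#' @export
overlap_any <- function(query, subject, min_bp = 1) {
  validate_bed(query); validate_bed(subject)
  if (!nrow(query)) return(logical(0))
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  hits <- GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                                       minoverlap = min_bp,
                                       ignore.strand = TRUE)
  hits > 0
}

#' Merge overlapping and book-ended intervals
#'
#' Fuses intervals that overlap or abut (distance 0), mirroring default
#' `bedtools merge` semantics. With `track_sources = TRUE` the merged
#' interval's `name` is the comma-joined names of its constituents in
#' positional order (the `-c 4 -o collapse` idiom used to preserve
#' species-of-origin when merging lifted interval sets).
#'
#' @param df interval data frame (may be unsorted).
#' @param track_sources join constituent names into the output `name` column.
#' @return Sorted, non-overlapping interval data frame.
#' @export
merge_intervals <- function(df, track_sources = FALSE) {
  validate_bed(df)
  if (!nrow(df)) return(df)
  gr <- as_granges(df)
  GenomicRanges::strand(gr) <- "*"
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 1L)
  out <- granges_as_bed(red)
  if (track_sources) {
    stop_if(is.null(df$name), "track_sources requires a name column")
    revmap <- S4Vectors::mcols(red)$revmap
    out$name <- vapply(seq_along(revmap), function(i) {
      idx <- revmap[[i]]
      idx <- idx[order(df$start[idx], df$end[idx])]
      paste(df$name[idx], collapse = ",")
    }, "")
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Subtract one interval set from another
#'
#' Returns the portions of the union of `a` not covered by any interval in
#' `b`, so that total returned length equals length(a) - length(a intersect b)
#' (lengths of the respective unions).
#'
#' @param a,b interval data frames.
#' @return Sorted interval data frame.
#' @export
subtract_intervals <- function(a, b) {
  validate_bed(a); validate_bed(b)
  if (!nrow(a)) return(a[, c("chrom", "start", "end")])
  ga <- GenomicRanges::reduce(as_granges(a), min.gapwidth = 1L,
                              ignore.strand = TRUE)
  if (!nrow(b)) return(granges_as_bed(ga))
  gb <- GenomicRanges::reduce(as_granges(b), min.gapwidth = 1L,
                              ignore.strand = TRUE)
  granges_as_bed(GenomicRanges::setdiff(ga, gb, ignore.strand = TRUE))
}

#' Derive promoter windows upstream of transcription start sites
#'
#' For a TSS on the + strand at position p (the `start` of its interval) the
#' promoter window is [max(0, p - window_bp), p); for a - strand TSS at p
#' (the `end` of its interval) it is [p, p + window_bp). Windows are clipped
#' to chromosome bounds when `chrom_sizes` is supplied.
#'
#' @param tss interval data frame with a strand column (`+` or `-`).
#' @param window_bp window size in bases (default 2000, the conventional
#'   promoter exclusion zone upstream of a TSS).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return Interval data frame of promoter windows (degenerate zero-length
#'   windows at contig edges are dropped).
#' @export
derive_promoters <- function(tss, window_bp = 2000, chrom_sizes = NULL) {
  validate_bed(tss, require_strand = TRUE)
  stop_if(window_bp < 1, "window_bp must be positive")
  if (!nrow(tss)) return(tss[, c("chrom", "start", "end")])
  plus <- tss$strand == "+"
  p <- ifelse(plus, tss$start, tss$end)
  start <- ifelse(plus, pmax(0, p - window_bp), p)
  end <- ifelse(plus, p, p + window_bp)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[tss$chrom]
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  keep <- start < end
  data.frame(chrom = tss$chrom[keep], start = start[keep], end = end[keep],
             stringsAsFactors = FALSE)
}
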