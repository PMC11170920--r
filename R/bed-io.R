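#' Genomic intervals as BED-style data frames
#'
#' Throughout the package a set of genomic intervals is a plain `data.frame`
#' with columns `chrom` (character), `start` and `end` (0-based half-open,
#' `start < end`), and optionally `name` (character), `score` (numeric) and
#' `strand` (one of `"+"`, `"-"`, `"."`). All coordinates are 0-based
#' half-open everywhere in memory and in every BED file read or written;
#' conversion to the 1-based closed convention happens only internally at the
#' IRanges boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name,score,strand optional columns.
#' @return A validated interval data frame.
#' @export
bed_frame <- function(chrom, start, end, name = NULL, score = NULL,
                      strand = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name))   df$name   <- as.character(name)
  if (!is.null(score))  df$score  <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_bed(df)
  df
}

validate_bed <- function(df, require_strand = FALSE) {
  stop_if(!is.data.frame(df), "intervals must be a data.frame")
  stop_if(!all(c("chrom", "start", "end") %in% names(df)),
          "interval data.frame needs chrom/start/end columns")
  if (nrow(df)) {
    stop_if(any(df$start < 0), "negative start coordinate")
    bad <- which(df$start >= df$end)
    stop_if(length(bad) > 0,
            "empty or inverted interval (start >= end) at row %d", bad[1])
    if (require_strand) {
      stop_if(is.null(df$strand) || any(!df$strand %in% c("+", "-")),
              "strand (+/-) required for every interval")
    }
  }
  invisible(df)
}

#' Read a BED file
#'
#' Tab-separated, headerless BED in the bed3, bed4 (name) or bed6
#' (name, score, strand) dialect. Coordinates are taken verbatim (BED is
#' already 0-based half-open).
#'
#' @param path path to a BED file.
#' @param dialect one of `"bed3"`, `"bed4"`, `"bed6"`.
#' @return An interval data frame in file order.
#' @export
read_bed <- function(path, dialect = c("bed3", "bed4", "bed6")) {
  dialect <- match.arg(dialect)
  stop_if(!file.exists(path), "BED file not found: %s", path)
  ncol_needed <- c(bed3 = 3L, bed4 = 4L, bed6 = 6L)[[dialect]]
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(bed_frame(character(), numeric(), numeric() + 1)[0, , drop = FALSE])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  stop_if(length(bad) > 0, "malformed BED line %d in %s: %d field(s), need %d",
          bad[1], path, nf[bad[1]], ncol_needed)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  stop_if(length(bad) > 0, "non-numeric coordinates on line %d of %s",
          bad[1], path)
  bad <- which(start >= end)
  stop_if(length(bad) > 0, "start >= end on line %d of %s", bad[1], path)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (dialect %in% c("bed4", "bed6")) {
    df$name <- vapply(fields, `[[`, "", 4L)
  }
  if (dialect == "bed6") {
    df$score  <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    df$strand <- vapply(fields, `[[`, "", 6L)
  }
  df
}

#' Write intervals as BED
#'
#' Emits tab-separated headerless BED, sorted by (chrom, start, end). The
#' dialect is inferred from the columns present (`strand` implies bed6, in
#' which case a missing `score` is written as 0 and a missing `name` as
#' `"."`).
#'
#' @param df interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_bed(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  cols <- list(df$chrom, format_coord(df$start), format_coord(df$end))
  if (!is.null(df$strand)) {
    cols <- c(cols, list(df$name %||% rep(".", nrow(df)),
                         df$score %||% rep(0, nrow(df)), df$strand))
  } else if (!is.null(df$score)) {
    cols <- c(cols, list(df$name %||% rep(".", nrow(df)), df$score))
  } else if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

# 0-based half-open data.frame -> GRanges (1-based closed) and back
as_granges <- function(df) {
  validate_bed(df)
  strand <- if (!is.null(df$strand)) df$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end),
                         strand = strand)
}

granges_as_bed <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df
}

#' Read a two-column chromosome sizes table
#'
#' @param path TSV with columns chrom, size (no header).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "size"),
                    stringsAsFactors = FALSE)
  setNames(as.numeric(tab$size), tab$chrom)
}
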