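#' Block coordinate map between two genomes
#'
#' A liftOver-style surrogate: a set of aligned block pairs of equal length,
#' non-overlapping and order-preserving within each chromosome on both
#' genomes. Bases falling between blocks are unmapped (indel gaps).
#'
#' @param blocks data frame with columns src_chrom, src_start, src_end,
#'   tgt_chrom, tgt_start, tgt_end (0-based half-open; paired blocks must
#'   have equal lengths).
#' @param min_match minimum fraction of an interval's bases that must lie in
#'   aligned blocks for the interval to map (default 0.8, the liftOver
#'   minMatch convention).
#' @return A `coordinate_map` object.
#' @export
coordinate_map <- function(blocks, min_match = 0.8) {
  need <- c("src_chrom", "src_start", "src_end",
            "tgt_chrom", "tgt_start", "tgt_end")
  stop_if(!all(need %in% names(blocks)), "map blocks need columns: %s",
          paste(need, collapse = ", "))
  stop_if(min_match <= 0 || min_match > 1, "min_match must be in (0, 1]")
  if (nrow(blocks)) {
    stop_if(any(blocks$src_end - blocks$src_start !=
                  blocks$tgt_end - blocks$tgt_start),
            "paired map blocks must have equal lengths")
    blocks <- blocks[order(blocks$src_chrom, blocks$src_start), ,
                     drop = FALSE]
    ov <- unlist(tapply(seq_len(nrow(blocks)), blocks$src_chrom, function(i) {
      if (length(i) < 2) return(FALSE)
      blocks$src_start[i][-1] < blocks$src_end[i][-length(i)]
    }))
    stop_if(any(ov), "map blocks overlap on the source genome")
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, min_match = min_match),
            class = "coordinate_map")
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat(sprintf("coordinate map: %d block(s), %d source chromosome(s), minMatch %.2f\n",
              nrow(x$blocks), length(unique(x$blocks$src_chrom)),
              x$min_match))
  invisible(x)
}

#' Invert a coordinate map
#'
#' Swaps source and target genomes (block pairs are symmetric).
#'
#' @param map a [coordinate_map()].
#' @return The inverted map.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "coordinate_map"))
  b <- map$blocks
  coordinate_map(data.frame(src_chrom = b$tgt_chrom, src_start = b$tgt_start,
                            src_end = b$tgt_end, tgt_chrom = b$src_chrom,
                            tgt_start = b$src_start, tgt_end = b$src_end,
                            stringsAsFactors = FALSE),
                 min_match = map$min_match)
}

#' Read / write a coordinate map TSV
#'
#' Six tab-separated columns, no header:
#' srcChrom srcStart srcEnd tgtChrom tgtStart tgtEnd.
#'
#' @param path file path.
#' @param min_match passed to [coordinate_map()].
#' @export
read_coordinate_map <- function(path, min_match = 0.8) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("src_chrom", "src_start", "src_end",
                                  "tgt_chrom", "tgt_start", "tgt_end"),
                    stringsAsFactors = FALSE)
  coordinate_map(tab, min_match = min_match)
}

#' @rdname read_coordinate_map
#' @param map a [coordinate_map()].
#' @export
write_coordinate_map <- function(map, path) {
  stopifnot(inherits(map, "coordinate_map"))
  b <- map$blocks
  write.table(data.frame(b$src_chrom, format_coord(b$src_start),
                         format_coord(b$src_end), b$tgt_chrom,
                         format_coord(b$tgt_start),
                         format_coord(b$tgt_end)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Map one interval through a coordinate map
#'
#' Returns the target-genome span running from the mapped position of the
#' interval's first mappable base to that of its last, provided at least
#' `min_match` of its bases lie in aligned blocks and all touched blocks are
#' co-linear on a single target chromosome. Otherwise the interval is
#' unmapped (returned as `NA` -- a value, not an error).
#'
#' @param chrom,start,end the source interval (0-based half-open).
#' @param map a [coordinate_map()].
#' @return A list(chrom, start, end), with NA fields when unmapped.
#' @export
map_interval <- function(chrom, start, end, map) {
  stopifnot(inherits(map, "coordinate_map"))
  b <- map$blocks
  unmapped <- list(chrom = NA_character_, start = NA_real_, end = NA_real_)
  rows <- which(b$src_chrom == chrom & b$src_start < end & b$src_end > start)
  if (!length(rows)) return(unmapped)
  rows <- rows[order(b$src_start[rows])]
  ov_start <- pmax(b$src_start[rows], start)
  ov_end <- pmin(b$src_end[rows], end)
  mapped_bases <- sum(ov_end - ov_start)
  if (mapped_bases / (end - start) < map$min_match) return(unmapped)
  tchrom <- unique(b$tgt_chrom[rows])
  if (length(tchrom) != 1) return(unmapped)
  # co-linearity: target blocks must advance in the same order as source
  tstarts <- b$tgt_start[rows]
  if (is.unsorted(tstarts, strictly = TRUE) && length(rows) > 1) {
    return(unmapped)
  }
  first <- rows[1]; last <- rows[length(rows)]
  t_first <- b$tgt_start[first] + (ov_start[1] - b$src_start[first])
  t_last <- b$tgt_start[last] +
    (ov_end[length(rows)] - 1 - b$src_start[last])
  list(chrom = tchrom, start = t_first, end = t_last + 1)
}

#' Map many intervals
#'
#' Vectorized wrapper over [map_interval()]; unmapped rows have NA
#' coordinates.
#'
#' @param df interval data frame (source coordinates).
#' @param map a [coordinate_map()].
#' @return Data frame of mapped intervals, row-parallel to `df`.
#' @export
map_intervals <- function(df, map) {
  validate_bed(df)
  if (!nrow(df)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(df)), function(i) {
    map_interval(df$chrom[i], df$start[i], df$end[i], map)
  })
  data.frame(chrom = vapply(res, `[[`, "", "chrom"),
             start = vapply(res, `[[`, 0, "start"),
             end = vapply(res, `[[`, 0, "end"), stringsAsFactors = FALSE)
}
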