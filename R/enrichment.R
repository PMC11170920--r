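#' Percentage of oCGIs overlapping at least one peak
#'
#' @param ocgis interval data frame (must be non-empty).
#' @param peaks interval data frame.
#' @param min_bp minimum overlap in bases (default 1).
#' @return Percent in [0, 100].
#' @export
overlap_fraction <- function(ocgis, peaks, min_bp = 1) {
  validate_bed(ocgis)
  stop_if(!nrow(ocgis), "overlap_fraction of an empty oCGI set is undefined")
  100 * mean(overlap_any(ocgis, peaks, min_bp = min_bp))
}

# sorted, merged per-chromosome interval lookup for fast point queries
interval_lookup <- function(df) {
  if (is.null(df) || !nrow(df)) return(list())
  merged <- merge_intervals(df)
  lapply(split(merged, merged$chrom),
         function(x) list(start = x$start, end = x$end))
}

# does [s, e) on `lk` (one chromosome's lookup entry) hit any interval?
lookup_hit <- function(lk, s, e) {
  if (is.null(lk)) return(rep(FALSE, length(s)))
  n <- length(lk$start)
  k <- findInterval(s, lk$start)
  (k >= 1 & lk$end[pmax(k, 1)] > s) | (k < n & lk$start[pmin(k + 1, n)] < e)
}

#' Redistribute intervals uniformly at random on their own chromosomes
#'
#' One shuffling round: each interval is placed uniformly at random on its
#' own chromosome, preserving its length, overlapping neither the excluded
#' regions nor any previously placed interval (the semantics of
#' `bedtools shuffle -chrom -noOverlapping`). Placement is by rejection
#' sampling with a retry cap; an interval that cannot be placed raises an
#' error naming its chromosome.
#'
#' @param df interval data frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param excluded interval data frame of forbidden regions (or a prebuilt
#'   internal lookup).
#' @param max_attempts placement attempts per interval before failing.
#' @return Data frame of shuffled intervals, row-parallel to `df`.
#' @export
shuffle_intervals <- function(df, chrom_sizes, excluded = NULL,
                              max_attempts = 10000) {
  excl <- if (is.data.frame(excluded)) interval_lookup(excluded)
          else excluded %||% list()
  chroms <- df$chrom
  lens <- df$end - df$start
  out_start <- numeric(length(lens))
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    idx <- idx[order(lens[idx], decreasing = TRUE)]  # big ones first
    stop_if(is.na(chrom_sizes[chrom]), "no size for chromosome %s", chrom)
    csize <- chrom_sizes[[chrom]]
    ex <- excl[[chrom]]
    np <- 0L
    ps <- numeric(length(idx)); pe <- numeric(length(idx))
    for (i in idx) {
      len <- lens[i]
      lim <- csize - len
      stop_if(lim < 0, "interval longer than chromosome %s", chrom)
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        s <- floor(runif(1, 0, lim + 1))
        e <- s + len
        if (!is.null(ex) && lookup_hit(ex, s, e)) next
        if (np > 0L && any(ps[seq_len(np)] < e & pe[seq_len(np)] > s)) next
        ok <- TRUE
        break
      }
      stop_if(!ok,
              "could not place a %d bp interval on %s after %d attempts",
              len, chrom, max_attempts)
      np <- np + 1L
      ps[np] <- s; pe[np] <- e
      out_start[i] <- s
    }
  }
  data.frame(chrom = chroms, start = out_start, end = out_start + lens,
             stringsAsFactors = FALSE)
}

#' Genomic shuffle test for oCGI/peak overlap enrichment
#'
#' Compares the observed percentage of oCGIs overlapping peaks to a null in
#' which oCGI intervals are redistributed uniformly at random on their own
#' chromosomes (length-preserving, non-overlapping, avoiding excluded
#' regions: annotated features plus repeat-masked sequence). Because real
#' oCGI sets are additionally filtered through the human genome, each
#' shuffled set is passed through [cross_species_filter()] when a map is
#' supplied, and only the survivors are scored. The expected value is the
#' mean shuffled overlap percentage; the p-value is a two-sided add-one
#' permutation p:
#' p = (1 + #rounds with |shuffled - expected| >= |observed - expected|) /
#' (1 + rounds).
#'
#' @param ocgis oCGI interval data frame.
#' @param peaks peak interval data frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param excluded intervals unavailable to shuffled placements.
#' @param map_to_human,human_exclude optional [coordinate_map()] and human
#'   feature sets re-applying the cross-species filter per round.
#' @param rounds number of shuffling rounds (>= 1; 20,000 at full scale).
#' @param seed optional integer seed.
#' @param check_rounds assert length/chromosome preservation and exclusion
#'   avoidance for every round (used by the test suite).
#' @return List with observed, expected, p_value, and the per-round shuffled
#'   percentages.
#' @export
shuffle_test <- function(ocgis, peaks, chrom_sizes, excluded = NULL,
                         map_to_human = NULL, human_exclude = list(),
                         rounds = 20000, seed = NULL, check_rounds = FALSE) {
  stop_if(rounds < 1, "rounds must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- overlap_fraction(ocgis, peaks)
  excl_lk <- interval_lookup(excluded)
  peak_lk <- interval_lookup(peaks)
  frac_against_peaks <- function(df) {
    if (!nrow(df)) return(0)
    hit <- logical(nrow(df))
    for (chrom in unique(df$chrom)) {
      j <- df$chrom == chrom
      hit[j] <- lookup_hit(peak_lk[[chrom]], df$start[j], df$end[j])
    }
    100 * mean(hit)
  }
  fractions <- numeric(rounds)
  for (r in seq_len(rounds)) {
    sh <- shuffle_intervals(ocgis, chrom_sizes, excl_lk)
    if (check_rounds) {
      stopifnot(all(sh$end - sh$start == ocgis$end - ocgis$start),
                all(sh$chrom == ocgis$chrom),
                is.null(excluded) || !nrow(excluded) ||
                  !any(overlap_any(sh, excluded)))
    }
    if (!is.null(map_to_human)) {
      sh <- cross_species_filter(sh, map_to_human, human_exclude)
    }
    fractions[r] <- frac_against_peaks(sh)
  }
  expected <- mean(fractions)
  p <- (1 + sum(abs(fractions - expected) >= abs(observed - expected))) /
    (1 + rounds)
  list(observed = observed, expected = expected, p_value = p,
       fractions = fractions)
}

#' Reads per kilobase per million mapped reads
#'
#' @param peak_length_bp peak length in bases (> 0).
#' @param read_count reads falling in the peak.
#' @param library_size total mapped reads in the library (> 0).
#' @return RPKM value(s); vectorized.
#' @export
quantify_rpkm <- function(peak_length_bp, read_count, library_size) {
  stop_if(any(library_size <= 0), "library size must be positive")
  stop_if(any(peak_length_bp <= 0), "peak length must be positive")
  read_count / ((peak_length_bp / 1000) * (library_size / 1e6))
}

#' Summarize constrained-element overlap for an interval
#'
#' Reports the maximum LOD score among overlapping elements, the aggregate
#' (summed) LOD across them, and the fraction of the interval's bases
#' covered by at least one element. No overlap gives (0, 0, 0).
#'
#' @param chrom,start,end the query interval.
#' @param elements data frame with chrom/start/end and a `score` column of
#'   non-negative LOD values.
#' @return List with max_lod, aggregate_lod, covered_fraction.
#' @export
conservation_summary <- function(chrom, start, end, elements) {
  validate_bed(elements)
  stop_if(!is.null(elements$score) && any(elements$score < 0),
          "LOD scores must be non-negative")
  hit <- elements$chrom == chrom & elements$start < end &
    elements$end > start
  if (!any(hit)) {
    return(list(max_lod = 0, aggregate_lod = 0, covered_fraction = 0))
  }
  e <- elements[hit, , drop = FALSE]
  cov <- merge_intervals(data.frame(chrom = e$chrom,
                                    start = pmax(e$start, start),
                                    end = pmin(e$end, end),
                                    stringsAsFactors = FALSE))
  list(max_lod = max(e$score), aggregate_lod = sum(e$score),
       covered_fraction = sum(cov$end - cov$start) / (end - start))
}

#' Ordered sequence-age categories
#'
#' Raw segmentation ages from youngest to oldest; the most ancient three are
#' collapsed into "OlderThanAmniota" on assignment.
#' @export
age_levels <- function() {
  c("Human", "Ape", "Primate", "Eutheria", "Theria", "Mammalia",
    "Amniota", "Tetrapoda", "Gnathostomata", "Vertebrata")
}

#' Assign a sequence age to an interval
#'
#' Takes the most ancient raw age among age-map segments overlapping the
#' interval (ages are assigned on the human genome and inferred for other
#' species through their human ortholog), collapses
#' Tetrapoda/Gnathostomata/Vertebrata into "OlderThanAmniota", and converts
#' the age to "Unknown" when it names a clade that does not contain the
#' query species (e.g. a pig interval dated "Human").
#'
#' @param chrom,start,end query interval in human coordinates.
#' @param age_map data frame with chrom/start/end and a `name` column of raw
#'   ages (disjoint segments).
#' @param species_valid_ages character vector of raw ages naming clades that
#'   contain the query species; defaults to all.
#' @return A single age label.
#' @export
assign_age <- function(chrom, start, end, age_map,
                       species_valid_ages = age_levels()) {
  validate_bed(age_map)
  hit <- age_map$chrom == chrom & age_map$start < end & age_map$end > start
  if (!any(hit)) return("Unknown")
  ages <- age_map$name[hit]
  ranks <- match(ages, age_levels())
  stop_if(any(is.na(ranks)), "unrecognized age label: %s",
          paste(unique(ages[is.na(ranks)]), collapse = ", "))
  oldest <- ages[which.max(ranks)]
  if (!oldest %in% species_valid_ages) return("Unknown")
  if (oldest %in% c("Tetrapoda", "Gnathostomata", "Vertebrata")) {
    return("OlderThanAmniota")
  }
  oldest
}
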