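#' Build a feature set for orphan filtering
#'
#' A feature set is an interval data frame tagged with an annotation
#' category. `tss` features must carry strand (promoter windows are derived
#' from them); every other category is excluded by direct overlap.
#'
#' @param intervals interval data frame.
#' @param category one of `"exon"`, `"tss"`, `"blacklist"`,
#'   `"fantom_promoter"`, `"repeat_mask"`, `"other"`.
#' @return The intervals, sorted, with a `category` attribute.
#' @export
feature_set <- function(intervals,
                        category = c("exon", "tss", "blacklist",
                                     "fantom_promoter", "repeat_mask",
                                     "other")) {
  category <- match.arg(category)
  validate_bed(intervals, require_strand = category == "tss")
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  attr(intervals, "category") <- category
  intervals
}

feature_category <- function(fs) attr(fs, "category") %||% "other"

# expand a list of feature sets into the exclusion intervals they imply:
# tss sets become promoter windows (and, when flagged fantom_promoter with
# strand, the same derivation applies); all other sets are excluded as-is.
exclusion_intervals <- function(features, promoter_window_bp = 2000,
                                chrom_sizes = NULL) {
  pieces <- lapply(features, function(fs) {
    if (feature_category(fs) %in% c("tss", "fantom_promoter") &&
        !is.null(fs$strand)) {
      derive_promoters(fs, promoter_window_bp, chrom_sizes)
    } else {
      fs[, c("chrom", "start", "end")]
    }
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  out
}

#' Filter CGI calls down to orphan CGIs
#'
#' Removes any CGI overlapping (by at least 1 bp) an exon, a derived promoter
#' window (2 kb upstream of a TSS by default), a blacklist interval, or a
#' promoter annotated from CAGE data -- i.e. any supplied feature set.
#' Exclusion categories are data-driven: whichever feature sets are supplied
#' are excluded, so species with richer annotation (extra blacklist or CAGE
#' promoter sets) are configuration, not special-cased code. Survivors keep
#' their order and statistics.
#'
#' @param cgis CGI call data frame (from [segment_cgis()]).
#' @param features list of [feature_set()] objects; must include `exon` and
#'   `tss` categories.
#' @param promoter_window_bp promoter window size upstream of each TSS.
#' @param chrom_sizes optional named vector for clipping promoter windows.
#' @return The surviving calls.
#' @export
filter_orphan <- function(cgis, features, promoter_window_bp = 2000,
                          chrom_sizes = NULL) {
  validate_bed(cgis)
  cats <- vapply(features, feature_category, "")
  stop_if(!all(c("exon", "tss") %in% cats),
          "features must include at least exon and tss categories")
  excl <- exclusion_intervals(features, promoter_window_bp, chrom_sizes)
  if (!nrow(cgis) || !nrow(excl)) return(cgis)
  hit <- overlap_any(cgis, excl, min_bp = 1)
  cgis[!hit, , drop = FALSE]
}

#' Cross-species (human-intermediate) orphan filter
#'
#' Restricts oCGIs to those with orthologous sequence in the human genome
#' whose mapped interval overlaps none of the human exclusion features.
#' oCGIs that fail to map (insufficient aligned bases or non-co-linear
#' projection) are removed. Survivors keep their source-genome coordinates.
#'
#' @param ocgis oCGI data frame in source-genome coordinates.
#' @param map_to_human a [coordinate_map()] from the source genome to human.
#' @param human_features list of [feature_set()] objects annotated in human
#'   (exclusion is by 1 bp overlap with the mapped interval; tss sets are
#'   expanded to promoter windows).
#' @param promoter_window_bp promoter window for human tss sets.
#' @return The surviving oCGIs (source coordinates).
#' @export
cross_species_filter <- function(ocgis, map_to_human, human_features = list(),
                                 promoter_window_bp = 2000) {
  validate_bed(ocgis)
  if (!nrow(ocgis)) return(ocgis)
  mapped <- map_intervals(ocgis, map_to_human)
  keep <- !is.na(mapped$start)
  excl <- exclusion_intervals(human_features, promoter_window_bp)
  if (nrow(excl) && any(keep)) {
    hit <- overlap_any(mapped[keep, , drop = FALSE], excl, min_bp = 1)
    keep[keep] <- !hit
  }
  ocgis[keep, , drop = FALSE]
}
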