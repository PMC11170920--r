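#' Build orthologous oCGI sites for a species pair via a human intermediate
#'
#' Both species' oCGIs are lifted to the human genome; overlapping or
#' book-ended projections are merged into anchors (with source tracking);
#' each anchor whose sequence maps back to *both* species becomes an
#' orthologous site. Presence in a species means an oCGI of that species
#' projects into the anchor; sites are labeled `A_only`, `B_only` or
#' `shared`. The underlying sequence is required in both species even when
#' the oCGI is called in only one, so absence is genuine turnover rather
#' than missing orthology. Anchors whose projections are not co-linear on a
#' single chromosome in a species are dropped with a warning.
#'
#' For a species without an oCGI call at a site, the observed/expected CpG
#' ratio is recomputed on the back-mapped sequence when the species genome is
#' supplied (`seq_A` / `seq_B`); otherwise it is `NA` (treated as 0 by
#' [apply_min_oe_delta()], the conservative maximal-difference reading).
#'
#' @param ocgis_A,ocgis_B orphan-filtered oCGI call data frames; an
#'   `obs_exp_ratio` column is carried through when present.
#' @param map_A_to_human,map_B_to_human,map_human_to_A,map_human_to_B
#'   [coordinate_map()] objects.
#' @param seq_A,seq_B optional named character vectors of genome sequence
#'   used to recompute O/E at absent sites.
#' @return Data frame with one row per site: human anchor coordinates,
#'   per-species intervals (NA where absent), `present_A`, `present_B`,
#'   `oe_A`, `oe_B`, and `label`.
#' @export
build_orthologous_sites <- function(ocgis_A, ocgis_B,
                                    map_A_to_human, map_B_to_human,
                                    map_human_to_A, map_human_to_B,
                                    seq_A = NULL, seq_B = NULL) {
  validate_bed(ocgis_A); validate_bed(ocgis_B)
  proj <- function(ocgis, map, species) {
    if (!nrow(ocgis)) return(NULL)
    m <- map_intervals(ocgis, map)
    ok <- !is.na(m$start)
    if (!any(ok)) return(NULL)
    data.frame(chrom = m$chrom[ok], start = m$start[ok], end = m$end[ok],
               name = paste0(species, ":", which(ok)),
               species = species, src_row = which(ok),
               stringsAsFactors = FALSE)
  }
  pa <- proj(ocgis_A, map_A_to_human, "A")
  pb <- proj(ocgis_B, map_B_to_human, "B")
  all_proj <- rbind(pa, pb)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), chrom_A = character(),
                      start_A = numeric(), end_A = numeric(),
                      chrom_B = character(), start_B = numeric(),
                      end_B = numeric(), present_A = logical(),
                      present_B = logical(), oe_A = numeric(),
                      oe_B = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  if (is.null(all_proj) || !nrow(all_proj)) return(empty)

  anchors <- merge_intervals(all_proj, track_sources = TRUE)
  n_dropped <- 0L
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    members <- strsplit(anchors$name[i], ",", fixed = TRUE)[[1]]
    sp <- sub(":.*", "", members)
    idx <- as.integer(sub(".*:", "", members))
    back_A <- map_interval(anchors$chrom[i], anchors$start[i],
                           anchors$end[i], map_human_to_A)
    back_B <- map_interval(anchors$chrom[i], anchors$start[i],
                           anchors$end[i], map_human_to_B)
    if (is.na(back_A$start) || is.na(back_B$start)) return(NULL)
    present_A <- "A" %in% sp
    present_B <- "B" %in% sp
    oe_of <- function(ocgis, rows_in) {
      if (!is.null(ocgis$obs_exp_ratio)) max(ocgis$obs_exp_ratio[rows_in])
      else NA_real_
    }
    iv_A <- if (present_A) {
      k <- idx[sp == "A"]
      list(chrom = ocgis_A$chrom[k[1]], start = min(ocgis_A$start[k]),
           end = max(ocgis_A$end[k]), oe = oe_of(ocgis_A, k))
    } else {
      oe <- if (!is.null(seq_A) && back_A$chrom %in% names(seq_A)) {
        cgi_stats(seq_A[[back_A$chrom]], back_A$start,
                  back_A$end)$obs_exp_ratio
      } else NA_real_
      list(chrom = back_A$chrom, start = back_A$start, end = back_A$end,
           oe = oe)
    }
    iv_B <- if (present_B) {
      k <- idx[sp == "B"]
      list(chrom = ocgis_B$chrom[k[1]], start = min(ocgis_B$start[k]),
           end = max(ocgis_B$end[k]), oe = oe_of(ocgis_B, k))
    } else {
      oe <- if (!is.null(seq_B) && back_B$chrom %in% names(seq_B)) {
        cgi_stats(seq_B[[back_B$chrom]], back_B$start,
                  back_B$end)$obs_exp_ratio
      } else NA_real_
      list(chrom = back_B$chrom, start = back_B$start, end = back_B$end,
           oe = oe)
    }
    data.frame(chrom = anchors$chrom[i], start = anchors$start[i],
               end = anchors$end[i],
               chrom_A = iv_A$chrom, start_A = iv_A$start, end_A = iv_A$end,
               chrom_B = iv_B$chrom, start_B = iv_B$start, end_B = iv_B$end,
               present_A = present_A, present_B = present_B,
               oe_A = iv_A$oe, oe_B = iv_B$oe,
               label = if (present_A && present_B) "shared"
                       else if (present_A) "A_only" else "B_only",
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, TRUE)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("%d anchor(s) without orthologous sequence in both species dropped",
                    n_dropped))
  }
  if (!any(keep)) return(empty)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  out
}

#' Impose a minimal O/E difference on species-specific sites
#'
#' Species-specific sites whose per-species observed/expected CpG ratios
#' differ by less than `delta` are removed; shared sites are unaffected.
#' Missing O/E values count as 0 (maximal difference). Larger `delta` never
#' increases the species-specific count.
#'
#' @param sites output of [build_orthologous_sites()].
#' @param delta non-negative minimum |oe_A - oe_B|; 0 returns the input.
#' @return Filtered site data frame.
#' @export
apply_min_oe_delta <- function(sites, delta) {
  stop_if(!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
            delta < 0, "delta must be a non-negative number")
  if (delta == 0 || !nrow(sites)) return(sites)
  oe_A <- ifelse(is.na(sites$oe_A), 0, sites$oe_A)
  oe_B <- ifelse(is.na(sites$oe_B), 0, sites$oe_B)
  drop <- sites$label != "shared" & abs(oe_A - oe_B) < delta
  sites[!drop, , drop = FALSE]
}

#' Presence/absence patterns of oCGIs across species
#'
#' Lifts every species' oCGIs to the human genome, merges the projections
#' (preserving species of origin), and reports, per merged site, which
#' species contribute an oCGI.
#'
#' @param ocgi_list named list of oCGI data frames, one per species.
#' @param maps_to_human named list of [coordinate_map()]s (same names).
#' @return Data frame: anchor coordinates plus one logical column per
#'   species.
#' @export
presence_patterns <- function(ocgi_list, maps_to_human) {
  stopifnot(!is.null(names(ocgi_list)),
            all(names(ocgi_list) %in% names(maps_to_human)))
  proj <- do.call(rbind, lapply(names(ocgi_list), function(sp) {
    m <- map_intervals(ocgi_list[[sp]], maps_to_human[[sp]])
    ok <- !is.na(m$start)
    if (!any(ok)) return(NULL)
    data.frame(chrom = m$chrom[ok], start = m$start[ok], end = m$end[ok],
               name = sp, stringsAsFactors = FALSE)
  }))
  species <- names(ocgi_list)
  if (is.null(proj) || !nrow(proj)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
    for (sp in species) out[[sp]] <- logical(0)
    return(out)
  }
  anchors <- merge_intervals(proj, track_sources = TRUE)
  present <- do.call(rbind, lapply(strsplit(anchors$name, ",", fixed = TRUE),
                                   function(x) species %in% x))
  colnames(present) <- species
  cbind(anchors[, c("chrom", "start", "end")], as.data.frame(present))
}

#' Polarize oCGI gains and losses with an outgroup
#'
#' A site counts as a gain on the focal branch when present in the focal
#' species but absent from both the sister species and the outgroup; a loss
#' when absent from the focal species but present in both. All other
#' patterns are unpolarized.
#'
#' @param patterns data frame with one logical presence column per species
#'   (e.g. from [presence_patterns()]).
#' @param focal,sister,outgroup species column names.
#' @return Named integer vector: gain, loss, unpolarized.
#' @export
polarize_gain_loss <- function(patterns, focal, sister, outgroup) {
  for (sp in c(focal, sister, outgroup)) {
    stop_if(!sp %in% names(patterns) || !is.logical(patterns[[sp]]),
            "species '%s' not present as a logical column", sp)
  }
  f <- patterns[[focal]]; s <- patterns[[sister]]; o <- patterns[[outgroup]]
  gain <- f & !s & !o
  loss <- !f & s & o
  c(gain = sum(gain), loss = sum(loss),
    unpolarized = sum(!(gain | loss)))
}
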