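#' Specification for the synthetic multi-species generators
#'
#' Bundles every knob of the seeded generators. Defaults emulate the
#' statistical structure of mammalian comparative data at desk scale:
#' CpG-depleted background (CpG frequency about 0.25 of the iid
#' expectation, mimicking genome-wide deamination-driven depletion),
#' planted islands with controllable GC and observed/expected CpG ratio,
#' pairwise turnover fractions, a tunable oCGI/peak species-specificity
#' coupling, a signal boost at oCGI-containing peaks, indel-bearing
#' coordinate maps, and per-gene expression effects.
#'
#' @param seed master integer seed; every generator is a pure function of
#'   the spec including this seed.
#' @param n_chroms,chrom_length_bp genome shape.
#' @param background_gc background GC fraction.
#' @param cpg_depletion fraction of iid-expected CpGs retained in
#'   background sequence.
#' @param n_islands,island_length_bp,island_gc,island_oe_target planted
#'   island count, length, GC and O/E target (achieved within +/- 0.05).
#' @param mask_fraction fraction of background sequence soft-masked in
#'   blocks.
#' @param turnover_fractions length-3 simplex c(shared, A_only, B_only).
#' @param degrade_cpg_prob probability a CpG is deaminated (C->T) when an
#'   island is planted absent in a species.
#' @param indel_rate_per_kb indel events per kb when deriving each species
#'   from the anchor genome.
#' @param indel_mean_bp mean indel length (geometric).
#' @param peak_coupling factor by which the probability that a peak's
#'   species-specificity matches its oCGI's exceeds the marginal
#'   probability (1 = no association; the observed/expected enrichment of
#'   the matched grid cell equals this factor in expectation).
#' @param peak_fractions length-4 simplex of marginal peak labels
#'   c(A_only, B_only, shared, none).
#' @param signal_boost_at_ocgi multiplicative signal boost for peaks
#'   containing an oCGI.
#' @param n_genes,expression_log2_effect,nb_dispersion expression table
#'   shape: planted log2 fold effect for A-only-set genes (mirrored for
#'   B), negative-binomial size parameter.
#' @param hge_pattern_multiplier fold excess of the human-only oCGI
#'   pattern among HGEs relative to background enhancers.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1,
                           n_chroms = 2, chrom_length_bp = 1e6,
                           background_gc = 0.41, cpg_depletion = 0.25,
                           n_islands = 200, island_length_bp = 400,
                           island_gc = 0.6, island_oe_target = 1.0,
                           mask_fraction = 0.05,
                           turnover_fractions = c(shared = 0.4,
                                                  A_only = 0.3,
                                                  B_only = 0.3),
                           degrade_cpg_prob = 0.9,
                           indel_rate_per_kb = 0.05, indel_mean_bp = 40,
                           peak_coupling = 1,
                           peak_fractions = c(A_only = 0.15, B_only = 0.15,
                                              shared = 0.5, none = 0.2),
                           signal_boost_at_ocgi = 2,
                           n_genes = 2000, expression_log2_effect = 0,
                           nb_dispersion = 20,
                           hge_pattern_multiplier = 1) {
  spec <- as.list(environment())
  stop_if(abs(sum(turnover_fractions) - 1) > 1e-8,
          "turnover_fractions must sum to 1")
  stop_if(abs(sum(peak_fractions) - 1) > 1e-8,
          "peak_fractions must sum to 1")
  stop_if(any(unlist(spec[c("cpg_depletion", "indel_rate_per_kb",
                            "mask_fraction")]) < 0),
          "rates must be non-negative")
  stop_if(peak_coupling < 1, "peak_coupling must be >= 1")
  # theoretical maximum: every C immediately followed by a G gives
  # cpg = gc*L/2 and O/E = 2/gc
  max_oe <- 2 / island_gc
  stop_if(island_oe_target > max_oe,
          "island O/E target %.2f exceeds the achievable maximum %.2f",
          island_oe_target, max_oe)
  structure(spec, class = "synthetic_spec")
}

BASES <- c("A", "C", "G", "T")

random_seq_chars <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  BASES[sample.int(4L, len, replace = TRUE, prob = p)]
}

# thin CpGs in a character vector down to `keep` of those present,
# via deamination (C->T) or the complementary-strand path (G->A)
deplete_cpgs <- function(x, keep) {
  if (keep >= 1) return(x)
  cg <- which(x[-length(x)] == "C" & x[-1] == "G")
  hit <- cg[runif(length(cg)) >= keep]
  if (length(hit)) {
    to_t <- runif(length(hit)) < 0.5
    x[hit[to_t]] <- "T"
    x[hit[!to_t] + 1L] <- "A"
  }
  x
}

# build one island with GC and O/E near targets: exact base composition,
# then local swaps steering the CpG count toward the target
make_island_chars <- function(len, gc, oe_target) {
  n_gc <- round(len * gc / 2) * 2
  x <- sample(c(rep(c("C", "G"), n_gc / 2),
                rep(c("A", "T"), ceiling((len - n_gc) / 2))))[seq_len(len)]
  target_cpg <- round(oe_target * (n_gc / 2)^2 / len)
  for (iter in 1:300) {
    cg <- which(x[-len] == "C" & x[-1] == "G")
    d <- length(cg) - target_cpg
    if (abs(d) <= max(1, round(0.02 * target_cpg))) break
    if (d > 0) {
      # too many CpGs: swap the G of a random CpG with a random non-G base
      k <- cg[sample.int(length(cg), 1)] + 1L
      j <- sample(which(x != "G"), 1)
      tmp <- x[k]; x[k] <- x[j]; x[j] <- tmp
    } else {
      # too few: move a free G directly after a free C
      ci <- which(x == "C")
      ci <- ci[ci < len]
      ci <- ci[x[ci + 1L] != "G"]
      gi <- which(x == "G")
      gi <- gi[gi > 1]
      gi <- gi[x[gi - 1L] != "C"]
      if (!length(ci) || !length(gi)) break
      i1 <- sample(ci, 1); j1 <- sample(gi, 1)
      if (j1 == i1 + 1L) next
      tmp <- x[i1 + 1L]; x[i1 + 1L] <- x[j1]; x[j1] <- tmp
    }
  }
  x
}

#' Generate a genome with planted CpG islands
#'
#' Background sequence has the requested GC with CpGs depleted to
#' `cpg_depletion` of the iid expectation; islands are inserted at
#' recorded, non-overlapping positions with GC and observed/expected CpG
#' ratio within about +/- 0.05 of their targets; optional soft-masked
#' (lowercase) blocks are placed in background sequence and recorded.
#'
#' @param spec a [synthetic_spec()].
#' @return List: `genome` (named character vector), `islands` (BED-style
#'   data frame of planted islands), `masked` (data frame of soft-masked
#'   blocks), `spec`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_per <- ceiling(spec$n_islands / spec$n_chroms)
  genome <- character(spec$n_chroms)
  names(genome) <- paste0("chr", seq_len(spec$n_chroms))
  islands <- NULL; masked <- NULL
  planted <- 0L
  for (ci in seq_len(spec$n_chroms)) {
    len <- spec$chrom_length_bp
    x <- random_seq_chars(len, spec$background_gc)
    x <- deplete_cpgs(x, spec$cpg_depletion)
    n_here <- min(n_per, spec$n_islands - planted)
    pos <- NULL
    if (n_here > 0) {
      # non-overlapping island slots with a flanking margin that shrinks
      # on short or crowded chromosomes
      L <- spec$island_length_bp
      margin <- max(100, min(1000,
                             floor((len - n_here * L) / (2 * n_here + 2))))
      slot <- L + 2 * margin
      stop_if(len <= slot, "chromosome too short for an island slot")
      starts <- sort(sample.int(len - slot, n_here))
      # push apart any slots closer than `slot`
      for (k in seq_along(starts)[-1]) {
        if (starts[k] < starts[k - 1] + slot) {
          starts[k] <- starts[k - 1] + slot
        }
      }
      starts <- starts[starts + slot <= len]
      pos <- starts + margin  # island offset inside its slot
      for (s in pos) {
        x[s:(s + L - 1)] <- make_island_chars(L, spec$island_gc,
                                              spec$island_oe_target)
      }
      if (length(pos)) {
        islands <- rbind(islands, data.frame(
          chrom = names(genome)[ci], start = pos - 1,
          end = pos - 1 + L,
          name = sprintf("island_%d", planted + seq_along(pos)),
          stringsAsFactors = FALSE))
      }
      planted <- planted + length(pos)
    }
    if (spec$mask_fraction > 0) {
      block <- 500L
      n_blocks <- floor(len * spec$mask_fraction / block)
      if (n_blocks > 0) {
        bs <- sort(sample.int(len - block, n_blocks))
        # keep masked blocks clear of islands and of each other
        ok <- rep(TRUE, length(bs))
        if (length(pos)) {
          for (k in seq_along(bs)) {
            if (any(bs[k] < pos + spec$island_length_bp + 100 &
                      bs[k] + block > pos - 100)) ok[k] <- FALSE
          }
        }
        bs <- bs[ok]
        if (length(bs) > 1) bs <- bs[c(TRUE, diff(bs) >= block)]
        for (s in bs) {
          x[s:(s + block - 1)] <- tolower(x[s:(s + block - 1)])
        }
        if (length(bs)) {
          masked <- rbind(masked, data.frame(
            chrom = names(genome)[ci], start = bs - 1,
            end = bs - 1 + block, stringsAsFactors = FALSE))
        }
      }
    }
    genome[ci] <- paste(x, collapse = "")
  }
  list(genome = genome,
       islands = islands %||% data.frame(chrom = character(),
                                         start = numeric(), end = numeric(),
                                         name = character(),
                                         stringsAsFactors = FALSE),
       masked = masked %||% data.frame(chrom = character(),
                                       start = numeric(), end = numeric(),
                                       stringsAsFactors = FALSE),
       spec = spec)
}

# derive one species genome from the anchor: indels outside protected
# intervals, plus CpG degradation of islands absent in this species.
# Returns the species sequence and the anchor->species block map.
derive_species <- function(anchor, protected, degrade, spec) {
  blocks <- NULL
  seqs <- character(length(anchor))
  names(seqs) <- names(anchor)
  for (ci in seq_along(anchor)) {
    chrom <- names(anchor)[ci]
    x <- strsplit(anchor[[ci]], "")[[1]]
    # degrade absent islands first (substitutions keep coordinates)
    dg <- degrade[degrade$chrom == chrom, , drop = FALSE]
    if (nrow(dg)) {
      for (k in seq_len(nrow(dg))) {
        rng <- (dg$start[k] + 1):dg$end[k]
        seg <- x[rng]
        cg <- which(seg[-length(seg)] == "C" & seg[-1] == "G")
        hit <- cg[runif(length(cg)) < spec$degrade_cpg_prob]
        seg[hit] <- "T"
        x[rng] <- seg
      }
    }
    len <- length(x)
    n_events <- rbinom(1, round(len / 1000), min(1, spec$indel_rate_per_kb))
    prot <- protected[protected$chrom == chrom, , drop = FALSE]
    ev_pos <- sort(sample.int(len - 1, n_events))
    if (nrow(prot) && length(ev_pos)) {
      bad <- vapply(ev_pos, function(p) {
        any(p > prot$start - 100 & p <= prot$end + 100)
      }, TRUE)
      ev_pos <- ev_pos[!bad]
    }
    ev_len <- 1 + stats::rgeom(length(ev_pos), 1 / spec$indel_mean_bp)
    ev_del <- runif(length(ev_pos)) < 0.5
    # walk the anchor, emitting species sequence and aligned blocks
    out <- character(0)
    cur_anchor <- 0  # anchor bases consumed (0-based)
    cur_tgt <- 0
    for (k in seq_along(ev_pos)) {
      p <- ev_pos[k]
      if (p <= cur_anchor) next
      keep <- x[(cur_anchor + 1):p]
      out <- c(out, keep)
      blocks <- rbind(blocks, data.frame(
        src_chrom = chrom, src_start = cur_anchor, src_end = p,
        tgt_chrom = chrom, tgt_start = cur_tgt,
        tgt_end = cur_tgt + (p - cur_anchor), stringsAsFactors = FALSE))
      cur_tgt <- cur_tgt + (p - cur_anchor)
      if (ev_del[k]) {
        d <- min(ev_len[k], len - p)
        cur_anchor <- p + d          # anchor bases absent from species
      } else {
        ins <- random_seq_chars(ev_len[k], spec$background_gc)
        out <- c(out, ins)           # species bases absent from anchor
        cur_tgt <- cur_tgt + ev_len[k]
        cur_anchor <- p
      }
    }
    if (cur_anchor < len) {
      out <- c(out, x[(cur_anchor + 1):len])
      blocks <- rbind(blocks, data.frame(
        src_chrom = chrom, src_start = cur_anchor, src_end = len,
        tgt_chrom = chrom, tgt_start = cur_tgt,
        tgt_end = cur_tgt + (len - cur_anchor), stringsAsFactors = FALSE))
    }
    seqs[ci] <- paste(out, collapse = "")
  }
  list(seq = seqs, map_from_anchor = coordinate_map(blocks))
}

#' Generate a species pair with planted oCGI turnover
#'
#' Builds a "human" anchor genome with planted islands, assigns each island
#' a turnover status (shared / A_only / B_only) from
#' `spec$turnover_fractions`, then derives species A and B genomes by
#' applying indels (which break coordinate-map blocks) and by degrading
#' each island's CpGs (C->T deamination) in the species where it is
#' planted absent, keeping the sequence alignable. Indels avoid planted
#' islands so the planted truth stays clean.
#'
#' @param spec a [synthetic_spec()].
#' @return List: `human`, `A`, `B` (named sequence vectors), `maps` (all
#'   four [coordinate_map()]s via the human intermediate), `islands`
#'   (planted truth: human coordinates, per-species coordinates and
#'   `status`), and the anchor's `masked` blocks.
#' @export
make_species_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  anchor <- make_genome(spec)
  set.seed(spec$seed + 1)
  isl <- anchor$islands
  status <- sample(names(spec$turnover_fractions), nrow(isl),
                   replace = TRUE, prob = spec$turnover_fractions)
  isl$status <- status
  degrade_A <- isl[isl$status == "B_only", c("chrom", "start", "end")]
  degrade_B <- isl[isl$status == "A_only", c("chrom", "start", "end")]
  prot <- isl[, c("chrom", "start", "end")]
  A <- derive_species(anchor$genome, prot, degrade_A, spec)
  B <- derive_species(anchor$genome, prot, degrade_B, spec)
  map_h_to_A <- A$map_from_anchor
  map_h_to_B <- B$map_from_anchor
  coords_in <- function(map) {
    m <- map_intervals(isl, map)
    data.frame(chrom = m$chrom, start = m$start, end = m$end,
               stringsAsFactors = FALSE)
  }
  cA <- coords_in(map_h_to_A); cB <- coords_in(map_h_to_B)
  isl$chrom_A <- cA$chrom; isl$start_A <- cA$start; isl$end_A <- cA$end
  isl$chrom_B <- cB$chrom; isl$start_B <- cB$start; isl$end_B <- cB$end
  list(human = anchor$genome, A = A$seq, B = B$seq,
       maps = list(A_to_human = invert_map(map_h_to_A),
                   B_to_human = invert_map(map_h_to_B),
                   human_to_A = map_h_to_A, human_to_B = map_h_to_B),
       islands = isl, masked = anchor$masked, spec = spec)
}

#' Draw labeled sites under the oCGI/peak coupling model
#'
#' The statistical core consumed by the grid test: each site has an oCGI
#' species-specificity label and a peak label. Peak `none` labels are
#' assigned independently of the oCGI label (so excluding no-peak sites is
#' ignorable); among the remaining labels, the probability that a
#' species-specific oCGI's peak carries the *same* species label is
#' `coupling` times its marginal, with the shared-oCGI row absorbing the
#' complement so the peak marginals are preserved exactly. At coupling 1
#' the labels are independent.
#'
#' @param n number of sites.
#' @param ocgi_fractions length-3 simplex over c(A_only, B_only, shared).
#' @param peak_fractions length-4 simplex over c(A_only, B_only, shared,
#'   none).
#' @param coupling enrichment factor (>= 1) of the matched cells.
#' @param seed optional integer seed.
#' @return Data frame with `label` and `peak_label` columns.
#' @export
simulate_labeled_sites <- function(n,
                                   ocgi_fractions = c(A_only = 0.2,
                                                      B_only = 0.2,
                                                      shared = 0.6),
                                   peak_fractions = c(A_only = 0.15,
                                                      B_only = 0.15,
                                                      shared = 0.5,
                                                      none = 0.2),
                                   coupling = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- ocgi_fractions / sum(ocgi_fractions)
  m4 <- peak_fractions / sum(peak_fractions)
  m <- m4[c("A_only", "B_only", "shared")] / (1 - m4[["none"]])
  cond <- conditional_peak_probs(f, m, coupling)
  ocgi <- sample(c("A_only", "B_only", "shared"), n, replace = TRUE,
                 prob = f)
  peak <- character(n)
  is_none <- runif(n) < m4[["none"]]
  for (lab in c("A_only", "B_only", "shared")) {
    idx <- which(ocgi == lab & !is_none)
    if (length(idx)) {
      peak[idx] <- sample(c("A_only", "B_only", "shared"), length(idx),
                          replace = TRUE, prob = cond[lab, ])
    }
  }
  peak[is_none] <- "none"
  data.frame(label = ocgi, peak_label = peak, stringsAsFactors = FALSE)
}

# conditional P(peak label | ocgi label) among sites with a peak, chosen so
# P(match | A_only) = coupling * m_A (same for B), with the shared row
# solving the marginal constraints exactly
conditional_peak_probs <- function(f, m, coupling) {
  labs <- c("A_only", "B_only", "shared")
  f <- setNames(as.numeric(f[labs]), labs)
  m <- setNames(as.numeric(m[labs]), labs)
  cond <- matrix(0, 3, 3, dimnames = list(labs, labs))
  for (lab in c("A_only", "B_only")) {
    pm <- coupling * m[[lab]]
    stop_if(pm > 1, "coupling %.2f infeasible: conditional exceeds 1",
            coupling)
    rest <- m[setdiff(labs, lab)]
    cond[lab, lab] <- pm
    cond[lab, setdiff(labs, lab)] <- (1 - pm) * rest / sum(rest)
  }
  cond["shared", ] <- (m - f[["A_only"]] * cond["A_only", ] -
                         f[["B_only"]] * cond["B_only", ]) / f[["shared"]]
  stop_if(any(cond["shared", ] < -1e-9),
          "coupling %.2f infeasible for these fractions", coupling)
  cond["shared", ] <- pmax(cond["shared", ], 0)
  cond["shared", ] <- cond["shared", ] / sum(cond["shared", ])
  cond
}

#' Place peaks and signal over a species pair
#'
#' Realizes the coupling model on the genomes of [make_species_pair()]:
#' each planted island (ordered by status) receives a peak label drawn
#' from the conditional coupling distribution given its oCGI status; a
#' peak interval (island extended by `flank_bp`) is created in each
#' species where the peak is present. Background peaks landing away from
#' islands are added in both species ("shared", uncoupled). Per-peak
#' signal is log-normal, multiplied by `signal_boost_at_ocgi` for peaks
#' containing an oCGI, and converted to integer read counts consistent
#' with RPKM at the stated library size.
#'
#' @param pair output of [make_species_pair()].
#' @param spec the same [synthetic_spec()].
#' @param flank_bp peak extension on each side of an island.
#' @param n_background_peaks background (island-free) peaks per species.
#' @param library_size per-species library size in reads.
#' @return List with per-species peak data frames (interval, signal,
#'   read_count, has_ocgi), library sizes, and the per-island truth table.
#' @export
make_peaks_and_signal <- function(pair, spec, flank_bp = 300,
                                  n_background_peaks = 100,
                                  library_size = 2e7) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2)
  isl <- pair$islands
  f <- spec$turnover_fractions[c("A_only", "B_only", "shared")]
  m4 <- spec$peak_fractions / sum(spec$peak_fractions)
  m <- m4[c("A_only", "B_only", "shared")] / (1 - m4[["none"]])
  cond <- conditional_peak_probs(f / sum(f), m, spec$peak_coupling)
  n <- nrow(isl)
  peak_label <- character(n)
  is_none <- runif(n) < m4[["none"]]
  for (lab in c("A_only", "B_only", "shared")) {
    idx <- which(isl$status == lab & !is_none)
    if (length(idx)) {
      peak_label[idx] <- sample(c("A_only", "B_only", "shared"),
                                length(idx), replace = TRUE,
                                prob = cond[lab, ])
    }
  }
  peak_label[is_none] <- "none"
  isl$peak_label <- peak_label

  base_signal <- rlnorm(n, meanlog = 1, sdlog = 0.5)
  # background peaks: placed on the human anchor away from islands and
  # realized in both species through the coordinate maps, so they are
  # shared-by-construction (orthologous) and never fake species-specific
  # turnover at a site
  gl <- nchar(pair$human)
  bg_chrom <- sample(names(pair$human), n_background_peaks, replace = TRUE)
  bg_start <- floor(runif(n_background_peaks, 0, gl[bg_chrom] - 1000))
  bg_h <- data.frame(chrom = bg_chrom, start = bg_start,
                     end = bg_start + 800,
                     name = sprintf("bgpeak_%d",
                                    seq_len(n_background_peaks)),
                     stringsAsFactors = FALSE)
  bg_h <- bg_h[!overlap_any(bg_h, bed_frame(isl$chrom,
                                            pmax(0, isl$start - flank_bp),
                                            isl$end + flank_bp)), ,
               drop = FALSE]
  bg_signal <- rlnorm(nrow(bg_h), 1, 0.5)

  mk_peaks <- function(side) {
    chrom <- isl[[paste0("chrom_", side)]]
    start <- isl[[paste0("start_", side)]]
    end <- isl[[paste0("end_", side)]]
    present_peak <- peak_label %in% c(paste0(side, "_only"), "shared") &
      !is.na(start)
    has_ocgi <- isl$status %in% c(paste0(side, "_only"), "shared")
    sig <- base_signal * ifelse(has_ocgi, spec$signal_boost_at_ocgi, 1)
    idx <- which(present_peak)
    df <- data.frame(chrom = chrom[idx],
                     start = pmax(0, start[idx] - flank_bp),
                     end = end[idx] + flank_bp,
                     name = isl$name[idx], signal = sig[idx],
                     has_ocgi = has_ocgi[idx], stringsAsFactors = FALSE)
    bg <- map_intervals(bg_h, pair$maps[[paste0("human_to_", side)]])
    ok <- !is.na(bg$start)
    bg <- data.frame(chrom = bg$chrom[ok], start = bg$start[ok],
                     end = bg$end[ok], name = bg_h$name[ok],
                     signal = bg_signal[ok], has_ocgi = FALSE,
                     stringsAsFactors = FALSE)
    df <- rbind(df, bg)
    df$read_count <- as.integer(round(
      df$signal * ((df$end - df$start) / 1000) * (library_size / 1e6)))
    df
  }
  peaks_A <- mk_peaks("A")
  peaks_B <- mk_peaks("B")
  list(peaks_A = peaks_A, peaks_B = peaks_B,
       library_sizes = c(A = library_size, B = library_size),
       truth = isl)
}

#' Generate a gene expression table with planted effects
#'
#' Genes get log-normal baseline expression and negative-binomial read
#' counts in each species; genes planted in the A-only set receive a
#' `2^expression_log2_effect` fold boost in species A (and symmetrically
#' for the B-only set in species B).
#'
#' @param spec a [synthetic_spec()].
#' @param gene_sets_truth optional character vector (length `n_genes`) of
#'   planted set labels (`A_only_set`, `B_only_set`, `background_set`);
#'   default: 10% A-only, 10% B-only.
#' @return Data frame: id, exon_length_bp, counts_A, counts_B,
#'   is_one_to_one_ortholog, set_truth.
#' @export
make_expression <- function(spec, gene_sets_truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3)
  n <- spec$n_genes
  if (is.null(gene_sets_truth)) {
    gene_sets_truth <- sample(c("A_only_set", "B_only_set",
                                "background_set"), n, replace = TRUE,
                              prob = c(0.1, 0.1, 0.8))
  }
  stopifnot(length(gene_sets_truth) == n)
  exon_len <- round(runif(n, 500, 10000))
  base_mu <- rlnorm(n, meanlog = 4, sdlog = 1)
  eff <- spec$expression_log2_effect
  mu_A <- base_mu * ifelse(gene_sets_truth == "A_only_set", 2^eff, 1)
  mu_B <- base_mu * ifelse(gene_sets_truth == "B_only_set", 2^eff, 1)
  scale <- exon_len / 1000
  data.frame(id = sprintf("gene_%d", seq_len(n)),
             exon_length_bp = exon_len,
             counts_A = rnbinom(n, mu = mu_A * scale,
                                size = spec$nb_dispersion),
             counts_B = rnbinom(n, mu = mu_B * scale,
                                size = spec$nb_dispersion),
             is_one_to_one_ortholog = TRUE,
             set_truth = gene_sets_truth, stringsAsFactors = FALSE)
}

#' Generate an enhancer table with a planted HGE pattern excess
#'
#' Background enhancers draw oCGI triple patterns from a fixed mammalian-
#' like distribution; HGEs draw the same distribution with the human-only
#' pattern probability multiplied by `hge_pattern_multiplier`
#' (renormalized), plus a higher mean signal so that signal matching is
#' exercised.
#'
#' @param spec a [synthetic_spec()].
#' @param n_hge,n_background set sizes.
#' @return Data frame: signal, is_hge, pattern.
#' @export
make_enhancers <- function(spec, n_hge = 300, n_background = 3000) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 4)
  base <- c(human_only = 0.05, rhesus_only = 0.04, mouse_only = 0.04,
            human_rhesus = 0.06, human_mouse = 0.03, rhesus_mouse = 0.03,
            all_three = 0.10, none = 0.65)
  hge_probs <- base
  hge_probs[["human_only"]] <- base[["human_only"]] *
    spec$hge_pattern_multiplier
  hge_probs <- hge_probs / sum(hge_probs)
  data.frame(
    signal = c(rlnorm(n_hge, 1.5, 0.6), rlnorm(n_background, 1.0, 0.8)),
    is_hge = rep(c(TRUE, FALSE), c(n_hge, n_background)),
    pattern = c(sample(names(base), n_hge, replace = TRUE,
                       prob = hge_probs),
                sample(names(base), n_background, replace = TRUE,
                       prob = base)),
    stringsAsFactors = FALSE)
}
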