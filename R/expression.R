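#' Transcripts per million from counts and exon lengths
#'
#' rate_g = counts_g / exon_length_kb_g; TPM_g = 1e6 * rate_g / sum(rates).
#' Per-sample TPM values sum to 1e6 exactly (up to floating tolerance).
#'
#' @param counts non-negative integer vector of per-gene read counts.
#' @param exon_length_bp positive per-gene total exon lengths.
#' @param ids optional gene ids used as names.
#' @return Named numeric vector of TPM values.
#' @export
compute_tpm <- function(counts, exon_length_bp, ids = NULL) {
  stop_if(any(exon_length_bp <= 0), "exon lengths must be positive")
  stop_if(any(counts < 0), "counts must be non-negative")
  stop_if(all(counts == 0), "all-zero counts: TPM undefined")
  rate <- counts / (exon_length_bp / 1000)
  tpm <- 1e6 * rate / sum(rate)
  if (!is.null(ids)) names(tpm) <- ids
  tpm
}

#' GREAT-rule regulatory domains
#'
#' Each gene gets a strand-aware basal domain of 5 kb upstream and 1 kb
#' downstream of its TSS. The basal domain is then extended, in each
#' direction, to the boundary of the nearest other gene's basal domain, up
#' to 1 Mb from the basal edge, and clipped to the chromosome. Basal
#' domains are never truncated, even when they overlap a neighboring basal
#' domain.
#'
#' @param genes data frame with columns `id`, `chrom`, `tss` (0-based
#'   position), `strand` (+/-).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param basal_upstream_bp,basal_downstream_bp basal window (defaults 5 kb
#'   up / 1 kb down).
#' @param max_extension_bp extension cap beyond the basal edge (default
#'   1 Mb).
#' @return Data frame: id, chrom, basal_start, basal_end, start, end
#'   (extended domain).
#' @export
great_domains <- function(genes, chrom_sizes,
                          basal_upstream_bp = 5000,
                          basal_downstream_bp = 1000,
                          max_extension_bp = 1e6) {
  stopifnot(all(c("id", "chrom", "tss", "strand") %in% names(genes)))
  stop_if(any(!genes$strand %in% c("+", "-")), "gene strand must be + or -")
  stop_if(any(!genes$chrom %in% names(chrom_sizes)),
          "gene on a chromosome with unknown size")
  plus <- genes$strand == "+"
  basal_start <- pmax(0, ifelse(plus, genes$tss - basal_upstream_bp,
                                genes$tss - basal_downstream_bp))
  lim <- chrom_sizes[genes$chrom]
  basal_end <- pmin(lim, ifelse(plus, genes$tss + basal_downstream_bp,
                                genes$tss + basal_upstream_bp))
  n <- nrow(genes)
  ext_start <- numeric(n); ext_end <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- same[same != i]
    lo <- max(0, basal_start[i] - max_extension_bp)
    hi <- min(lim[i], basal_end[i] + max_extension_bp)
    if (length(same)) {
      # nearest basal edge on each side, clamped so an overlapping
      # neighbor stops extension at the basal edge itself
      left_edges <- pmin(basal_end[same], basal_start[i])
      left_edges <- left_edges[basal_start[same] <= basal_start[i] |
                                 basal_end[same] <= basal_start[i]]
      if (length(left_edges)) lo <- max(lo, max(left_edges))
      right_edges <- pmax(basal_start[same], basal_end[i])
      right_edges <- right_edges[basal_end[same] >= basal_end[i] |
                                   basal_start[same] >= basal_end[i]]
      if (length(right_edges)) hi <- min(hi, min(right_edges))
    }
    ext_start[i] <- min(lo, basal_start[i])
    ext_end[i] <- max(hi, basal_end[i])
  }
  data.frame(id = genes$id, chrom = genes$chrom,
             basal_start = basal_start, basal_end = basal_end,
             start = ext_start, end = ext_end, stringsAsFactors = FALSE)
}

#' Assign genes to oCGI-turnover gene sets
#'
#' Using only species-specific oCGIs lying in same-species-specific peaks
#' (the qualifying sites), a gene joins the A-only set when at least one
#' A-qualifying site falls in its extended regulatory domain and no
#' B-qualifying site does; symmetrically for the B-only set. Genes with
#' both kinds are the mixed set (excluded from testing); genes with
#' neither form the background set.
#'
#' @param domains output of [great_domains()].
#' @param qualifying_sites interval data frame with a `label` column of
#'   `A_only`/`B_only` (sites where oCGI label equals peak label), in the
#'   same coordinate system as `domains`.
#' @return Named character vector gene id -> set label (`A_only_set`,
#'   `B_only_set`, `mixed_set`, `background_set`).
#' @export
assign_gene_sets <- function(domains, qualifying_sites) {
  stop_if(!all(qualifying_sites$label %in% c("A_only", "B_only")),
          "qualifying sites must be labeled A_only or B_only")
  dom <- data.frame(chrom = domains$chrom, start = domains$start,
                    end = domains$end, stringsAsFactors = FALSE)
  qa <- qualifying_sites[qualifying_sites$label == "A_only", , drop = FALSE]
  qb <- qualifying_sites[qualifying_sites$label == "B_only", , drop = FALSE]
  has_a <- overlap_any(dom, qa)
  has_b <- overlap_any(dom, qb)
  labels <- ifelse(has_a & has_b, "mixed_set",
                   ifelse(has_a, "A_only_set",
                          ifelse(has_b, "B_only_set", "background_set")))
  setNames(labels, domains$id)
}

#' Expression-matched resampling test on log2 TPM ratios
#'
#' For every 1:1-ortholog gene with non-zero TPM in both species,
#' r_g = log2(TPM_A / TPM_B). For each test set (A-only and B-only), each
#' round resamples from the background set a gene set matched in size and
#' in mean-expression bin composition (quantile bins of the mean of the two
#' species' log2 TPM), recording its median r. The observed median is
#' normalized by subtracting the across-round median of background medians;
#' the p-value is a two-sided add-one tail probability of the observed
#' median against the resampled-median distribution, with BH correction
#' across the tested sets.
#'
#' @param assignments named vector gene id -> set label (from
#'   [assign_gene_sets()]).
#' @param tpm_A,tpm_B named TPM vectors covering the assigned genes.
#' @param rounds resampling rounds (default 10000).
#' @param n_bins expression quantile bins (default 10).
#' @param seed optional integer seed.
#' @return An `expression_ratio_test` data frame with one row per tested
#'   set: n_genes, median_log2_ratio (raw), normalized_median, p, q,
#'   underpowered flag; attribute `n_zero_dropped` counts genes removed for
#'   zero TPM.
#' @export
expression_ratio_test <- function(assignments, tpm_A, tpm_B, rounds = 10000,
                                  n_bins = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(assignments)
  stop_if(is.null(ids), "assignments must be named by gene id")
  stop_if(!all(ids %in% names(tpm_A)) || !all(ids %in% names(tpm_B)),
          "TPM vectors must cover all assigned genes")
  a <- tpm_A[ids]; b <- tpm_B[ids]
  nonzero <- a > 0 & b > 0
  n_dropped <- sum(!nonzero)
  keep <- nonzero & assignments != "mixed_set"
  ids <- ids[keep]; a <- a[keep]; b <- b[keep]
  lab <- assignments[keep]
  r <- log2(a / b)
  m <- (log2(a) + log2(b)) / 2
  edges <- unique(quantile(m, probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  bin <- cut(m, edges, labels = FALSE)
  nb <- length(edges) - 1L
  bg <- which(lab == "background_set")
  stop_if(!length(bg), "no background genes available")
  bg_by_bin <- lapply(seq_len(nb), function(k) bg[bin[bg] == k])

  test_one <- function(set_label) {
    test <- which(lab == set_label)
    if (!length(test)) return(NULL)
    # per-set RNG stream keyed by the set's gene composition, not by the
    # order sets are processed: swapping species (which swaps the A and B
    # set labels over the same genes) then reproduces identical resampling
    # draws, making the sign-flip under species swap exact
    if (!is.null(seed)) {
      set.seed(as.integer((seed + sum(as.numeric(test)) * 131 +
                             length(test)) %% (.Machine$integer.max - 1)))
    }
    counts <- tabulate(bin[test], nb)
    empty <- which(counts > 0 & lengths(bg_by_bin) == 0)
    stop_if(length(empty) > 0,
            "expression bin %d has test genes but no background; use fewer bins",
            empty[1])
    meds <- vapply(seq_len(rounds), function(rd) {
      picks <- unlist(lapply(which(counts > 0), function(k) {
        bg_by_bin[[k]][sample.int(length(bg_by_bin[[k]]), counts[k],
                                  replace = TRUE)]
      }))
      median(r[picks])
    }, 0)
    center <- median(meds)
    obs <- median(r[test])
    p <- (1 + sum(abs(meds - center) >= abs(obs - center))) / (1 + rounds)
    data.frame(set = set_label, n_genes = length(test),
               median_log2_ratio = obs, normalized_median = obs - center,
               p = p, underpowered = length(test) < 5,
               stringsAsFactors = FALSE)
  }
  out <- rbind(test_one("A_only_set"), test_one("B_only_set"))
  stop_if(is.null(out), "no genes in the A-only or B-only sets")
  out$q <- bh_correct(out$p)
  attr(out, "n_zero_dropped") <- n_dropped
  attr(out, "rounds") <- rounds
  class(out) <- c("expression_ratio_test", "data.frame")
  out
}

#' @export
print.expression_ratio_test <- function(x, ...) {
  cat(sprintf("expression-matched resampling test (%d rounds; %d gene(s) dropped for zero TPM)\n",
              attr(x, "rounds"), attr(x, "n_zero_dropped")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (any(x$underpowered)) {
    cat("note: sets with fewer than 5 genes are flagged underpowered\n")
  }
  invisible(x)
}
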