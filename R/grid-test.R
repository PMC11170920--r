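ocgi_label_levels <- c("A_only", "B_only", "shared")
peak_label_levels <- c("A_only", "B_only", "shared", "none")

#' Label orthologous oCGI sites by peak species-specificity
#'
#' Each orthologous site is intersected (1 bp of overlap suffices) with the
#' reproducible peaks of both species: a site overlapping peaks in both
#' species is `shared`, in exactly one `A_only`/`B_only`, and in neither
#' `none`. `none` sites are retained but flagged excluded -- they do not
#' enter the enrichment grid.
#'
#' @param sites output of [build_orthologous_sites()] (needs the
#'   per-species interval columns).
#' @param peaks_A,peaks_B peak interval data frames in the two species'
#'   genomes.
#' @return `sites` with added `peak_label` and `excluded` columns.
#' @export
label_sites <- function(sites, peaks_A, peaks_B) {
  if (!nrow(sites)) {
    sites$peak_label <- character(0); sites$excluded <- logical(0)
    return(sites)
  }
  iv_A <- data.frame(chrom = sites$chrom_A, start = sites$start_A,
                     end = sites$end_A, stringsAsFactors = FALSE)
  iv_B <- data.frame(chrom = sites$chrom_B, start = sites$start_B,
                     end = sites$end_B, stringsAsFactors = FALSE)
  in_A <- overlap_any(iv_A, peaks_A)
  in_B <- overlap_any(iv_B, peaks_B)
  sites$peak_label <- ifelse(in_A & in_B, "shared",
                             ifelse(in_A, "A_only",
                                    ifelse(in_B, "B_only", "none")))
  sites$excluded <- sites$peak_label == "none"
  sites
}

#' Tally the 3x3 oCGI-by-peak species-specificity grid
#'
#' Counts sites over the nine (oCGI label x peak label) combinations,
#' excluding sites with no peak in either species.
#'
#' @param sites data frame with `label` (oCGI: A_only/B_only/shared) and
#'   `peak_label` (A_only/B_only/shared/none) columns.
#' @return 3x3 integer matrix (rows: oCGI label; columns: peak label).
#' @export
build_grid <- function(sites) {
  keep <- sites$peak_label != "none"
  tab <- table(factor(sites$label[keep], levels = ocgi_label_levels),
               factor(sites$peak_label[keep],
                      levels = ocgi_label_levels))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(ocgi = ocgi_label_levels,
                              peak = ocgi_label_levels))
  m
}

#' Label-permutation test on the species-specificity grid
#'
#' Holds the anchored entity's labels fixed and permutes the other entity's
#' label multiset across sites uniformly at random, re-tallying the grid
#' each round. In the oCGI-centric mode (the default) oCGI labels are fixed
#' and peak labels are permuted; the peak-centric mode is the same operation
#' with the roles swapped. Per cell: expected = mean permuted count,
#' enrichment = observed/expected (NA when expected is 0), two-sided
#' add-one p, and BH q across the nine cells. Sites with no peak in either
#' species are excluded first.
#'
#' @param sites labeled site data frame (see [label_sites()]).
#' @param rounds number of permutation rounds (>= 100).
#' @param seed optional integer seed.
#' @param mode `"ocgi"` (permute peak labels) or `"peak"` (permute oCGI
#'   labels).
#' @param check_marginals assert per-round marginal preservation (test
#'   mode).
#' @return A `grid_test` object: observed, expected, enrichment, p, q
#'   matrices plus metadata.
#' @export
permutation_grid_test <- function(sites, rounds = 20000, seed = NULL,
                                  mode = c("ocgi", "peak"),
                                  check_marginals = FALSE) {
  mode <- match.arg(mode)
  stop_if(rounds < 100, "rounds must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  keep <- sites$peak_label != "none"
  anchored <- factor(sites$label[keep], levels = ocgi_label_levels)
  permuted <- factor(sites$peak_label[keep], levels = ocgi_label_levels)
  if (mode == "peak") { tmp <- anchored; anchored <- permuted; permuted <- tmp }
  n <- length(anchored)
  stop_if(n == 0, "no sites with a peak in either species")
  a <- as.integer(anchored)
  b <- as.integer(permuted)
  observed <- matrix(tabulate((a - 1L) * 3L + b, nbins = 9L), 3, 3,
                     byrow = TRUE,
                     dimnames = list(anchored = ocgi_label_levels,
                                     permuted = ocgi_label_levels))
  acc <- matrix(0, 3, 3)
  extreme <- matrix(0, 3, 3)
  perm_counts <- matrix(0L, rounds, 9L)
  row_marg <- tabulate(a, 3L); col_marg <- tabulate(b, 3L)
  for (r in seq_len(rounds)) {
    bp <- b[sample.int(n)]
    cnt <- tabulate((a - 1L) * 3L + bp, nbins = 9L)
    if (check_marginals) {
      m <- matrix(cnt, 3, 3, byrow = TRUE)
      stopifnot(all(rowSums(m) == row_marg), all(colSums(m) == col_marg))
    }
    perm_counts[r, ] <- cnt
  }
  expected <- matrix(colMeans(perm_counts), 3, 3, byrow = TRUE,
                     dimnames = dimnames(observed))
  obs_vec <- as.vector(t(observed))
  exp_vec <- colMeans(perm_counts)
  p_vec <- vapply(1:9, function(k) {
    (1 + sum(abs(perm_counts[, k] - exp_vec[k]) >=
               abs(obs_vec[k] - exp_vec[k]))) / (1 + rounds)
  }, 0)
  p <- matrix(p_vec, 3, 3, byrow = TRUE, dimnames = dimnames(observed))
  q <- matrix(bh_correct(p_vec), 3, 3, byrow = TRUE,
              dimnames = dimnames(observed))
  enrichment <- observed / expected
  enrichment[expected == 0] <- NA_real_
  structure(list(observed = observed, expected = expected,
                 enrichment = enrichment, p = p, q = q, rounds = rounds,
                 mode = mode, n_sites = n), class = "grid_test")
}

#' @export
print.grid_test <- function(x, ...) {
  cat(sprintf("%s-centric label-permutation grid test (%d sites, %d rounds)\n",
              x$mode, x$n_sites, x$rounds))
  cat("\nObserved counts:\n"); print(x$observed)
  cat("\nEnrichment (observed/expected):\n")
  print(round(x$enrichment, 3))
  cat("\nBH q-values:\n"); print(signif(x$q, 3))
  invisible(x)
}

#' Benjamini-Hochberg correction
#'
#' Step-up BH q-values (validation wrapper around `p.adjust`).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
bh_correct <- function(p_values) {
  stop_if(any(is.na(p_values)) || any(p_values < 0 | p_values > 1),
          "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
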