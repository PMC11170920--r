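# Independent brute-force oracles used to cross-check the interval algebra
# and sequence statistics. These deliberately use per-base boolean masks and
# quadratic scans, not the package's own code paths.

# per-base coverage mask of an interval set over [0, size) on one chromosome
bitmask_oracle <- function(df, chrom, size) {
  mask <- logical(size)
  sel <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    mask[(sel$start[i] + 1):sel$end[i]] <- TRUE
  }
  mask
}

mask_to_intervals <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

# quadratic overlap check
overlap_oracle <- function(query, subject, min_bp = 1) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          pmin(subject$end, query$end[i]) -
            pmax(subject$start, query$start[i]) >= min_bp)
  }, TRUE)
}

# character-level recount of interval sequence statistics
stats_oracle <- function(seq, start, end) {
  x <- strsplit(substr(seq, start + 1, end), "")[[1]]
  x[x %in% letters] <- "N"
  x[!x %in% c("A", "C", "G", "T")] <- "N"
  nc <- sum(x == "C"); ng <- sum(x == "G")
  counted <- sum(x != "N")
  cpg <- sum(x[-length(x)] == "C" & x[-1] == "G")
  L <- end - start
  list(gc_fraction = if (counted) (nc + ng) / counted else 0,
       cpg_count = cpg,
       obs_exp_ratio = if (nc * ng > 0) cpg * L / (nc * ng) else 0)
}

# random interval set generator for property tests
random_intervals <- function(n, chroms = c("chr1", "chr2"), size = 10000,
                             max_len = 500) {
  start <- floor(runif(n, 0, size - max_len))
  len <- ceiling(runif(n, 1, max_len))
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + len, stringsAsFactors = FALSE)
}

# per-gene nearest-basal scan for GREAT domains (direct definition)
great_oracle <- function(genes, chrom_sizes, up = 5000, down = 1000,
                         cap = 1e6) {
  plus <- genes$strand == "+"
  bs <- pmax(0, ifelse(plus, genes$tss - up, genes$tss - down))
  be <- pmin(chrom_sizes[genes$chrom],
             ifelse(plus, genes$tss + down, genes$tss + up))
  n <- nrow(genes)
  out <- data.frame(id = genes$id, start = numeric(n), end = numeric(n))
  for (i in seq_len(n)) {
    lo <- max(0, bs[i] - cap); hi <- min(chrom_sizes[genes$chrom[i]],
                                         be[i] + cap)
    for (j in seq_len(n)) {
      if (j == i || genes$chrom[j] != genes$chrom[i]) next
      if (be[j] <= bs[i]) {
        lo <- max(lo, be[j])                 # neighbor fully upstream
      } else if (bs[j] <= bs[i]) {
        lo <- max(lo, bs[i])                 # neighbor basal covers our edge
      }
      if (bs[j] >= be[i]) {
        hi <- min(hi, bs[j])                 # neighbor fully downstream
      } else if (be[j] >= be[i]) {
        hi <- min(hi, be[i])                 # neighbor basal covers our edge
      }
    }
    out$start[i] <- min(lo, bs[i]); out$end[i] <- max(hi, be[i])
  }
  out
}
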